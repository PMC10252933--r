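## Readers and writers for the delimited-text interchange formats:
## portal-style matrix exports (CSV or TSV), two-column lineage tables,
## gene-category pair tables, survival tables and the package's own TSV
## record tables.

.detectDelim <- function(path) {
    header <- readLines(path, n = 1L)
    if (length(header) == 0L) stop("empty file: ", path)
    nTab <- lengths(regmatches(header, gregexpr("\t", header)))
    nCom <- lengths(regmatches(header, gregexpr(",", header)))
    if (nTab >= nCom) "\t" else ","
}

.readDelimRaw <- function(path, delim = NULL) {
    if (is.null(delim)) delim <- .detectDelim(path)
    utils::read.table(path, sep = delim, header = TRUE, check.names = FALSE,
                      colClasses = "character", quote = "\"",
                      comment.char = "", stringsAsFactors = FALSE)
}

#' Load a gene-effect, expression or dependency-probability matrix
#'
#' Reads a delimited matrix export (one header row, first column = labels)
#' and returns it in the canonical lines-by-genes orientation. The delimiter
#' is auto-detected between comma and tab from the header row unless given.
#' Empty cells (and literal `NA`) become missing values. Gene labels of the
#' portal form `"SYMBOL (1234)"` are kept verbatim as the gene identity;
#' [geneSymbols()] parses the bare symbol on demand.
#'
#' @param path path to a CSV/TSV file.
#' @param orientation `"lines_by_genes"` (rows are cell lines, the portal
#'   export convention) or `"genes_by_lines"`; the file is transposed to the
#'   canonical orientation as needed.
#' @param what which container to build: `"effect"` (default),
#'   `"expression"` or `"probability"`.
#' @param platform platform tag for gene-effect matrices.
#' @param delim optional delimiter override (`","` or `"\t"`).
#' @return A [GeneEffectMatrix-class], [ExpressionMatrix-class] or
#'   [DependencyProbabilityMatrix-class].
#' @details Duplicate row or column labels, non-numeric cells (reported with
#'   their row/column coordinates) and, for probabilities, values outside
#'   \[0, 1\] are hard errors.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(line = c("A", "B"), `MYB (4602)` = c(-1, 0),
#'                      TP53 = c(0.2, NA), check.names = FALSE),
#'           f, row.names = FALSE)
#' ge <- loadMatrix(f, platform = "crispr")
#' geneSymbols(ge)
#' @export
loadMatrix <- function(path,
                       orientation = c("lines_by_genes", "genes_by_lines"),
                       what = c("effect", "expression", "probability"),
                       platform = c("crispr", "rnai"),
                       delim = NULL) {
    orientation <- match.arg(orientation)
    what <- match.arg(what)
    platform <- match.arg(platform)
    raw <- .readDelimRaw(path, delim)
    if (ncol(raw) < 2L)
        stop("matrix file needs a label column plus at least one data column")
    rowLabels <- raw[[1L]]
    colLabels <- colnames(raw)[-1L]
    if (anyDuplicated(rowLabels))
        stop("duplicate row labels: ",
             paste(unique(rowLabels[duplicated(rowLabels)]), collapse = ", "))
    if (anyDuplicated(colLabels))
        stop("duplicate column labels: ",
             paste(unique(colLabels[duplicated(colLabels)]), collapse = ", "))
    vals <- matrix(NA_real_, nrow(raw), length(colLabels),
                   dimnames = list(rowLabels, colLabels))
    for (j in seq_along(colLabels)) {
        cell <- raw[[j + 1L]]
        blank <- is.na(cell) | !nzchar(trimws(cell)) | trimws(cell) == "NA"
        num <- suppressWarnings(as.numeric(cell))
        bad <- which(is.na(num) & !blank)
        if (length(bad))
            stop("non-numeric value '", cell[bad[1L]], "' at row '",
                 rowLabels[bad[1L]], "', column '", colLabels[j], "'")
        vals[, j] <- num
    }
    if (orientation == "genes_by_lines") vals <- t(vals)
    switch(what,
           effect = GeneEffectMatrix(vals, platform = platform),
           expression = ExpressionMatrix(vals),
           probability = DependencyProbabilityMatrix(vals))
}

#' Load a cell-line lineage annotation
#'
#' Reads a two-column delimited file (header row, then cell-line id and
#' lineage label per row). Exact duplicate rows are deduplicated; a line id
#' mapped to two different lineages is a hard error naming the line.
#'
#' @param path path to the file (delimiter auto-detected).
#' @param delim optional delimiter override.
#' @return A [LineageAnnotation-class].
#' @export
loadLineageAnnotation <- function(path, delim = NULL) {
    raw <- .readDelimRaw(path, delim)
    if (ncol(raw) < 2L)
        stop("lineage file needs two columns: cell-line id, lineage")
    df <- unique(data.frame(line = raw[[1L]], lineage = raw[[2L]],
                            stringsAsFactors = FALSE))
    conflict <- unique(df$line[duplicated(df$line)])
    if (length(conflict))
        stop("cell line mapped to more than one lineage: ",
             paste(conflict, collapse = ", "))
    LineageAnnotation(df$line, df$lineage)
}

#' Load a gene-to-category annotation table
#'
#' Reads a two-column file of (gene, category) pairs, one pair per row.
#'
#' @param path path to the file (delimiter auto-detected).
#' @param background optional universe gene ids; defaults to the annotated
#'   genes.
#' @param delim optional delimiter override.
#' @return An [AnnotationTable-class].
#' @export
loadAnnotationTable <- function(path, background = NULL, delim = NULL) {
    raw <- .readDelimRaw(path, delim)
    if (ncol(raw) < 2L)
        stop("annotation file needs two columns: gene, category")
    AnnotationTable(raw[[1L]], raw[[2L]], background = background)
}

#' Load a survival table
#'
#' Reads a delimited file with columns `patient`, `time`, `event`,
#' `expression` (extra columns are ignored).
#'
#' @param path path to the file (delimiter auto-detected).
#' @param delim optional delimiter override.
#' @return A data.frame usable as a survival cohort (see [kmLogrankHr()]).
#' @export
loadSurvivalCohort <- function(path, delim = NULL) {
    raw <- .readDelimRaw(path, delim)
    need <- c("time", "event", "expression")
    if (!all(need %in% colnames(raw)))
        stop("survival file needs columns: ", paste(need, collapse = ", "))
    out <- data.frame(time = as.numeric(raw$time),
                      event = as.integer(raw$event),
                      expression = as.numeric(raw$expression))
    if ("patient" %in% colnames(raw)) out <- cbind(patient = raw$patient, out)
    .validateSurvivalCohort(out)
    out
}

#' Write a record table to TSV
#'
#' Serialises a record data.frame (screen records, concordance records,
#' enrichment records, ...) as a tab-separated table with a header row and a
#' stable column order (the data.frame's own). Floating-point values are
#' written with 15 significant digits so a read-back reproduces them to
#' within one unit in the last place; `p = 1e-300` survives a round trip.
#'
#' @param records a data.frame, or a list of data.frames of one record type
#'   (identical column names), which are row-bound.
#' @param path output file path.
#' @return Invisibly, the path.
#' @seealso [readRecords()]
#' @export
writeRecords <- function(records, path) {
    if (is.list(records) && !is.data.frame(records)) {
        if (length(records) == 0L)
            stop("cannot infer columns from an empty record list; ",
                 "pass a zero-row data.frame instead")
        cols <- lapply(records, names)
        if (!all(vapply(cols, identical, logical(1), cols[[1L]])))
            stop("records of mixed types (differing columns) cannot be ",
                 "written to one table")
        records <- do.call(rbind, records)
    }
    stopifnot(is.data.frame(records))
    out <- records
    for (j in seq_along(out)) {
        if (is.double(out[[j]])) {
            formatted <- sprintf("%.15g", out[[j]])
            formatted[is.na(out[[j]])] <- "NA"
            out[[j]] <- formatted
        }
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read back a record table written by [writeRecords()]
#'
#' @param path path to the TSV file.
#' @return A data.frame with numeric columns restored.
#' @export
readRecords <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = "")
}

#' Write a matrix container to CSV/TSV
#'
#' Inverse of [loadMatrix()]: writes the canonical lines-by-genes matrix
#' with the label column first.
#'
#' @param x a [LineGeneMatrix-class] derivative.
#' @param path output path.
#' @param delim `","` or `"\t"`.
#' @return Invisibly, the path.
#' @export
writeMatrix <- function(x, path, delim = ",") {
    v <- as.matrix(x)
    df <- data.frame(line = rownames(v), check.names = FALSE,
                     stringsAsFactors = FALSE)
    body <- as.data.frame(v, check.names = FALSE)
    for (j in seq_along(body)) {
        formatted <- sprintf("%.15g", body[[j]])
        formatted[is.na(body[[j]])] <- ""
        body[[j]] <- formatted
    }
    df <- cbind(df, body)
    utils::write.table(df, path, sep = delim, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
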