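## Expression breadth across a cell-line panel and the relative-expression
## index (focal-lineage median over panel-wide median).

#' Fraction of cell lines expressing a gene above a threshold
#'
#' The breadth of expression: the fraction of lines (with a present value)
#' whose log2(TPM+1) value strictly exceeds the threshold. Ties at the
#' cutoff count as not expressed. Common cutoffs are 1 (TPM > 1) and the
#' stricter 2 (TPM > 3) used to exclude very low-expressing genes.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param gene gene id (full label or unique symbol).
#' @param threshold cutoff on the log2(TPM+1) scale (default 1).
#' @return The fraction in \[0, 1\].
#' @export
expressionBreadth <- function(expr, gene, threshold = 1) {
    stopifnot(is(expr, "ExpressionMatrix"))
    v <- as.matrix(expr)[, .resolveGene(expr, gene)]
    v <- v[!is.na(v)]
    if (length(v) == 0L)
        stop("gene '", gene, "' has no present expression values")
    mean(v > threshold)
}

#' Relative expression index of a gene in a focal lineage
#'
#' The ratio between the median expression of the gene in the focal
#' lineage's cell lines and its median over all lines of the panel,
#' computed on the matrix's stored log2(TPM+1) scale by default
#' (`linear = TRUE` takes medians of `2^value - 1`, i.e. TPM). An index
#' above 1 means the gene is relatively overexpressed where it matters;
#' the result carries `attr(, "undefined") = TRUE` when the panel-wide
#' median is 0.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param ann a [LineageAnnotation-class].
#' @param gene gene id.
#' @param lineage focal lineage label.
#' @param linear compute medians on the linear TPM scale instead.
#' @return The ratio (with attribute `undefined` when the denominator is 0).
#' @export
relativeExpressionIndex <- function(expr, ann, gene, lineage,
                                    linear = FALSE) {
    stopifnot(is(expr, "ExpressionMatrix"), is(ann, "LineageAnnotation"))
    v <- as.matrix(expr)[, .resolveGene(expr, gene)]
    inLines <- intersect(linesOf(ann, lineage), names(v))
    if (length(inLines) == 0L)
        stop("no lines of lineage '", lineage, "' in the expression matrix")
    if (linear) v <- 2^v - 1
    num <- stats::median(v[inLines], na.rm = TRUE)
    den <- stats::median(v, na.rm = TRUE)
    if (is.na(den) || den == 0)
        return(structure(NA_real_, undefined = TRUE))
    num / den
}

#' Summarise expression breadth and relative expression for a gene set
#'
#' One record per (gene, focal lineage) pair: breadths at the two standard
#' cutoffs plus the relative expression index.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param ann a [LineageAnnotation-class].
#' @param genes character vector of gene ids.
#' @param lineage focal lineage label, recycled across genes if length one.
#' @param thresholds two log2(TPM+1) cutoffs (default `c(1, 2)`).
#' @param linear passed to [relativeExpressionIndex()].
#' @return A data.frame with columns `gene`, `focal_lineage`, `breadth_t1`,
#'   `breadth_t2`, `rel_index`.
#' @export
expressionSummary <- function(expr, ann, genes, lineage,
                              thresholds = c(1, 2), linear = FALSE) {
    stopifnot(length(thresholds) == 2L)
    if (length(lineage) == 1L) lineage <- rep(lineage, length(genes))
    stopifnot(length(lineage) == length(genes))
    rows <- lapply(seq_along(genes), function(i) {
        ri <- relativeExpressionIndex(expr, ann, genes[i], lineage[i],
                                      linear = linear)
        data.frame(gene = genes[i],
                   focal_lineage = lineage[i],
                   breadth_t1 = expressionBreadth(expr, genes[i],
                                                  thresholds[1L]),
                   breadth_t2 = expressionBreadth(expr, genes[i],
                                                  thresholds[2L]),
                   rel_index = as.numeric(ri),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
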