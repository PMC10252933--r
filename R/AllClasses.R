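#' @import methods
NULL

## Central data containers. All matrix classes store values in the canonical
## lines-by-genes orientation (rows = cell lines, columns = genes); readers
## convert at the boundary. Missing values are plain NA, never sentinels.

.checkDimnames <- function(m) {
    msgs <- character()
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("matrix must carry both row (cell line) and column (gene) labels")
    if (anyDuplicated(rownames(m)))
        msgs <- c(msgs, paste0("duplicate cell-line labels: ",
                               paste(unique(rownames(m)[duplicated(rownames(m))]),
                                     collapse = ", ")))
    if (anyDuplicated(colnames(m)))
        msgs <- c(msgs, paste0("duplicate gene labels: ",
                               paste(unique(colnames(m)[duplicated(colnames(m))]),
                                     collapse = ", ")))
    msgs
}

#' Virtual parent of line-by-gene matrix containers
#'
#' Common machinery for [GeneEffectMatrix-class],
#' [DependencyProbabilityMatrix-class] and [ExpressionMatrix-class]: a numeric
#' matrix with unique cell-line row labels and unique gene column labels, in
#' which any present value must be finite and `NA` marks a missing
#' measurement.
#'
#' @slot values numeric matrix, rows = cell lines, columns = genes.
#' @keywords classes
setClass("LineGeneMatrix",
         representation("VIRTUAL", values = "matrix"),
         validity = function(object) {
    m <- object@values
    msgs <- .checkDimnames(m)
    if (!is.numeric(m))
        msgs <- c(msgs, "values must be numeric")
    else if (any(is.infinite(m) | is.nan(m)))
        msgs <- c(msgs, "present values must be finite")
    if (length(msgs)) msgs else TRUE
})

#' Gene-effect matrix from a knockout or knockdown screen
#'
#' Per-line, per-gene essentiality scores on the Chronos/DEMETER2 scale:
#' 0 is the behaviour of a non-essential gene and -1 the median of common
#' essential genes; strongly negative scores mark lines whose viability
#' depends on the gene. The `platform` tag records whether the scores come
#' from a CRISPR knockout or an RNAi knockdown screen.
#'
#' @slot values numeric matrix (lines x genes) of gene-effect scores.
#' @slot platform `"crispr"` or `"rnai"`.
#' @seealso [GeneEffectMatrix()], [screenAll()], [loadMatrix()]
#' @keywords classes
#' @export
setClass("GeneEffectMatrix",
         contains = "LineGeneMatrix",
         representation(platform = "character"),
         validity = function(object) {
    if (length(object@platform) != 1L ||
        !object@platform %in% c("crispr", "rnai"))
        return("platform must be one of 'crispr', 'rnai'")
    TRUE
})

#' Dependency-probability matrix
#'
#' Per-line, per-gene probability that the line depends on the gene for
#' viability. Values lie in \[0, 1\]; `NA` marks missing measurements.
#'
#' @slot values numeric matrix (lines x genes) of probabilities.
#' @seealso [callDependency()], [DependencyProbabilityMatrix()]
#' @keywords classes
#' @export
setClass("DependencyProbabilityMatrix",
         contains = "LineGeneMatrix",
         validity = function(object) {
    v <- object@values
    if (any(v < 0 | v > 1, na.rm = TRUE))
        return("probabilities must lie in [0, 1]")
    TRUE
})

#' Expression matrix in log2(TPM+1) units
#'
#' Cell-line by gene expression on the log2(TPM+1) scale; all present values
#' are nonnegative.
#'
#' @slot values numeric matrix (lines x genes), log2(TPM+1).
#' @seealso [expressionBreadth()], [relativeExpressionIndex()]
#' @keywords classes
#' @export
setClass("ExpressionMatrix",
         contains = "LineGeneMatrix",
         validity = function(object) {
    if (any(object@values < 0, na.rm = TRUE))
        return("log2(TPM+1) values must be nonnegative")
    TRUE
})

#' Cell-line lineage annotation
#'
#' Maps every cell line to exactly one lineage (tumor type) label.
#'
#' @slot map named character vector: names are cell-line ids, values are
#'   lineage labels.
#' @seealso [LineageAnnotation()], [loadLineageAnnotation()]
#' @keywords classes
#' @export
setClass("LineageAnnotation",
         representation(map = "character"),
         validity = function(object) {
    m <- object@map
    msgs <- character()
    if (length(m) == 0L)
        msgs <- c(msgs, "annotation is empty")
    if (is.null(names(m)) || any(!nzchar(names(m))))
        msgs <- c(msgs, "every entry must be named by a cell-line id")
    if (anyDuplicated(names(m)))
        msgs <- c(msgs, paste0("cell line mapped more than once: ",
                               paste(unique(names(m)[duplicated(names(m))]),
                                     collapse = ", ")))
    if (anyNA(m) || any(!nzchar(m)))
        msgs <- c(msgs, "lineage labels must be non-missing and nonempty")
    if (length(msgs)) msgs else TRUE
})

#' Gene-to-category annotation table
#'
#' A set of (gene, category) pairs - GO-like terms, pathway labels or
#' DNA-binding motif classes - together with the background gene universe
#' against which enrichment is assessed. Every annotated gene must belong to
#' the background.
#'
#' @slot pairs data.frame with character columns `gene` and `category`,
#'   one pair per row, deduplicated.
#' @slot background character vector of all universe gene ids.
#' @seealso [AnnotationTable()], [categoryEnrichment()],
#'   [motifClassRepresentation()]
#' @keywords classes
#' @export
setClass("AnnotationTable",
         representation(pairs = "data.frame", background = "character"),
         validity = function(object) {
    p <- object@pairs
    msgs <- character()
    if (!all(c("gene", "category") %in% names(p)))
        msgs <- c(msgs, "pairs must have columns 'gene' and 'category'")
    if (anyDuplicated(object@background))
        msgs <- c(msgs, "background universe contains duplicates")
    if (all(c("gene", "category") %in% names(p))) {
        missing <- setdiff(unique(p$gene), object@background)
        if (length(missing))
            msgs <- c(msgs, paste0("annotated genes outside the background: ",
                                   paste(utils::head(missing, 5),
                                         collapse = ", ")))
    }
    if (length(msgs)) msgs else TRUE
})
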