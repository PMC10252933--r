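## Constructors, accessors and show methods for the S4 containers.

.asLabelledMatrix <- function(values) {
    if (is.data.frame(values)) values <- as.matrix(values)
    storage.mode(values) <- "double"
    values
}

#' Construct a gene-effect matrix
#'
#' @param values numeric matrix in lines-by-genes orientation with cell-line
#'   row names and gene column names. Gene labels may be plain symbols or the
#'   portal-export form `"SYMBOL (1234)"`; the full label is the gene's
#'   identity and [geneSymbols()] exposes the parsed symbol as a view.
#' @param platform `"crispr"` or `"rnai"`.
#' @return A [GeneEffectMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("ACH-", 1:3), c("MYB (4602)", "TP53")))
#' ge <- GeneEffectMatrix(m, platform = "crispr")
#' geneSymbols(ge)
#' @export
GeneEffectMatrix <- function(values, platform = c("crispr", "rnai")) {
    platform <- match.arg(platform)
    new("GeneEffectMatrix", values = .asLabelledMatrix(values),
        platform = platform)
}

#' Construct a dependency-probability matrix
#'
#' @param values numeric matrix in lines-by-genes orientation, values in
#'   \[0, 1\], `NA` allowed.
#' @return A [DependencyProbabilityMatrix-class] object.
#' @export
DependencyProbabilityMatrix <- function(values) {
    new("DependencyProbabilityMatrix", values = .asLabelledMatrix(values))
}

#' Construct an expression matrix
#'
#' @param values numeric matrix in lines-by-genes orientation, log2(TPM+1)
#'   units, nonnegative.
#' @return An [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(values) {
    new("ExpressionMatrix", values = .asLabelledMatrix(values))
}

#' Construct a lineage annotation
#'
#' @param lines character vector of cell-line ids, or a named character
#'   vector (names = lines, values = lineages) if `lineage` is missing.
#' @param lineage character vector of lineage labels, recycled against
#'   `lines` if of length one.
#' @return A [LineageAnnotation-class] object.
#' @examples
#' ann <- LineageAnnotation(c("L1", "L2", "L3"), c("AML", "AML", "skin"))
#' lineageSizes(ann)
#' @export
LineageAnnotation <- function(lines, lineage) {
    if (missing(lineage)) {
        map <- lines
    } else {
        if (length(lineage) == 1L) lineage <- rep(lineage, length(lines))
        map <- stats::setNames(as.character(lineage), as.character(lines))
    }
    new("LineageAnnotation", map = map)
}

#' Construct a gene-to-category annotation table
#'
#' @param gene character vector of gene ids (one per pair).
#' @param category character vector of category labels, parallel to `gene`.
#' @param background character vector of universe gene ids; defaults to the
#'   annotated genes themselves (the annotated-genome convention).
#' @return An [AnnotationTable-class] object.
#' @export
AnnotationTable <- function(gene, category, background = NULL) {
    pairs <- unique(data.frame(gene = as.character(gene),
                               category = as.character(category),
                               stringsAsFactors = FALSE))
    if (is.null(background)) background <- unique(pairs$gene)
    new("AnnotationTable", pairs = pairs,
        background = unique(as.character(background)))
}

## ---- accessors --------------------------------------------------------

#' Cell-line identifiers of a matrix container
#' @param x a [LineGeneMatrix-class] derivative.
#' @return Character vector of cell-line ids (matrix rows).
#' @export
setMethod("lineIDs", "LineGeneMatrix", function(x) rownames(x@values))

#' Gene identifiers of a matrix container
#' @param x a [LineGeneMatrix-class] derivative.
#' @return Character vector of full gene labels (matrix columns).
#' @export
setMethod("geneIDs", "LineGeneMatrix", function(x) colnames(x@values))

#' Parsed gene symbols
#'
#' Portal exports label genes as `"SYMBOL (numeric-id)"`. The full label is
#' the gene's identity throughout the package; this accessor is a parsed
#' view that strips the trailing parenthesised id.
#'
#' @param x a [LineGeneMatrix-class] derivative.
#' @return Character vector of bare symbols, parallel to [geneIDs()].
#' @export
setMethod("geneSymbols", "LineGeneMatrix",
          function(x) parseGeneSymbol(geneIDs(x)))

#' Parse portal-style gene labels to bare symbols
#'
#' @param ids character vector of labels such as `"MYB (4602)"`.
#' @return The symbols with any trailing `" (id)"` suffix removed.
#' @examples
#' parseGeneSymbol(c("MYB (4602)", "TP53"))
#' @export
parseGeneSymbol <- function(ids) sub("[ ]*\\([^()]*\\)$", "", ids)

#' Screen platform of a gene-effect matrix
#' @param x a [GeneEffectMatrix-class].
#' @return `"crispr"` or `"rnai"`.
#' @export
setMethod("platform", "GeneEffectMatrix", function(x) x@platform)

#' @describeIn GeneEffectMatrix extract the underlying numeric matrix
#'   (lines x genes).
#' @param x,... see base [as.matrix()].
#' @export
setMethod("as.matrix", "LineGeneMatrix", function(x, ...) x@values)

#' @export
setMethod("dim", "LineGeneMatrix", function(x) dim(x@values))

#' Lineage annotation accessors
#'
#' @param x a [LineageAnnotation-class].
#' @param lineage a lineage label.
#' @param line a cell-line id.
#' @return `lineages()`: sorted unique lineage labels. `lineageSizes()`:
#'   named integer vector of lines per lineage. `linesOf()`: the cell lines
#'   of one lineage. `lineageOf()`: the lineage of one or more lines (`NA`
#'   for unannotated lines).
#' @name lineages
NULL

#' @rdname lineages
#' @export
setMethod("lineages", "LineageAnnotation",
          function(x) sort(unique(unname(x@map))))

#' @rdname lineages
#' @export
setMethod("lineageSizes", "LineageAnnotation", function(x) {
    tab <- table(unname(x@map))
    stats::setNames(as.integer(tab), names(tab))
})

#' @rdname lineages
#' @export
setMethod("linesOf", "LineageAnnotation", function(x, lineage) {
    if (!lineage %in% x@map)
        stop("lineage not found in annotation: ", lineage)
    names(x@map)[x@map == lineage]
})

#' @rdname lineages
#' @export
setMethod("lineageOf", "LineageAnnotation", function(x, line) {
    unname(x@map[line])
})

#' @export
setMethod("length", "LineageAnnotation", function(x) length(x@map))

#' Annotation-table accessors
#'
#' @param x an [AnnotationTable-class].
#' @param gene a gene id.
#' @param category a category label.
#' @return `background()`: the universe gene ids. `categories()`: sorted
#'   unique category labels. `categoriesOf()`: categories annotated to one
#'   gene. `genesOf()`: genes carrying one category.
#' @name annotation-accessors
NULL

#' @rdname annotation-accessors
#' @export
setMethod("background", "AnnotationTable", function(x) x@background)

#' @rdname annotation-accessors
#' @export
setMethod("categories", "AnnotationTable",
          function(x) sort(unique(x@pairs$category)))

#' @rdname annotation-accessors
#' @export
setMethod("categoriesOf", "AnnotationTable", function(x, gene) {
    sort(unique(x@pairs$category[x@pairs$gene %in% gene]))
})

#' @rdname annotation-accessors
#' @export
setMethod("genesOf", "AnnotationTable", function(x, category) {
    sort(unique(x@pairs$gene[x@pairs$category %in% category]))
})

## ---- show -------------------------------------------------------------

.showMatrix <- function(object, what) {
    v <- object@values
    cat(what, ": ", nrow(v), " cell lines x ", ncol(v), " genes\n", sep = "")
    cat("  lines: ", paste(utils::head(rownames(v), 3), collapse = ", "),
        if (nrow(v) > 3) ", ..." else "", "\n", sep = "")
    cat("  genes: ", paste(utils::head(colnames(v), 3), collapse = ", "),
        if (ncol(v) > 3) ", ..." else "", "\n", sep = "")
    nmiss <- sum(is.na(v))
    if (nmiss > 0) cat("  missing values: ", nmiss, "\n", sep = "")
}

setMethod("show", "GeneEffectMatrix", function(object) {
    .showMatrix(object, paste0("GeneEffectMatrix [", object@platform, "]"))
})

setMethod("show", "DependencyProbabilityMatrix", function(object) {
    .showMatrix(object, "DependencyProbabilityMatrix")
})

setMethod("show", "ExpressionMatrix", function(object) {
    .showMatrix(object, "ExpressionMatrix [log2(TPM+1)]")
})

setMethod("show", "LineageAnnotation", function(object) {
    sz <- lineageSizes(object)
    cat("LineageAnnotation: ", length(object@map), " cell lines, ",
        length(sz), " lineages\n", sep = "")
    cat("  ", paste(sprintf("%s (%d)", names(sz), sz), collapse = ", "),
        "\n", sep = "")
})

setMethod("show", "AnnotationTable", function(object) {
    cat("AnnotationTable: ", nrow(object@pairs), " gene-category pairs, ",
        length(unique(object@pairs$category)), " categories, background of ",
        length(object@background), " genes\n", sep = "")
})

## Resolve a user-supplied gene to one matrix column: exact full-label match
## first, then unique symbol match.
.resolveGene <- function(x, gene) {
    ids <- geneIDs(x)
    hit <- which(ids == gene)
    if (length(hit) == 1L) return(hit)
    sym <- parseGeneSymbol(ids)
    hit <- which(sym == gene)
    if (length(hit) == 1L) return(hit)
    if (length(hit) > 1L)
        stop("gene symbol '", gene, "' is ambiguous: ",
             paste(ids[hit], collapse = ", "))
    stop("gene not found in matrix: ", gene)
}
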