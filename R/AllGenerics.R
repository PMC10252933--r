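#' @rdname lineIDs
#' @export
setGeneric("lineIDs", function(x) standardGeneric("lineIDs"))

#' @rdname geneIDs
#' @export
setGeneric("geneIDs", function(x) standardGeneric("geneIDs"))

#' @rdname geneSymbols
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname platform
#' @export
setGeneric("platform", function(x) standardGeneric("platform"))

#' @rdname lineages
#' @export
setGeneric("lineages", function(x) standardGeneric("lineages"))

#' @rdname lineages
#' @export
setGeneric("lineageSizes", function(x) standardGeneric("lineageSizes"))

#' @rdname lineages
#' @export
setGeneric("linesOf", function(x, lineage) standardGeneric("linesOf"))

#' @rdname lineages
#' @export
setGeneric("lineageOf", function(x, line) standardGeneric("lineageOf"))

#' @rdname annotation-accessors
#' @export
setGeneric("background", function(x) standardGeneric("background"))

#' @rdname annotation-accessors
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' @rdname annotation-accessors
#' @export
setGeneric("categoriesOf", function(x, gene) standardGeneric("categoriesOf"))

#' @rdname annotation-accessors
#' @export
setGeneric("genesOf", function(x, category) standardGeneric("genesOf"))
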