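## Category overrepresentation of a study gene set against a background
## universe: Fisher's exact test per category, fold enrichment
## (observed / expected), Benjamini-Hochberg FDR, and the DNA-binding
## motif-class representation summary.

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Sums hypergeometric probabilities, at fixed margins, of every table at
#' most as probable as the observed one (the minimum-likelihood two-sided
#' convention, with a relative tie tolerance of 1e-7).
#'
#' @param a,b,c,d nonnegative integer cell counts, row-wise:
#'   `matrix(c(a, b, c, d), 2, byrow = TRUE)`.
#' @return The two-sided p-value.
#' @examples
#' fisherExact2x2(3, 1, 1, 3)  # 34/70
#' @export
fisherExact2x2 <- function(a, b, c, d) {
    counts <- c(a, b, c, d)
    if (any(is.na(counts)) || any(counts < 0) ||
        any(counts != round(counts)))
        stop("cell counts must be nonnegative integers")
    stats::fisher.test(matrix(as.integer(counts), nrow = 2L,
                              byrow = TRUE))$p.value
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in the sorted order, capped at 1 and
#' returned in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as `p`.
#' @export
bhFdr <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Category overrepresentation of a study gene set
#'
#' For every category with at least `minBackground` background genes (plus
#' any category hit by the study set), builds the 2x2 table of study /
#' non-study by in-category / out-of-category over the annotation's
#' background universe, tests it with [fisherExact2x2()], and reports the
#' fold enrichment `observed / expected` where
#' `expected = n_study_total * n_bg / n_bg_total`. P-values are BH-adjusted
#' across all tested categories. Study genes outside the background are
#' dropped with a warning.
#'
#' @param study character vector of study gene ids.
#' @param annotation an [AnnotationTable-class].
#' @param minBackground minimum background count for a category to be
#'   tested (default 2; smaller categories give degenerate tables).
#' @return A data.frame ordered by raw p with columns `category`,
#'   `n_study`, `n_study_total`, `n_bg`, `n_bg_total`, `expected`,
#'   `fold_enrichment`, `p_raw`, `fdr`.
#' @export
categoryEnrichment <- function(study, annotation, minBackground = 2L) {
    stopifnot(is(annotation, "AnnotationTable"))
    study <- unique(as.character(study))
    if (length(study) == 0L) stop("study set is empty")
    bg <- background(annotation)
    outside <- setdiff(study, bg)
    if (length(outside)) {
        warning("dropping ", length(outside),
                " study genes outside the background universe: ",
                paste(utils::head(outside, 5), collapse = ", "))
        study <- setdiff(study, outside)
    }
    if (length(study) == 0L) stop("no study genes left inside the background")
    nStudy <- length(study)
    nBgTotal <- length(bg)
    pairs <- annotation@pairs
    catSizes <- table(pairs$category)
    studyHits <- table(pairs$category[pairs$gene %in% study])
    test <- names(catSizes)[catSizes >= minBackground |
                            names(catSizes) %in% names(studyHits)]
    if (length(test) == 0L)
        return(data.frame(category = character(), n_study = integer(),
                          n_study_total = integer(), n_bg = integer(),
                          n_bg_total = integer(), expected = numeric(),
                          fold_enrichment = numeric(), p_raw = numeric(),
                          fdr = numeric(), stringsAsFactors = FALSE))
    rows <- lapply(test, function(cat) {
        nBg <- as.integer(catSizes[cat])
        nHit <- if (cat %in% names(studyHits))
                    as.integer(studyHits[cat]) else 0L
        expected <- nStudy * nBg / nBgTotal
        p <- fisherExact2x2(nHit, nStudy - nHit,
                            nBg - nHit, (nBgTotal - nBg) - (nStudy - nHit))
        data.frame(category = cat, n_study = nHit, n_study_total = nStudy,
                   n_bg = nBg, n_bg_total = nBgTotal, expected = expected,
                   fold_enrichment = nHit / expected, p_raw = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$fdr <- bhFdr(out$p_raw)
    out <- out[order(out$p_raw, out$category), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' DNA-binding motif-class representation of a gene set
#'
#' For each motif class in the annotation, reports how many study genes
#' carry it, the percentage of the study set that represents, and the
#' percentage of all background genes carrying the class that the study
#' genes account for - the framing behind observations like "18 study
#' proteins have the HTH domain, yet that is only 4.4% of all HTH
#' proteins".
#'
#' @param study character vector of study gene ids.
#' @param annotation an [AnnotationTable-class] of motif classes.
#' @return A data.frame with columns `motif_class`, `n_study_in_class`,
#'   `pct_of_study`, `n_class_total`, `pct_of_class`, plus attributes
#'   `classes_hit` and `classes_total`.
#' @export
motifClassRepresentation <- function(study, annotation) {
    stopifnot(is(annotation, "AnnotationTable"))
    study <- unique(as.character(study))
    cls <- categories(annotation)
    if (length(cls) == 0L) stop("motif annotation is empty")
    rows <- lapply(cls, function(cl) {
        members <- genesOf(annotation, cl)
        nIn <- length(intersect(study, members))
        data.frame(motif_class = cl,
                   n_study_in_class = nIn,
                   pct_of_study = 100 * nIn / max(length(study), 1L),
                   n_class_total = length(members),
                   pct_of_class = 100 * nIn / length(members),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(-out$n_study_in_class, out$motif_class), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "classes_hit") <- sum(out$n_study_in_class > 0L)
    attr(out, "classes_total") <- length(cls)
    out
}
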