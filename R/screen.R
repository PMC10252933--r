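## Core screening statistic: one-vs-rest two-sample T-statistics over a
## gene-effect matrix, computed column-wise with per-gene missing-value
## handling, plus top-k selection per lineage.

## Column-wise count/mean/variance with NA removal. Columns are centred by
## their overall mean before the moment sums, which keeps the computation
## well-conditioned and makes the statistic location-equivariant to within
## rounding.
.colMoments <- function(M) {
    ok <- !is.na(M)
    n <- colSums(ok)
    M0 <- M
    M0[!ok] <- 0
    s <- colSums(M0)
    m <- ifelse(n > 0, s / n, NA_real_)
    ss <- colSums(M0 * M0)
    v <- ifelse(n > 1, (ss - n * m^2) / (n - 1), NA_real_)
    v <- pmax(v, 0)
    list(n = n, mean = m, var = v)
}

## Vectorised two-sample t over all columns of V, contrasting rows in
## `inRows` against the rest. Returns per-gene t, two-sided p, df, group
## means and sizes; genes with fewer than minGroup present values in either
## group get NA statistics.
.groupTStats <- function(V, inRows, pooled = TRUE, minGroup = 2L) {
    center <- colMeans(V, na.rm = TRUE)
    center[is.nan(center)] <- 0
    Vc <- sweep(V, 2L, center, "-")
    A <- .colMoments(Vc[inRows, , drop = FALSE])
    B <- .colMoments(Vc[!inRows, , drop = FALSE])
    eligible <- A$n >= minGroup & B$n >= minGroup
    d <- A$mean - B$mean
    if (pooled) {
        df <- A$n + B$n - 2
        sp2 <- ((A$n - 1) * A$var + (B$n - 1) * B$var) / df
        se <- sqrt(sp2 * (1 / A$n + 1 / B$n))
    } else {
        w1 <- A$var / A$n
        w2 <- B$var / B$n
        se <- sqrt(w1 + w2)
        df <- (w1 + w2)^2 / (w1^2 / (A$n - 1) + w2^2 / (B$n - 1))
    }
    t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
    ## zero pooled variance with equal means: t = 0, p = 1 by convention
    df[se == 0 & d == 0] <- 1
    p <- 2 * stats::pt(-abs(t), df)
    p[is.infinite(t)] <- 0
    t[!eligible] <- NA_real_
    p[!eligible] <- NA_real_
    list(t = t, p = p, df = df,
         meanIn = A$mean + center, meanOut = B$mean + center,
         nIn = A$n, nOut = B$n, eligible = eligible)
}

#' Two-sample T-statistic of gene-effect difference
#'
#' The screening statistic: a two-sample t contrasting the gene effects of a
#' focal group of cell lines against the rest. By default it is the
#' equal-variance (Student) statistic with `na + nb - 2` degrees of freedom,
#' the pooled-variance convention of the standard independent-samples t
#' routine; `pooled = FALSE` gives Welch's statistic with Satterthwaite
#' degrees of freedom. Strongly negative values mark genes whose knockout is
#' selectively lethal in the focal group.
#'
#' @param a numeric vector of gene effects in the focal group (NA dropped).
#' @param b numeric vector of gene effects in the comparison group.
#' @param pooled logical; pooled-variance Student t (default) or Welch.
#' @return A list with elements `t`, `p` (two-sided), `df`, `meanA`,
#'   `meanB`, `nA`, `nB`.
#' @details Groups with fewer than two present values are an error at this
#'   level (the matrix-level screen skips such genes instead). If both
#'   groups are constant and equal the statistic is 0 with p = 1 and a
#'   warning; if both are constant but unequal, t is signed infinite with
#'   p = 0.
#' @examples
#' twoSampleT(c(-1, -0.9, -1.1), c(0, 0.1, -0.1))
#' @export
twoSampleT <- function(a, b, pooled = TRUE) {
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least two present values")
    V <- matrix(c(a, b), ncol = 1L)
    res <- .groupTStats(V, seq_along(c(a, b)) <= length(a), pooled = pooled)
    if (res$t[1L] == 0 && stats::var(a) == 0 && stats::var(b) == 0)
        warning("both groups constant and equal; t = 0, p = 1 by convention")
    list(t = unname(res$t[1L]), p = unname(res$p[1L]),
         df = unname(res$df[1L]),
         meanA = unname(res$meanIn[1L]), meanB = unname(res$meanOut[1L]),
         nA = length(a), nB = length(b))
}

#' Screen one lineage for differentially essential genes
#'
#' For every gene with sufficient data, contrasts the gene effects of the
#' focal lineage's cell lines against all other lines in the matrix
#' (one-vs-rest) with [twoSampleT()], dropping missing values per group.
#' Genes are ranked by ascending T-statistic - the most negative first, i.e.
#' the genes whose loss most selectively kills the lineage - with ties
#' broken lexicographically by gene label, and the `k` top-ranked records
#' are returned.
#'
#' @param effects a [GeneEffectMatrix-class].
#' @param ann a [LineageAnnotation-class]; lines absent from the annotation
#'   still count as part of the "rest" group.
#' @param lineage focal lineage label.
#' @param k number of top genes to return (default 5).
#' @param minGroup minimum present values per group for a gene to be tested
#'   (default 2); undersized genes are skipped, not errors.
#' @param pooled passed to [twoSampleT()].
#' @return A data.frame of screen records with columns `gene`, `lineage`,
#'   `t_statistic`, `p_value`, `mean_in`, `mean_out`, `n_in`, `n_out`,
#'   `rank`. Skipped gene labels are kept in `attr(, "skipped")`.
#' @examples
#' sim <- simulateScreenDataset(syntheticConfig(
#'     nGenes = 50, nLines = 40, lineages = c(AML = 10, skin = 10),
#'     seed = 1))
#' screenLineage(sim$effects, sim$lineages, "AML", k = 5)
#' @export
screenLineage <- function(effects, ann, lineage, k = 5L, minGroup = 2L,
                          pooled = TRUE) {
    stopifnot(is(effects, "GeneEffectMatrix"), is(ann, "LineageAnnotation"))
    if (!lineage %in% ann@map)
        stop("lineage not found in annotation: ", lineage)
    V <- as.matrix(effects)
    inRows <- rownames(V) %in% linesOf(ann, lineage)
    if (sum(inRows) < minGroup)
        stop("lineage '", lineage, "' has fewer than ", minGroup,
             " lines in the matrix")
    if (sum(!inRows) < minGroup)
        stop("fewer than ", minGroup, " lines outside lineage '", lineage, "'")
    st <- .groupTStats(V, inRows, pooled = pooled, minGroup = minGroup)
    genes <- colnames(V)
    keep <- which(st$eligible)
    if (length(keep) == 0L) {
        warning("all genes skipped for lineage '", lineage, "'")
        out <- data.frame(gene = character(), lineage = character(),
                          t_statistic = numeric(), p_value = numeric(),
                          mean_in = numeric(), mean_out = numeric(),
                          n_in = integer(), n_out = integer(),
                          rank = integer(), stringsAsFactors = FALSE)
        attr(out, "skipped") <- genes
        return(out)
    }
    ord <- keep[order(st$t[keep], genes[keep], method = "radix")]
    res <- data.frame(gene = genes[ord],
                      lineage = lineage,
                      t_statistic = st$t[ord],
                      p_value = st$p[ord],
                      mean_in = st$meanIn[ord],
                      mean_out = st$meanOut[ord],
                      n_in = as.integer(st$nIn[ord]),
                      n_out = as.integer(st$nOut[ord]),
                      rank = seq_along(ord),
                      stringsAsFactors = FALSE)
    rownames(res) <- NULL
    out <- utils::head(res, k)
    attr(out, "skipped") <- genes[!st$eligible]
    out
}

#' Screen every lineage independently
#'
#' Runs [screenLineage()] once per lineage in the annotation. Because the
#' T-statistic scale depends on each lineage's size, the top-k lists are
#' selected independently per lineage rather than pooled. Lineages that
#' fail the screen's preconditions (too few lines inside or outside) are
#' reported with a warning and omitted from the result.
#'
#' @inheritParams screenLineage
#' @return A named list of screen-record data.frames (one per lineage,
#'   each as returned by [screenLineage()]), with class `"ScreenHitSet"`
#'   and attribute `k`. Use [as.data.frame()] to flatten.
#' @examples
#' sim <- simulateScreenDataset(syntheticConfig(
#'     nGenes = 50, nLines = 40, lineages = c(AML = 10, skin = 10),
#'     seed = 1))
#' st <- screenAll(sim$effects, sim$lineages, k = 3)
#' head(as.data.frame(st))
#' @export
screenAll <- function(effects, ann, k = 5L, minGroup = 2L, pooled = TRUE) {
    out <- list()
    for (lin in lineages(ann)) {
        rec <- tryCatch(
            screenLineage(effects, ann, lin, k = k, minGroup = minGroup,
                          pooled = pooled),
            error = function(e) {
                warning("lineage '", lin, "' omitted: ", conditionMessage(e),
                        call. = FALSE)
                NULL
            })
        if (!is.null(rec)) out[[lin]] <- rec
    }
    structure(out, class = c("ScreenHitSet", "list"), k = k)
}

#' @export
as.data.frame.ScreenHitSet <- function(x, ...) {
    if (length(x) == 0L)
        return(data.frame(gene = character(), lineage = character(),
                          t_statistic = numeric(), p_value = numeric(),
                          mean_in = numeric(), mean_out = numeric(),
                          n_in = integer(), n_out = integer(),
                          rank = integer(), stringsAsFactors = FALSE))
    out <- do.call(rbind, lapply(unclass(x), function(d) {
        attr(d, "skipped") <- NULL
        d
    }))
    rownames(out) <- NULL
    out
}

#' @export
print.ScreenHitSet <- function(x, ...) {
    cat("Top-", attr(x, "k"), " differential-dependency screen over ",
        length(x), " lineages\n", sep = "")
    for (lin in names(x)) {
        cat("  ", lin, ": ",
            paste(parseGeneSymbol(x[[lin]]$gene), collapse = ", "),
            "\n", sep = "")
    }
    invisible(x)
}

#' Call per-line dependency from a probability matrix
#'
#' A cell line is called dependent on a gene when its dependency probability
#' strictly exceeds the threshold (default 0.5); a probability of exactly
#' 0.5 is not a dependency call. Missing probabilities stay missing.
#'
#' Note on direction: higher probability means more likely dependent, which
#' is the portal's scale and is consistent with the gene-effect anchors
#' (score 0 = non-essential, -1 = common-essential median). Descriptions
#' that phrase the call as "probability < 0.5" invert this convention; this
#' implementation keeps the internally consistent direction.
#'
#' @param prob a [DependencyProbabilityMatrix-class].
#' @param threshold probability cutoff in \[0, 1\].
#' @return A logical matrix (lines x genes) of dependency calls, NA where
#'   the probability is missing.
#' @export
callDependency <- function(prob, threshold = 0.5) {
    stopifnot(is(prob, "DependencyProbabilityMatrix"))
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        is.na(threshold) || threshold < 0 || threshold > 1)
        stop("threshold must be a single value in [0, 1]")
    as.matrix(prob) > threshold
}
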