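## Cross-platform validation: does a CRISPR-identified lineage dependency
## replicate in the RNAi screen? A gene earns a knockdown (KD) score of 1
## when its one-vs-rest gene-effect difference on the RNAi matrix is
## negative and significant at a strict threshold (p < 0.0005, the portal's
## confidence convention); results are summarised by the external per-gene
## prediction-accuracy group of the RNAi data.

#' RNAi knockdown score for one gene in one lineage
#'
#' Recomputes the one-vs-rest [twoSampleT()] contrast on the RNAi
#' gene-effect matrix and scores the gene 1 when the difference is negative
#' (`t < 0`) and significant (`p < alpha`, two-sided by default), 0
#' otherwise. Genes absent from the RNAi panel (the CRISPR and RNAi panels
#' cover different line sets) yield an explicit missing record, never a
#' silent drop.
#'
#' @param rnai a [GeneEffectMatrix-class] with platform `"rnai"`.
#' @param ann a [LineageAnnotation-class] for the RNAi panel.
#' @param gene gene id (full label or unique symbol).
#' @param lineage focal lineage label.
#' @param alpha significance threshold (default 0.0005).
#' @param accuracyGroup optional `"high"` / `"low"` prediction-accuracy
#'   label carried into the record.
#' @param oneSided gate on the one-sided (negative-direction) p instead of
#'   the two-sided p with a sign gate.
#' @param minGroup minimum present values per group.
#' @return A one-row data.frame with columns `gene`, `lineage`, `rnai_t`,
#'   `rnai_p`, `kd_score`, `accuracy_group`, `missing`.
#' @export
rnaiKdScore <- function(rnai, ann, gene, lineage, alpha = 0.0005,
                        accuracyGroup = NA_character_, oneSided = FALSE,
                        minGroup = 2L) {
    stopifnot(is(rnai, "GeneEffectMatrix"), is(ann, "LineageAnnotation"))
    rec <- data.frame(gene = gene, lineage = lineage,
                      rnai_t = NA_real_, rnai_p = NA_real_,
                      kd_score = NA_integer_,
                      accuracy_group = accuracyGroup,
                      missing = TRUE, stringsAsFactors = FALSE)
    col <- tryCatch(.resolveGene(rnai, gene), error = function(e) NA_integer_)
    if (is.na(col)) return(rec)
    v <- as.matrix(rnai)[, col]
    inGroup <- names(v) %in% linesOf(ann, lineage)
    a <- v[inGroup]
    b <- v[!inGroup]
    if (sum(!is.na(a)) < minGroup || sum(!is.na(b)) < minGroup) return(rec)
    tt <- suppressWarnings(twoSampleT(a, b))
    pass <- if (oneSided) {
        pOne <- if (tt$t < 0) tt$p / 2 else 1 - tt$p / 2
        pOne < alpha
    } else {
        tt$t < 0 && tt$p < alpha
    }
    rec$rnai_t <- tt$t
    rec$rnai_p <- tt$p
    rec$kd_score <- as.integer(pass)
    rec$missing <- FALSE
    rec
}

#' Score a table of screen hits against an RNAi matrix
#'
#' Convenience wrapper applying [rnaiKdScore()] to each (gene, lineage) row
#' of a screen-record table, attaching each gene's prediction-accuracy
#' group.
#'
#' @param rnai,ann as in [rnaiKdScore()].
#' @param targets data.frame with columns `gene` and `lineage` (e.g. from
#'   [as.data.frame()] on a [screenAll()] result).
#' @param accuracy named character vector mapping gene id to
#'   `"high"` / `"low"`.
#' @param ... passed to [rnaiKdScore()].
#' @return A data.frame of concordance records, one per target row.
#' @export
scoreTargets <- function(rnai, ann, targets, accuracy = NULL, ...) {
    rows <- lapply(seq_len(nrow(targets)), function(i) {
        g <- targets$gene[i]
        grp <- if (is.null(accuracy)) NA_character_
               else unname(accuracy[g])
        rnaiKdScore(rnai, ann, g, targets$lineage[i],
                    accuracyGroup = grp, ...)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Summarise knockdown concordance by prediction-accuracy group
#'
#' Counts, per accuracy group, how many scored genes pass the knockdown
#' criterion - the table behind statements like "every high-accuracy gene
#' replicated, but only 7 of 25 low-accuracy genes did". Records with a
#' missing KD score are tallied separately and excluded from the fractions.
#'
#' @param records data.frame of concordance records from [rnaiKdScore()] /
#'   [scoreTargets()].
#' @return A data.frame with one row per accuracy group and columns
#'   `accuracy_group`, `n_genes`, `n_passing`, `fraction`, `n_missing`.
#' @export
concordanceSummary <- function(records) {
    if (nrow(records) == 0L)
        return(data.frame(accuracy_group = character(), n_genes = integer(),
                          n_passing = integer(), fraction = numeric(),
                          n_missing = integer(), stringsAsFactors = FALSE))
    groups <- sort(unique(records$accuracy_group), na.last = TRUE)
    rows <- lapply(groups, function(g) {
        sel <- if (is.na(g)) is.na(records$accuracy_group)
               else !is.na(records$accuracy_group) & records$accuracy_group == g
        sub <- records[sel, , drop = FALSE]
        scored <- sub[!sub$missing, , drop = FALSE]
        n <- nrow(scored)
        npass <- sum(scored$kd_score == 1L)
        data.frame(accuracy_group = g, n_genes = n, n_passing = npass,
                   fraction = if (n > 0) npass / n else NA_real_,
                   n_missing = sum(sub$missing), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
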