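## Prognostic screening: expression-dichotomized Kaplan-Meier comparison
## with the log-rank test and the Mantel-Haenszel one-step hazard ratio.
## The one-step estimator exp((O - E) / V) keeps the statistic fully
## specified and hand-checkable, unlike a fitted proportional-hazards model.

#' Log-rank test and hazard ratio for an expression-dichotomized cohort
#'
#' Splits patients into high (`expression > cutoff`) and low
#' (`expression <= cutoff`) groups - ties at the cutoff go low - and
#' compares their survival with the standard log-rank aggregation of
#' observed minus expected events over the event times (discrete
#' tie-handling). The hazard ratio of high vs low expression is the
#' Mantel-Haenszel one-step estimate `exp((O_high - E_high) / V)`.
#' High expression with HR > 1 is labelled `adverse` (shorter survival),
#' HR < 1 `protective`.
#'
#' @param cohort data.frame with columns `time`, `event` (1 = death
#'   observed, 0 = censored) and `expression`; see
#'   [simulateSurvivalCohort()] or [loadSurvivalCohort()].
#' @param cutoffRule `"median"` (default) or `"quantile"`.
#' @param q quantile in (0, 1) when `cutoffRule = "quantile"`.
#' @param alpha significance level for the `significant` flag
#'   (default 0.01).
#' @param gene optional gene id carried into the record.
#' @param minGroup minimum patients per group (default 5); a smaller group,
#'   or a group with zero events, yields a flagged record without test or
#'   HR.
#' @return A one-row data.frame with columns `gene`, `cutoff`, `n_high`,
#'   `n_low`, `logrank_chi2`, `p_value`, `hazard_ratio`, `direction`,
#'   `significant`, `flagged`. The Kaplan-Meier step functions of both
#'   groups (a [survival::survfit()] object) are attached as
#'   `attr(, "km")`. A group with fewer than 5 patients or zero events
#'   yields a flagged record without test or HR.
#' @examples
#' co <- simulateSurvivalCohort(hrTarget = 2, n = 200, seed = 1)
#' kmLogrankHr(co)
#' @export
kmLogrankHr <- function(cohort, cutoffRule = c("median", "quantile"),
                        q = 0.5, alpha = 0.01, gene = NA_character_,
                        minGroup = 5L) {
    .validateSurvivalCohort(cohort)
    cutoffRule <- match.arg(cutoffRule)
    cutoff <- if (cutoffRule == "median") stats::median(cohort$expression)
              else stats::quantile(cohort$expression, q, names = FALSE)
    high <- cohort$expression > cutoff
    group <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
    nHigh <- sum(high)
    nLow <- sum(!high)
    base <- data.frame(gene = gene, cutoff = cutoff,
                       n_high = nHigh, n_low = nLow,
                       logrank_chi2 = NA_real_, p_value = NA_real_,
                       hazard_ratio = NA_real_,
                       direction = NA_character_, significant = NA,
                       flagged = TRUE, stringsAsFactors = FALSE)
    if (nHigh < minGroup || nLow < minGroup ||
        sum(cohort$event[high]) < 1L || sum(cohort$event[!high]) < 1L)
        return(base)
    sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                             data = cbind(cohort, group = group))
    oHigh <- sd$obs[2L]
    eHigh <- sd$exp[2L]
    v <- sd$var[1L, 1L]
    chi2 <- sd$chisq
    p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
    hr <- exp((oHigh - eHigh) / v)
    out <- base
    out$logrank_chi2 <- chi2
    out$p_value <- p
    out$hazard_ratio <- hr
    out$direction <- if (hr > 1) "adverse" else "protective"
    out$significant <- p < alpha
    out$flagged <- FALSE
    attr(out, "km") <- survival::survfit(
        survival::Surv(time, event) ~ group,
        data = cbind(cohort, group = group))
    out
}

#' Survival screen over per-gene cohorts
#'
#' Applies [kmLogrankHr()] to every cohort in a named list, one record per
#' gene, flagging results significant at `alpha`.
#'
#' @param cohorts named list of survival cohorts (names are gene ids).
#' @param alpha significance level (default 0.01).
#' @param cutoffRule,q passed to [kmLogrankHr()].
#' @return A data.frame with one row per gene (empty input gives an empty
#'   frame with the same columns).
#' @export
survivalScreen <- function(cohorts, alpha = 0.01,
                           cutoffRule = "median", q = 0.5) {
    if (length(cohorts) == 0L)
        return(data.frame(gene = character(), cutoff = numeric(),
                          n_high = integer(), n_low = integer(),
                          logrank_chi2 = numeric(), p_value = numeric(),
                          hazard_ratio = numeric(), direction = character(),
                          significant = logical(), flagged = logical(),
                          stringsAsFactors = FALSE))
    nm <- names(cohorts)
    if (is.null(nm)) nm <- sprintf("gene%d", seq_along(cohorts))
    rows <- lapply(seq_along(cohorts), function(i) {
        r <- kmLogrankHr(cohorts[[i]], cutoffRule = cutoffRule, q = q,
                         alpha = alpha, gene = nm[i])
        attr(r, "km") <- NULL
        r
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Kaplan-Meier curve coordinates for plotting
#'
#' Extracts the step-function coordinates of the two groups from a
#' [kmLogrankHr()] result.
#'
#' @param result a [kmLogrankHr()] result carrying the `km` attribute.
#' @return A data.frame with columns `group`, `time`, `surv`, `n_risk`.
#' @export
kmCurves <- function(result) {
    fit <- attr(result, "km")
    if (is.null(fit)) stop("result carries no Kaplan-Meier fit")
    groups <- rep(sub("^group=", "", names(fit$strata)),
                  times = fit$strata)
    data.frame(group = groups, time = fit$time, surv = fit$surv,
               n_risk = fit$n.risk, stringsAsFactors = FALSE)
}
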