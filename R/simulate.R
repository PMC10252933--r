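## Synthetic DepMap-like data with known ground truth. The generator
## emulates the anchors of the gene-effect scale (0 = non-essential,
## -1 = common-essential median), implants lineage-specific dependencies,
## derives dependency probabilities through a fixed logistic map, couples
## implanted-gene expression to the implant lineage, and produces a noisy
## RNAi replicate with per-gene reliability. Everything is deterministic
## given the config seed.

#' Configuration for the synthetic screen generator
#'
#' Defaults describe a mid-sized panel: 1000 genes and 200 cell lines, five
#' annotated lineages of 20 lines each (the remaining lines form an `other`
#' background lineage), 10% common-essential genes, and five implanted
#' lineage-specific dependencies per lineage at the common-essential score
#' depth of -1 with Gaussian score noise of sd 0.3.
#'
#' @param nGenes number of genes.
#' @param nLines number of cell lines.
#' @param lineages named integer vector or list of lineage sizes; sizes must
#'   sum to at most `nLines`, and leftover lines are labelled `"other"`.
#' @param fracCommonEssential fraction of genes that are common-essential
#'   (score centred at `effectCommon` in every line).
#' @param implantsPerLineage number of lineage-specific genes implanted per
#'   named lineage (score centred at `effectImplant` inside the lineage and
#'   at 0 elsewhere).
#' @param effectCommon mean score of common-essential genes (default -1).
#' @param effectImplant mean in-lineage score of implanted genes
#'   (default -1).
#' @param noiseSd standard deviation of the Gaussian score noise (> 0).
#' @param exprFoldImplant linear fold-elevation of an implanted gene's TPM
#'   inside its lineage; 1 disables the dependency-expression coupling.
#' @param rnaiReliabilityHigh,rnaiReliabilityLow per-gene reliability (a
#'   correlation-like value in \[0, 1\]) of the RNAi replicate for genes in
#'   the high / low prediction-accuracy group.
#' @param seed integer RNG seed; derived generators use documented offsets
#'   from it (the RNAi replicate draws from `seed + 1`).
#' @return A validated list of class `"SyntheticConfig"`.
#' @seealso [simulateScreenDataset()], [simulateRnaiReplicate()]
#' @export
syntheticConfig <- function(nGenes = 1000L, nLines = 200L,
                            lineages = c(lineage1 = 20L, lineage2 = 20L,
                                         lineage3 = 20L, lineage4 = 20L,
                                         lineage5 = 20L),
                            fracCommonEssential = 0.1,
                            implantsPerLineage = 5L,
                            effectCommon = -1.0,
                            effectImplant = -1.0,
                            noiseSd = 0.3,
                            exprFoldImplant = 2.0,
                            rnaiReliabilityHigh = 0.9,
                            rnaiReliabilityLow = 0.0,
                            seed = 1L) {
    lineages <- unlist(lineages)
    cfg <- list(nGenes = as.integer(nGenes), nLines = as.integer(nLines),
                lineages = lineages,
                fracCommonEssential = fracCommonEssential,
                implantsPerLineage = as.integer(implantsPerLineage),
                effectCommon = effectCommon, effectImplant = effectImplant,
                noiseSd = noiseSd, exprFoldImplant = exprFoldImplant,
                rnaiReliabilityHigh = rnaiReliabilityHigh,
                rnaiReliabilityLow = rnaiReliabilityLow,
                seed = as.integer(seed))
    if (cfg$nGenes < 1L || cfg$nLines < 2L)
        stop("need at least one gene and two lines")
    if (is.null(names(lineages)) || any(!nzchar(names(lineages))))
        stop("lineages must be a named vector of sizes")
    if ("other" %in% names(lineages))
        stop("'other' is reserved for unassigned lines")
    if (sum(lineages) > cfg$nLines)
        stop("lineage sizes sum to more than nLines")
    if (any(lineages < 1L))
        stop("every lineage must be nonempty")
    if (cfg$fracCommonEssential < 0 || cfg$fracCommonEssential > 1)
        stop("fracCommonEssential must lie in [0, 1]")
    if (cfg$noiseSd <= 0)
        stop("noiseSd must be positive")
    if (cfg$exprFoldImplant <= 0)
        stop("exprFoldImplant must be positive")
    for (r in c(cfg$rnaiReliabilityHigh, cfg$rnaiReliabilityLow))
        if (r < 0 || r > 1)
            stop("reliabilities must lie in [0, 1]")
    nCommon <- round(cfg$fracCommonEssential * cfg$nGenes)
    nImplant <- cfg$implantsPerLineage * length(lineages)
    if (nCommon + nImplant > cfg$nGenes)
        stop("more common-essential plus implanted genes than genes ",
             "available (", nCommon, " + ", nImplant, " > ", cfg$nGenes, ")")
    structure(cfg, class = "SyntheticConfig")
}

## Logistic score-to-probability map: midpoint -0.5 (halfway between the
## non-essential anchor 0 and the common-essential anchor -1), steepness 10.
.PROB_MIDPOINT <- -0.5
.PROB_STEEPNESS <- 10

#' Map gene-effect scores to dependency probabilities
#'
#' Deterministic logistic map `p = 1 / (1 + exp(s * (e - m)))` with fixed
#' midpoint `m = -0.5` and steepness `s = 10`: a score of -0.5 maps to
#' probability 0.5, the non-essential anchor 0 maps to ~0.007 and the
#' common-essential anchor -1 to ~0.993. Monotone decreasing in the score.
#'
#' @param score numeric vector or matrix of gene-effect scores.
#' @return Probabilities of dependency, same shape as `score`.
#' @export
scoreToProbability <- function(score) {
    1 / (1 + exp(.PROB_STEEPNESS * (score - .PROB_MIDPOINT)))
}

.lineageFactor <- function(cfg) {
    labels <- c(rep(names(cfg$lineages), cfg$lineages),
                rep("other", cfg$nLines - sum(cfg$lineages)))
    labels
}

#' Simulate a CRISPR screen dataset with known ground truth
#'
#' Draws a gene-effect matrix whose scores are Gaussian around class means:
#' 0 for non-essential genes everywhere, `effectCommon` for common-essential
#' genes everywhere, and `effectImplant` for each implanted lineage-specific
#' gene inside its lineage (0 outside). The dependency-probability matrix is
#' derived deterministically from the scores via [scoreToProbability()].
#' Expression is log2(TPM+1) of a lognormal TPM baseline (log-mean 1,
#' log-sd 1), with implanted genes' TPM multiplied by `exprFoldImplant`
#' inside their lineage. Genes alternate deterministically between the
#' `high` and `low` RNAi prediction-accuracy groups. All draws happen in a
#' fixed, documented order (scores, then expression) under `set.seed(seed)`,
#' so identical configs give bit-identical output.
#'
#' @param config a [syntheticConfig()].
#' @return A list with elements `effects` ([GeneEffectMatrix-class],
#'   crispr), `probability` ([DependencyProbabilityMatrix-class]),
#'   `expression` ([ExpressionMatrix-class]), `lineages`
#'   ([LineageAnnotation-class]) and `truth` - a data.frame with columns
#'   `gene`, `class` (`common_essential` / `nonessential` /
#'   `lineage_specific`), `lineage` (`NA` except for implants) and
#'   `accuracy_group` (`high` / `low`).
#' @examples
#' sim <- simulateScreenDataset(syntheticConfig(
#'     nGenes = 100, nLines = 40, lineages = c(AML = 10, skin = 10),
#'     seed = 7))
#' table(sim$truth$class)
#' @export
simulateScreenDataset <- function(config = syntheticConfig()) {
    stopifnot(inherits(config, "SyntheticConfig"))
    cfg <- config
    set.seed(cfg$seed)

    geneIds <- sprintf("GENE%04d (%d)", seq_len(cfg$nGenes),
                       seq_len(cfg$nGenes))
    lineIds <- sprintf("LINE%03d", seq_len(cfg$nLines))
    lineLineage <- .lineageFactor(cfg)

    nCommon <- round(cfg$fracCommonEssential * cfg$nGenes)
    lineageNames <- names(cfg$lineages)
    nImplant <- cfg$implantsPerLineage * length(lineageNames)
    class <- rep("nonessential", cfg$nGenes)
    implantLineage <- rep(NA_character_, cfg$nGenes)
    if (nCommon > 0) class[seq_len(nCommon)] <- "common_essential"
    if (nImplant > 0) {
        idx <- nCommon + seq_len(nImplant)
        class[idx] <- "lineage_specific"
        implantLineage[idx] <- rep(lineageNames,
                                   each = cfg$implantsPerLineage)
    }

    means <- matrix(0, cfg$nLines, cfg$nGenes,
                    dimnames = list(lineIds, geneIds))
    means[, class == "common_essential"] <- cfg$effectCommon
    for (g in which(class == "lineage_specific"))
        means[lineLineage == implantLineage[g], g] <- cfg$effectImplant

    scores <- means + matrix(stats::rnorm(cfg$nLines * cfg$nGenes,
                                          sd = cfg$noiseSd),
                             cfg$nLines, cfg$nGenes)
    dimnames(scores) <- dimnames(means)

    tpm <- matrix(stats::rlnorm(cfg$nLines * cfg$nGenes,
                                meanlog = 1, sdlog = 1),
                  cfg$nLines, cfg$nGenes, dimnames = dimnames(means))
    if (cfg$exprFoldImplant != 1) {
        for (g in which(class == "lineage_specific")) {
            rows <- lineLineage == implantLineage[g]
            tpm[rows, g] <- tpm[rows, g] * cfg$exprFoldImplant
        }
    }

    accuracy <- ifelse(seq_len(cfg$nGenes) %% 2L == 1L, "high", "low")

    list(effects = GeneEffectMatrix(scores, platform = "crispr"),
         probability = DependencyProbabilityMatrix(scoreToProbability(scores)),
         expression = ExpressionMatrix(log2(tpm + 1)),
         lineages = LineageAnnotation(lineIds, lineLineage),
         truth = data.frame(gene = geneIds, class = class,
                            lineage = implantLineage,
                            accuracy_group = accuracy,
                            stringsAsFactors = FALSE))
}

#' Simulate an RNAi replicate of a CRISPR gene-effect matrix
#'
#' Per gene, the RNAi score is `r * crispr + sqrt(1 - r^2) * N(0, noiseSd)`
#' where `r` is the gene's reliability, taken from its prediction-accuracy
#' group in the ground truth (`rnaiReliabilityHigh` / `Low` in the config).
#' With `r = 1` the RNAi column reproduces the CRISPR column exactly; with
#' `r = 0` it is independent noise, emulating genes whose knockdown fails.
#' Draws use `set.seed(config$seed + 1)` so the replicate is reproducible
#' yet independent of the primary dataset's stream.
#'
#' @param crispr a [GeneEffectMatrix-class] (platform `"crispr"`).
#' @param truth ground-truth data.frame from [simulateScreenDataset()]
#'   covering every gene of `crispr`.
#' @param config the [syntheticConfig()] used to generate the dataset.
#' @return A [GeneEffectMatrix-class] with platform `"rnai"`.
#' @export
simulateRnaiReplicate <- function(crispr, truth, config) {
    stopifnot(is(crispr, "GeneEffectMatrix"),
              inherits(config, "SyntheticConfig"))
    V <- as.matrix(crispr)
    idx <- match(colnames(V), truth$gene)
    if (anyNA(idx))
        stop("ground truth does not cover genes: ",
             paste(utils::head(colnames(V)[is.na(idx)], 5), collapse = ", "))
    r <- ifelse(truth$accuracy_group[idx] == "high",
                config$rnaiReliabilityHigh, config$rnaiReliabilityLow)
    set.seed(config$seed + 1L)
    noise <- matrix(stats::rnorm(length(V), sd = config$noiseSd),
                    nrow(V), ncol(V))
    R <- matrix(r, nrow(V), ncol(V), byrow = TRUE)
    rnai <- V * R + sqrt(1 - R^2) * noise
    dimnames(rnai) <- dimnames(V)
    GeneEffectMatrix(rnai, platform = "rnai")
}

#' Construct a tumor-vs-normal clinical expression cohort
#'
#' @param gene gene id the cohort refers to.
#' @param tumor,normal nonnegative linear-scale expression values for tumor
#'   and normal samples; both must be nonempty.
#' @return A list of class `"ClinicalCohort"` with elements `gene`, `tumor`,
#'   `normal`.
#' @seealso [foldChangeMedian()], [simulateClinicalCohort()]
#' @export
clinicalCohort <- function(gene, tumor, normal) {
    tumor <- as.numeric(tumor)
    normal <- as.numeric(normal)
    if (length(tumor) == 0L || length(normal) == 0L)
        stop("both cohorts must be nonempty")
    if (any(tumor < 0, na.rm = TRUE) || any(normal < 0, na.rm = TRUE))
        stop("expression values must be nonnegative")
    structure(list(gene = gene, tumor = tumor, normal = normal),
              class = "ClinicalCohort")
}

#' Simulate a tumor-vs-normal cohort with a target fold-change median
#'
#' Normal samples are lognormal with log-median `log(baseMedian)` and
#' log-sd `logSd`; tumor samples share the spread with the log-median
#' shifted by `log(fcMedianTarget)`, so the population fold-change median is
#' exactly the target. `zeroNormal = TRUE` sets every normal value to 0,
#' the degenerate case of a transcript below detection in normal tissue,
#' for which the fold change is undefined-infinite.
#'
#' @param gene gene id.
#' @param fcMedianTarget target ratio of median tumor to median normal
#'   expression (> 0).
#' @param nTumor,nNormal sample sizes (> 0).
#' @param logSd lognormal log-sd; the default 0.5 is a typical within-cohort
#'   biological spread on the natural-log scale.
#' @param baseMedian median normal expression on the linear scale.
#' @param zeroNormal if TRUE, normal values are all zero.
#' @param seed integer RNG seed.
#' @return A `"ClinicalCohort"` (see [clinicalCohort()]).
#' @export
simulateClinicalCohort <- function(gene = "GENE", fcMedianTarget = 1,
                                   nTumor = 200L, nNormal = 200L,
                                   logSd = 0.5, baseMedian = 10,
                                   zeroNormal = FALSE, seed = 1L) {
    if (nTumor < 1L || nNormal < 1L)
        stop("sample sizes must be positive")
    if (!zeroNormal && fcMedianTarget <= 0)
        stop("fcMedianTarget must be positive")
    set.seed(seed)
    normal <- if (zeroNormal) rep(0, nNormal)
              else stats::rlnorm(nNormal, meanlog = log(baseMedian),
                                 sdlog = logSd)
    tumor <- stats::rlnorm(nTumor,
                           meanlog = log(baseMedian) +
                               log(max(fcMedianTarget, .Machine$double.xmin)),
                           sdlog = logSd)
    clinicalCohort(gene, tumor, normal)
}

.validateSurvivalCohort <- function(df) {
    stopifnot(is.data.frame(df),
              all(c("time", "event", "expression") %in% names(df)))
    if (any(df$time < 0, na.rm = TRUE))
        stop("survival times must be nonnegative")
    if (!all(df$event %in% c(0L, 1L)))
        stop("event must be 0 (censored) or 1 (death observed)")
    invisible(df)
}

#' Simulate a survival cohort with a target hazard ratio
#'
#' Expression is standard Gaussian; event times are exponential with hazard
#' `baselineHazard * hrTarget^(expression > median)`, so the high-expression
#' half carries the target hazard ratio. Censoring, when requested, is an
#' independent exponential whose rate is tuned so the expected censored
#' fraction approximates `censorRate` (rate = mean hazard *
#' censorRate / (1 - censorRate)).
#'
#' @param hrTarget hazard ratio of the high-expression group (> 0).
#' @param n number of patients (>= 10, so a median split leaves viable
#'   groups).
#' @param censorRate target censored fraction in \[0, 1).
#' @param baselineHazard event hazard of the low-expression group.
#' @param seed integer RNG seed.
#' @return A data.frame with columns `time`, `event` (1 = death observed,
#'   0 = censored) and `expression`.
#' @seealso [kmLogrankHr()]
#' @export
simulateSurvivalCohort <- function(hrTarget = 1, n = 200L, censorRate = 0,
                                   baselineHazard = 0.1, seed = 1L) {
    if (n < 10L) stop("need at least 10 patients for a dichotomized cohort")
    if (hrTarget <= 0) stop("hrTarget must be positive")
    if (censorRate < 0 || censorRate >= 1)
        stop("censorRate must lie in [0, 1)")
    set.seed(seed)
    expr <- stats::rnorm(n)
    high <- expr > stats::median(expr)
    hazard <- baselineHazard * hrTarget^high
    tEvent <- stats::rexp(n, rate = hazard)
    if (censorRate > 0) {
        censHazard <- mean(hazard) * censorRate / (1 - censorRate)
        tCens <- stats::rexp(n, rate = censHazard)
        time <- pmin(tEvent, tCens)
        event <- as.integer(tEvent <= tCens)
    } else {
        time <- tEvent
        event <- rep(1L, n)
    }
    out <- data.frame(time = time, event = event, expression = expr)
    .validateSurvivalCohort(out)
    out
}
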