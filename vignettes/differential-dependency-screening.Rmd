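---
title: "Lineage-specific differential dependency screening with depscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lineage-specific differential dependency screening with depscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depscreen)
```

## The problem

Genome-wide knockout screens measure, for every gene in every cell line of
a panel, a *gene-effect score*: 0 means knocking the gene out leaves the
line's growth untouched (a non-essential gene), and −1 is anchored at the
median score of genes essential in essentially every line. A gene that is
dispensable in most of the panel but strongly negative in the cell lines of
one tumor lineage is a candidate lineage-specific vulnerability — a
therapeutic target whose inactivation should preferentially hurt that tumor
type.

`depscreen` implements the screening statistic for this question and the
downstream analyses such a screen feeds: expression context in the cell-line
panel, tumor-vs-normal differential expression in clinical cohorts,
replication in an independent knockdown (RNAi) platform, functional-category
enrichment of the hit list, and prognostic value of hit expression in
patient survival cohorts.

## The screening statistic

For a focal lineage $L$ and gene $g$, the package contrasts the gene-effect
scores of the lines in $L$ against **all other lines in the matrix**
(one-vs-rest) with a two-sample t statistic:

$$ T_{g,L} \;=\; \frac{\bar{x}_{g,L} - \bar{x}_{g,\bar L}}
  {s_p \sqrt{\tfrac{1}{n_L} + \tfrac{1}{n_{\bar L}}}} , \qquad
  s_p^2 = \frac{(n_L-1)s_L^2 + (n_{\bar L}-1)s_{\bar L}^2}{n_L+n_{\bar L}-2}. $$

The pooled-variance (Student) form is the default because it is the default
of the standard independent-samples t routine that panel portals use to
report the score; Welch's unequal-variance form with Satterthwaite degrees
of freedom is available via `pooled = FALSE`. Genes are ranked by ascending
signed $T$ — the most negative first — and the top `k` (default 5) per
lineage form the hit list. Selection is on the signed statistic, not the
p-value, so directionality never depends on a sidedness convention; the
two-sided p is reported alongside. Because the magnitude of $T$ grows with
lineage size, hit lists are selected *independently per lineage* and are
not comparable across lineages on the $T$ scale.

Numerical and procedural choices:

* Missing scores are dropped per gene and per group; a gene needs at least
  `minGroup` (default 2) present values on each side or it is skipped and
  reported in `attr(, "skipped")`. The low default keeps very small
  lineages (real panels contain lineages with only 4 lines) screenable.
* Columns are centred by their overall mean before the moment sums, which
  keeps the variance computation well-conditioned and makes the statistic
  location-equivariant to within rounding.
* Ties in $T$ break lexicographically on the full gene label, so output is
  deterministic and independent of column order.
* If both groups are constant with equal values, the statistic is defined
  as $T = 0$, $p = 1$ (with a warning on a direct `twoSampleT()` call); a
  zero pooled variance with unequal means gives a signed infinite $T$ with
  $p = 0$.

Dependency-probability matrices complement the scores: `callDependency()`
calls a line dependent when its probability strictly exceeds 0.5. Higher
probability meaning *more* dependent is the portal scale and the only
direction consistent with the score anchors; descriptions that phrase the
call as "probability < 0.5" invert the convention, and the documentation
flags this explicitly.

## Synthetic data: what it emulates, and what it does not

Real gene-effect panels cannot be redistributed, so the package carries a
seeded generator whose defaults define the reference conditions used
throughout the test suite: 1000 genes × 200 lines, five annotated lineages
of 20 lines each (remaining lines form an `other` background lineage), 10%
common-essential genes (about the fraction observed in real panels), five
implanted lineage-specific dependencies per lineage at the full
common-essential depth of −1, and Gaussian score noise with sd 0.3 — a
calibration choice, since screens report no simple per-entry noise model.

* **Scores**: Gaussian around class means — 0 for non-essential genes,
  `effectCommon` (−1) for common-essentials everywhere, `effectImplant`
  (−1) for an implanted gene inside its lineage and 0 outside.
* **Probabilities** derive deterministically from scores through a logistic
  map with midpoint −0.5 (halfway between the two anchors) and steepness
  10, the simplest monotone map that places 0.5 between the anchors and
  ~0.99 at the common-essential depth.
* **Expression** is log2(TPM+1) of a lognormal TPM baseline (log-mean 1,
  log-sd 1). Implanted genes have their TPM multiplied by
  `exprFoldImplant` inside their lineage, tying dependency to relative
  overexpression the way real lineage factors are relatively overexpressed
  where they matter. The default fold of 2 mirrors the typical (not
  extreme) elevation of such genes; setting it to 1 gives the
  no-association null, and large values (e.g. 50, the scale of the most
  extreme myogenic regulators) are reachable by argument.
* **The RNAi replicate** models knockdown unreliability: per gene,
  `rnai = r·crispr + sqrt(1−r²)·N(0, noiseSd)` with `r` the gene's
  reliability, 0.9 for the `high` and 0.0 for the `low`
  prediction-accuracy group by default. Genes alternate deterministically
  between groups. `r = 1` reproduces the CRISPR column exactly; `r = 0`
  severs the platforms, emulating genes whose knockdown fails.
* **Clinical cohorts** are lognormal with the tumor log-median shifted by
  `log(fcMedianTarget)`; log-sd 0.5 is a typical within-cohort biological
  spread. **Survival cohorts** have standard-Gaussian expression and
  exponential event times whose hazard is multiplied by `hrTarget` above
  the expression median, with optional independent exponential censoring
  whose rate is tuned to the requested censored fraction.

Seeding: every generator is bit-reproducible given its seed; the RNAi
replicate draws from `seed + 1` so it is reproducible yet independent of
the primary stream, and all draws inside one generator happen in a fixed
documented order (scores, then expression).

The generator deliberately omits copy-number artifacts, screen-quality
covariates, batch effects, correlated gene modules, and heavy-tailed noise.
Tests passing on this synthetic family therefore demonstrate correctness of
the statistics and recovery under idealised Gaussian/lognormal conditions —
not robustness to the full messiness of real panels.

## Downstream analyses

**Expression context.** `expressionBreadth()` is the fraction of lines
whose log2(TPM+1) value strictly exceeds a cutoff; the conventional cutoffs
1 and 2 (i.e. TPM > 1 and TPM > 3) are both plain parameters. Strict
inequality means ties at the cutoff count as not expressed.
`relativeExpressionIndex()` is the ratio of the focal-lineage median to the
panel-wide median, on the stored log scale by default; `linear = TRUE`
takes the medians on the TPM scale, which is the scale on which statements
like "50-fold higher" live. The index is undefined (flagged, not an error)
when the panel-wide median is 0.

**Tumor vs normal.** `mannWhitneyU()` counts exceedance pairs with
half-weighted ties; the exact null distribution is used automatically for
$n_1+n_2 \le 16$ without ties, otherwise the tie-corrected normal
approximation with continuity correction (both correction variants are
exposed, since portals do not state theirs). The effect measure is the
fold-change median — median(tumor)/median(normal) on the linear scale — with
an explicit undefined-infinite flag when a transcript is below detection in
normal tissue. Direction comes from the fold change, significance (default
α = 0.01) from the test, and no cross-gene adjustment is applied by default
to match per-gene portal reporting (`adjust = TRUE` adds BH).

**RNAi concordance.** A screen hit replicates when its one-vs-rest contrast
on the RNAi matrix is negative *and* significant at α = 0.0005 (the strict
portal confidence threshold), read as a sign gate on the two-sided p; a
one-sided option exists since the portal's sidedness is unstated. The
prediction-accuracy grouping is an input annotation, not something the
package estimates — it reflects an external per-gene reliability
classification. Genes absent from the RNAi panel produce explicit missing
records.

**Enrichment.** `fisherExact2x2()` uses the minimum-likelihood two-sided
convention (sum of all fixed-margin tables at most as probable as the
observed, relative tie tolerance 1e−7). Fold enrichment is
observed/expected with `expected = n_study · n_category / n_background`;
the background defaults to all annotated genes, the annotated-genome
convention, and categories with fewer than 2 background genes are skipped.
"FDR" is Benjamini–Hochberg. `motifClassRepresentation()` reports the two
complementary percentage views of a motif class: what fraction of the study
set carries it, and what fraction of all carriers the study set accounts
for.

**Survival.** Patients split at the expression median (ties go low; a
quantile option exists, but optimal-cutoff scanning is deliberately out of
scope because it requires selection-bias correction). The log-rank test
uses the standard discrete O−E/V aggregation over event times, and the
hazard ratio is the Mantel–Haenszel one-step `exp((O−E)/V)` — fully
specified, hand-checkable against a risk-set table, and exactly inverse
under a group swap, at the price of mild shrinkage relative to a fitted
proportional-hazards model at large effects. Groups below `minGroup`
patients (default 5) or without events yield flagged records.

## Verification

The test suite checks every statistic against an independently coded
brute-force oracle (reference t routine, full-enumeration Mann–Whitney,
hypergeometric-enumeration Fisher, literal step-up BH, hand risk-set
log-rank), and checks the pipeline's behaviour under the reference
synthetic conditions: implant recovery into the per-lineage top five across
100 seeds, null calibration of the p < 0.0005 negative-tail rate over two
million implant-free gene-tests, the high/low reliability split of RNAi
concordance over 20 seeds, fold-change-median recovery at targets from 0.2
to 150, survival type-I error at α = 0.01 over 2000 null cohorts, and
hazard-ratio recovery at a true HR of 2 with n = 500 over 100 seeds. These
problem sizes were chosen to make Monte-Carlo error small relative to the
assertion margins while keeping the default suite fast. The same
quantities are recomputed from scratch by `scripts/acceptance.R`.

## A worked example

```{r example}
cfg <- syntheticConfig(seed = 42)
sim <- simulateScreenDataset(cfg)
hits <- screenAll(sim$effects, sim$lineages, k = 5)
hits

head(hits$lineage1, 3)

# do the lineage1 hits replicate on the RNAi platform?
rnai <- simulateRnaiReplicate(sim$effects, sim$truth, cfg)
acc <- setNames(sim$truth$accuracy_group, sim$truth$gene)
scoreTargets(rnai, sim$lineages, hits$lineage1, accuracy = acc)[,
    c("gene", "rnai_t", "rnai_p", "kd_score", "accuracy_group")]
```

## Limitations

* The screen takes the gene-effect matrix as given; it does not re-derive
  scores from raw reagent counts, nor model copy-number or off-target
  artifacts.
* One-vs-rest contrasts whatever lines the matrix contains — if a panel
  mixes cancer and non-transformed lines, the caller decides what "rest"
  means by subsetting first.
* The hit list is rank-based by design; no multiple-testing correction is
  applied to the screen itself, so top-k lists from lineages with weak
  signal are top-k of noise.
* The one-step hazard ratio under-shoots strongly non-proportional or very
  large effects; it is a screening statistic, not a replacement for a
  covariate-adjusted hazards model.
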