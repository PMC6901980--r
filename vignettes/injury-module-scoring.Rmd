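---
title: "Injury-module activation scoring: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Injury-module activation scoring: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxmod)
```

## The problem

Toxicogenomics assumes that chemical injury is accompanied by coordinated
changes in gene expression, and that exposures leading to the same injury
endpoint (fibrosis, necrosis, cellular infiltration, ...) perturb similar
gene sets.  Given replicated treatment and control cohorts of log-scale
expression — from rat tissue in vivo or primary cells in vitro — and a
library of *injury modules* (coexpressed gene sets previously linked to
histopathological phenotypes; inputs here, not derived by this package),
the question is which modules a compound activates, how strongly, and
whether activation seen in a cheap in vitro exposure predicts the in vivo
injury endpoint.

`toxmod` implements that scoring pipeline end to end: per-gene fold
changes and DEG calls, signed and absolute gene-set statistics with
random-gene-set permutation nulls, cross-condition concordance, and
max-over-conditions risk classification, together with a synthetic-data
generator that makes every stage testable without any external data.

## The statistics

**Fold change.** For gene $g$, $\mathrm{FC}_g = \bar{x}^{\,t}_g -
\bar{x}^{\,c}_g$, the difference of cohort means on the log-expression
scale.  Significance per gene is a two-sample pooled-variance Student's
t-test; cohorts of five are typical, and at least two samples per cohort
are required so the test is defined.  On natural-log input the fold
change is the natural-log effect size ($\beta$).

**DEG rule.** Benjamini–Hochberg adjusted p-values ($q$) across all genes;
a gene is a DEG when $q \le 0.05$ and $|\beta| \ge 0.41$.  The default
bound 0.41 is the natural-log value of a 1.5-fold change rounded to two
decimals (`round(log(1.5), 2)`).  BH was chosen as the FDR estimator;
the decision rule is agnostic to which FDR machinery produced $q$.

**Signed pathway score (AFC).** For a gene set $S$, the score is
$\sum_{g \in S} \mathrm{FC}_g$; its sign is the direction of regulation.
Mixed up/down activation cancels in this statistic — by design, it asks
about coherent directional shift.

**Activation score (AAFC).** The module statistic aggregates
$|\mathrm{FC}_g|$ over the measured set genes.  Absolute values make the
statistic sensitive to modules whose genes move strongly in *both*
directions, the regime in which signed aggregation reports nothing; our
synthetic contrast experiment (planted module with a 50/50 direction
mix) shows AAFC z-scores above 10 while the signed statistic stays at
noise level.

**Permutation null.** Both statistics are referred to the distribution
of the same statistic on random gene subsets of the measured universe,
drawn uniformly *without replacement* and preserving set size
(10,000 draws by default).  The p-value is one-sided — upper tail for
AAFC, the observed direction's tail for AFC — with ties counting as
as-or-more extreme, and an add-one correction
$(1 + \#\text{extreme})/(n_{\mathrm{perm}} + 1)$ so that downstream
Fisher combination and thresholding never see a zero.  The uncorrected
plain proportion is also reported (`p_plain`); on small universes an
exhaustive mode enumerates every subset instead of sampling.  The
z-score is the number of null standard deviations (sample SD of the
null draws) separating the observed score from the null mean.

**Fisher combined p-value.** Per module,
$X = -2\sum_{g \in S}\ln p_g \sim \chi^2_{2|S|}$ combines the member
genes' t-test p-values into one robustness indicator.  It is reported,
never used as a filter: set-level significance decisions rest on the
permutation p-value alone.

**Ranking, concordance, risk.** Within a condition, modules are ranked
by descending z (ties: ascending permutation p, then name); a module is
significant at $p < 0.01$.  Between two conditions, shared-module
z-vectors are compared by squared Pearson correlation with the
least-squares slope reported alongside, because $R^2$ is sign-blind and
anti-concordant activation must not masquerade as agreement.  Across a
compound's dose-by-time conditions, the row with the maximal activation
*score* is kept per module (its own z and p travel with it — not the
per-column maxima), and a compound is called high-risk when the target
module (e.g. fibrosis) is significant in that max table.

## Design decisions that were genuinely open

* **Mean vs sum aggregation.** Descriptions of the activation score vary
  between "average" and "total" absolute fold change.  We aggregate by
  mean, and compute the z-score and tail counts on subset *sums*: since
  the null preserves set size, the two aggregations differ by the
  constant $|S|$, so z and p are identical under either choice — the
  package asserts this identity bit-for-bit in its tests.
* **Log base.** Natural log internally (it matches the $\beta$
  definition); log2 input only rescales every fold change by a constant,
  which provably leaves every z and permutation p unchanged (also a
  tested exact invariance), so no conversion layer is needed.
* **Null sampling semantics.** "Randomly selected FC values" could mean
  with or without replacement; we draw gene subsets without replacement,
  matching the random-gene-set reading used for pathway scores.
* **One-sided AFC p.** The pathway p is defined through "greater than",
  yet down-regulated pathways are meaningful; we test in the observed
  direction and report the direction separately.
* **Degenerate cases.** A gene with zero variance in both cohorts gets
  $t = 0, p = 1$ when the means agree, and the smallest positive double
  with a warning when they differ (it must not crash the permutation
  stage).  A null with zero spread yields $z = 0$, $p = 1$ and a
  degeneracy flag.  Fisher inputs of exactly 0 are clamped to the
  smallest positive double with a warning.
* **Coverage.** Set genes absent from the matrix are dropped;
  `n_measured` and the coverage fraction are always reported, a set
  below the `minCoverage` gate (default 0.5) is flagged — never silently
  dropped — and a set with no measured genes is an error (a flagged NA
  row when scoring a whole collection).
* **Gene identifiers** are opaque, case-sensitive strings; harmonising
  module IDs with expression IDs (symbol vs Ensembl) is the caller's
  responsibility.

## What the synthetic generator emulates — and what it does not

`simulateExperiment()` mirrors the replicated exposure design the
statistics assume: two cohorts of `nPerCohort` samples (default 5, the
cohort size of the motivating in vivo study), i.i.d. Gaussian noise on
the log-expression scale (default SD 0.5, a mid-range value for
log-scale replicate variability in rat expression data), and planted
modules whose responding genes shift by exactly $\pm\delta$ in the
treatment cohort.  `responderFraction` controls how much of a module
responds and `directionMix` (default 0.5) how the responders split
between up- and down-regulation — the default deliberately exercises the
regime where only the absolute-value statistic can see the signal.
Truth objects record every planted per-gene shift, so parameter-recovery
tests compare against exact ground truth.

What it does **not** emulate: count-level sampling noise and
mean-variance dependence (the statistics operate entirely on log-scale
cohort means, so Gaussian noise on that scale exercises them fully),
gene-gene correlation within and between modules, library-size and
batch effects, and technical quantification variance.  Passing the
package's calibration and recovery tests therefore demonstrates that
the *statistics* behave as designed under their own assumptions — not
that real RNA-seq data meet those assumptions.

## Numerical and reproducibility choices

All randomness descends from one root seed.  Sub-seeds are derived
deterministically by hashing a stage or set-name key into a 32-bit
integer, so per-set permutation results are invariant to the order of
sets in a collection, and a pipeline re-run with the same configuration
reproduces every output byte for byte.  Exhaustive enumeration is
guarded by a subset-count cap (default $2 \times 10^5$); Monte-Carlo
and exhaustive p-values are cross-checked against each other on small
universes in the test suite.

The validation suites run at deliberately desk-sized problem scales —
2,000-gene universes, 30-gene modules, 8–11 modules, 400-draw nulls
inside 100–200-replicate loops, against the 10,000-draw default a real
analysis would use.  These sizes were chosen so the Monte-Carlo error of
each check sits well inside the tolerance being asserted while the whole
suite stays interactive; the z-scores and p-values they validate are the
same estimators at any scale.

## Known limitations

* Only injury phenotypes with a supplied module can ever be flagged;
  the module library is an input and its quality bounds the pipeline.
* The t-test DEG caller is a transparent stand-in for bootstrap-based
  quantifier variance models; DEG lists on real data will differ in the
  tails even when the decision rule ($q$, $\beta$ thresholds) matches.
* The gene-subset null is a competitive null: it asks whether a set is
  more perturbed than random genes of the measured universe, and ignores
  inter-gene correlation; sample-permutation nulls are out of scope.
* $R^2$ over ~10 shared modules is a coarse concordance summary and is
  dominated by the strongest modules; the slope must be consulted for
  direction.
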