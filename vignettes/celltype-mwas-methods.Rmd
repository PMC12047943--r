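---
title: "Cell type-specific methylome-wide association from bulk blood: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell type-specific methylome-wide association from bulk blood: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctmwas)
```

## The problem

Bulk blood DNA methylation is a proportion-weighted average of cell
type-specific methylomes. An association between a phenotype and bulk
methylation at a CpG site can therefore reflect a change inside one cell
type, a shift in cell-type composition, or both. `ctmwas` implements the
statistical-deconvolution route to cell type-specific inference: estimate
each sample's cell-type proportions from a reference panel, then test, per
site and per cell type, whether methylation *within* that cell type varies
with the phenotype — across many cohorts, two tissues (cord and peripheral
blood), and two measurement platforms (array-like beta values covering a
subset of CpGs; sequencing-like normalized scores covering the full
universe).

## The forward model (and the synthetic-data generator)

The generator is the forward direction of the analysis model. For site $i$,
sample $j$, cell types $t = 1, \dots, T$:

$$ \mathrm{bulk}_{ij} \;=\; \sum_t p_{jt}\,\bigl(\mu_{it} + \beta_{it}\,y_j\bigr)
\;+\; \mathbf{c}_j^\top \boldsymbol{\gamma}_i \;+\; h_j\,\delta_i
\;+\; \varepsilon_{ij}, \qquad \varepsilon_{ij} \sim N(0, \sigma^2) $$

* $p_j \sim \mathrm{Dirichlet}(\alpha)$ — true proportions. The default
  $\alpha$ is centered on typical leukocyte differentials (granulocytes
  ~60%, CD4T ~15%, CD8T and monocytes ~8%, NK ~5%, B cells ~4%) with total
  concentration 30, a realistic between-sample spread for blood.
* $\mu_{it}$ — the reference panel: a bimodal beta mixture (most CpGs are
  strongly methylated or strongly unmethylated), compressed into
  $[0.05, 0.95]$ so that default noise clips fewer than 1% of entries. At
  `n_discriminating` sites one random cell type is shifted by 0.3–0.5,
  which is what makes the proportions identifiable.
* $\beta_{it}$ — planted effects (`effect_spec()`): methylation change per
  1 SD of the latent phenotype, restricted to $|\beta| \le 0.5$. Effects can
  be shared between cord and peripheral arms, or oppose each other in two
  cell types at one site — the qualitative patterns of interest downstream.
* $y_j \sim N(0,1)$ — the latent symptom score. The observed instrument
  score is `round(max(0, mean + sd * y))`, so cohorts measured on different
  count scales are emulated and the within-cohort standardization step can
  be tested against known latent values. Association is planted as
  methylation varying with the latent score; for a cross-sectional
  association test the direction of causality is irrelevant.
* $\mathbf{c}_j$ — measured covariates (sex, age, technical batch), each
  shifting a configurable fraction of sites (default 10%, coefficients
  $N(0, 0.03)$); $h_j$ — one *hidden* binary confounder (an unrecorded
  batch) shifting 30% of sites by $\pm 0.05$ (configurable), which the
  principal-component capture step must absorb.
* Values are clipped to $[0,1]$ (array-like) or $[0,\infty)$
  (sequencing-like); the clipped fraction is recorded in the generator truth
  and stays below 1% at default settings.

Rarely methylated sites — the sequencing-only phenomenon motivating the
rare-site filter — are generated as *sporadically* methylated: the
Beta(0.5, 50) baseline is used as the per-sample probability of a nonzero
score rather than as a mean with additive noise. This mirrors how such sites
look in methyl-CpG-binding-domain sequencing (no methylated reads in most
samples, hence exact zeros) and places them decisively below the filter's
default thresholds; with additive noise instead, the zero-clipping bias
would push many of them above the mean threshold.

What the generator does *not* emulate: raw array intensities or sequencing
reads (generation starts at post-QC matrices), nucleated red blood cells
(cord and peripheral arms differ only by configuration), probe-specific
measurement error, genomic autocorrelation of *methylation values*
(sites are independent given the design; the enrichment module's rotation
null is exercised with explicitly block-correlated indicators in the tests),
and population structure. Passing tests therefore demonstrate correctness of
the estimators under the stated model, not robustness to every artifact of
real arrays.

Seeds derive from one master seed by a fixed counter scheme (panel = +1,
site subsetting = +2, effect placement = +3, catalog = +4, cohort $i$ =
+100+$i$), so appending a cohort to a configuration never changes the data
of existing cohorts.

## Proportion estimation

Per sample we solve

$$ \min_{p \ge 0,\; \sum_t p_t = 1} \;\lVert \mathrm{bulk}_j - M p \rVert^2 $$

over the panel-matched sites. The equality constraint (rather than
$\sum p \le 1$) is deliberate: downstream the proportions partition the bulk
signal, and $\sum p = 1$ lets the interaction design omit a separate
intercept. With at most 6–8 blood cell types the QP is solved *exactly* by
enumerating all $2^T - 1$ candidate support sets, solving each
equality-constrained subproblem from a pre-factorized KKT system, and taking
the feasible candidate with the lowest objective (ties broken by minimum
norm). The optimum's own support always appears among the candidates, so
this is the global solution — no projection heuristics, and the tests can
hold it to a dense simplex grid search. A panel whose condition number
exceeds 1e8 (e.g. no discriminating sites) is rejected with an instruction
to add discriminating sites.

Estimated — never true — proportions are passed downstream everywhere,
including in tests, so estimation error propagates realistically; the truth
is used only in recovery assertions.

## The per-cohort association model

After (1) within-cohort standardization of the symptom score (sample SD,
denominator $n-1$), (2) per-site OLS residualization of methylation on an
intercept plus measured covariates, (3) capture of the first principal
component of the residual matrix (samples as observations, sites
standardized to unit variance, at most 50 000 seeded random sites for
tractability; sign fixed by the largest-magnitude loading) and a second
residualization of both methylation and phenotype on it, we fit per site the
no-intercept regression

$$ r_{ij} = \sum_t a_{it}\, p_{jt} + \sum_t b_{it}\,(p_{jt} y_j) + e_{ij} $$

and test $H_0: b_{it} = 0$ per cell type with a $t$ statistic on $n - 2T$
degrees of freedom, converted to a signed $z$ carrying the identical
two-sided $p$ (log-space tails, accurate far below 1e-300). Design notes:

* The phenotype is residualized against the same covariates and PC as the
  methylation (symmetric partialling keeps confounding from leaking through
  the product term), then rescaled to unit SD so effects stay "per SD".
* Proportions are *not* additionally regressed out as covariates: their
  main effects are already columns of the design, and double adjustment
  would absorb the signal of interest.
* The $n - 2T$ degrees of freedom deliberately ignore the df spent in the
  residualization stages; with cohort sizes in the hundreds this
  approximation is negligible and is recorded in the diagnostics.
* Cell types whose mean estimated proportion falls below 0.01 stay in the
  design but are excluded from reports — their interaction terms are poorly
  identified and produce visibly deflated test statistics (the low-abundance
  B-cell phenomenon); the exclusion is recorded rather than silent.
* Sequencing-platform studies first drop sites with mean value < 0.01 or
  nonzero fraction < 0.05 (both configurable), the methylation analogue of a
  minor-allele-frequency filter.

Calibration is monitored with the genomic inflation factor
$\lambda = \mathrm{median}(z^2) / 0.4549364$ and QQ tables with 95%
order-statistic (beta-quantile) bands.

## Meta-analysis

Cohorts are combined per (site, cell type) with the sample-size-weighted
Stouffer statistic $z_{\mathrm{meta}} = \sum_k \sqrt{n_k} z_k / \sqrt{\sum_k n_k}$.
Because the sequencing panel cannot separate CD4+ from CD8+ T cells, its
pooled CD3T results are duplicated verbatim into both the CD4T and CD8T
streams before combination (and a planted CD4T/CD8T effect reaches a
sequencing cohort's CD3T profile at half strength, the pooled cell class
being an equal mix). Heterogeneity uses the calibrated sample-size-weighted
form: under $z_k \sim N(\delta\sqrt{n_k}, 1)$,
$\hat\delta = \sum \sqrt{n_k} z_k / \sum n_k$ and
$Q = \sum_k (z_k - \hat\delta\sqrt{n_k})^2$ is exactly $\chi^2_{k-1}$ under
homogeneity — the natural analogue of Cochran's Q for this weighting scheme.
FDR is controlled by a Benjamini–Hochberg step-up applied separately per
cell type within each analysis; the testing universe is an explicit
configuration choice, not hard-coded, because printed q/p ratios do not pin
it down. Direction strings report per-study signs in a fixed configured
study order, with `?` for studies not covering a site.

## Enrichment by circular permutation

Suggestive sites ($q < 0.5$, strict) are laid on the genome-ordered site
circle (chromosomes concatenated in configured order; a per-chromosome
variant is a flag). Each gene set's territory is the set of sites within
100 kb (inclusive bounds) of a member gene. The statistic is the *count* of
suggestive sites in the territory — the simplest statistic consistent with
site-level permutation, and one that makes exhaustive enumeration exact; a
rank-sum alternative is left as configuration. The null rotates the
indicator by uniformly drawn offsets (or all $m-1$ offsets exhaustively),
preserving both the indicator's autocorrelation and the gene-size bias;
$p = (1 + \#\{d: S_d \ge S_{\mathrm{obs}}\})/(n_{\mathrm{perm}} + 1)$ can
never be zero. All rotation statistics are evaluated at once via the FFT
circular cross-correlation (exact for 0/1 vectors after rounding), so
exhaustive mode costs $O(m \log m)$.

## Cross-tissue look-up

Discovery-significant sites ($q < 0.05$) are matched into the other tissue's
meta-analysis on (chromosome, position, cell type). Bonferroni correction
multiplies the target $p$ by the number of looked-up sites with available
target data, counted per cell type (the pooled-across-cell-types variant is
a one-line change; per cell type matches the per-cell-type FDR universe).
Whether replications exceed chance uses the continuity-corrected one-sample
proportions test against $p_0 = f_{\mathrm{disc}} \times f_{\mathrm{target}}$,
the product of the two analyses' significant fractions (independence null,
overridable). The continuity term is floored so the numerator is never
negative — at $k = m p_0$ the statistic is 0, matching `stats::prop.test`.
As in the underlying design, the test does not adjust for correlation
between nearby CpGs; that limitation is documented, not fixed.

## Numerical choices

* Coordinates are 1-based inclusive everywhere internally; BED files are
  0-based half-open on disk and converted only in the readers/writers.
  Chromosomes are autosomes labeled "1".."22".
* Proportion rows are validated to sum to 1 within 1e-8; Dirichlet draws
  sum to 1 within 1e-12 by construction.
* Residual orthogonality is held to 1e-8; the QP support enumeration uses a
  -1e-10 feasibility slack and a 1e-12 objective tie window.
* $t \to z$ conversion and $z \to p$ use `log.p` tails throughout, so
  extreme statistics keep finite, accurate p-values.
* Degenerate inputs fail loudly: constant phenotypes, rank-deficient
  covariate designs (collinear columns are named), duplicated positions,
  fewer than 10 panel-matched sites, empty study intersections.

## Problem sizes

The shipped configuration mirrors the two-arm consortium structure (seven
cord cohorts totalling 2 546 samples, five peripheral cohorts totalling
2 934, one of them sequencing-based with 583) at a desk-scale site universe:
8 000 sequencing sites containing a 4 000-site array subset, 300
discriminating panel sites, 20% rare sites. Property suites use 1 000–5 000
sites and cohorts of 100–500 samples, 20 master seeds for detection-rate
assertions, and 999 rotations per enrichment test. These sizes were chosen
so the whole pipeline and its tests are conveniently re-runnable on a
laptop-class single core while keeping every statistical check
well-powered.

## Known limitations

* Reference-based only: no reference-free or semi-supervised deconvolution.
* One principal component of confounding; structured multi-factor batch
  effects beyond the first component are out of scope by design.
* Fixed-effects (Stouffer) combination only; heterogeneity is reported, not
  modeled (no random-effects variant).
* The enrichment statistic is a count; graded evidence below the suggestive
  threshold does not contribute.
* Synthetic data are independent across sites given the design, so
  empirical type-I calibration of the site-level tests does not exercise
  methylation autocorrelation (the rotation null's raison d'être is tested
  with explicitly correlated indicators instead).
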