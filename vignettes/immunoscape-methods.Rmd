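---
title: "Spatial scoring of lymphocyte infiltration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial scoring of lymphocyte infiltration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

immunoscape turns a classified cell map of an H&E tumour section — cancer,
lymphocyte and stromal cell coordinates in micrometres — into a spatial
score of immune infiltration, the intratumour lymphocyte ratio (ITLR), and
links that score to survival and gene expression. This vignette explains
the models, the tunable parameters, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## The proximity-to-cancer model

Let $x_1,\dots,x_n$ be cancer-cell positions and $y_1,\dots,y_m$
lymphocyte positions in one section. The cancer landscape is a kernel
intensity estimate with the radially symmetric quartic (biweight) kernel
$K(u) = \tfrac{3}{\pi}(1-\lVert u\rVert^2)^2$ for $\lVert u\rVert \le 1$:

$$ f(p) \;=\; \frac{1}{h^2}\sum_{i=1}^{n} K\!\left(\frac{p - x_i}{h}\right), $$

and each lymphocyte's spatial proximity to cancer is $s_i = f(y_i)$,
evaluated exactly at the lymphocyte position (`proximity_to_cancer()`),
never interpolated from a grid — grids (`density_grid()`) exist only for
maps and contours. Two normalization decisions matter:

* **Intensity scale, no $1/n$.** $f$ is an intensity (cells/µm²), not a
  probability density. Dividing by $n$ would make $s$ values incomparable
  between tumours with very different cancer counts once lymphocytes are
  pooled for clustering; the intensity scale keeps them on one axis. All
  downstream classification logic is scale-free (see below), so this choice
  affects units, not classes.
* **No edge correction.** Sections are orders of magnitude larger than the
  bandwidth, so boundary bias affects a negligible fraction of cells.

The bandwidth `h` defaults to 50 µm, the scale of a few cell diameters
and of the nest structures the kernel is meant to smooth. When training
maps are available, `select_bandwidth()` chooses `h` by point-process
least-squares cross-validation: for each candidate it computes
$\int_W \hat f^2 - 2\sum_i \hat f_{-i}(x_i)$ on a random subset of maps
(default 10) and minimises the average. The integral term is approximated
on a grid of spacing $0.2\,h$, which is fine relative to the kernel
support; the leave-one-out term is exact because removing a point just
subtracts its own kernel peak $\tfrac{3}{\pi}h^{-2}$.

## Class discovery: mixture, BIC, stability, thresholds

Pooled $s$ values from all tumours are clustered with a univariate
Gaussian mixture fitted by EM (`fit_gmm()`). Numerical details, chosen
because the procedure must be reproducible and robust to the huge spike of
near-zero $s$ in lymphocyte-poor regions:

* 10 restarts from quantile-spread initializations (the first exact, the
  rest jittered); each restart runs a short EM (30 iterations, tolerance
  1e-6) and the best continues to full convergence (relative
  log-likelihood change below 1e-8, at most 1000 iterations);
* a variance floor of $10^{-12}\,\mathrm{var}(s)$ — distal lymphocytes can
  sit at exactly $s=0$ outside every kernel's support, and the floor lets a
  component model that spike without degenerating;
* components are reported sorted by mean, descending, so component 1 is
  always the intratumour-like cluster regardless of EM's internal
  permutation;
* a restart that collapses (a component weight going to zero) is discarded;
  the fit fails only if every restart collapses.

The number of classes is chosen by BIC in the higher-is-better convention
$\mathrm{BIC} = 2\log L - d\log N$ with $d = 3K-1$ free parameters
(`select_k()`, K = 1–5, ties resolve to the smaller K).
`stability_analysis()` repeats the selection on random subsamples (without
replacement — with pools this large the distinction is immaterial, and
without-replacement avoids duplicate-weighting artifacts) and reports the
modal K and the spread of the K = 3 component means. The production model
is then refit once, at the modal K, on a fixed-seed sample, because a
deterministic final model is needed downstream.

Lymphocytes are assigned to the three classes — intratumour (ITL),
adjacent-tumour (ATL) and distal-tumour (DTL) — by two thresholds on $s$
(`class_thresholds()`): each threshold is the crossing point of the
weighted normal densities of two adjacent components, found as the root of
a quadratic in closed form and required to lie between the two means; if
no crossing exists there (a pathological fit) the midpoint of the means is
used with a warning. Interval thresholds rather than raw max-posterior
assignment guarantee classes that are contiguous on the proximity axis;
with unequal variances max-posterior can assign the far tail of the axis
to the wrong component. Max-posterior assignment remains available via
`assign_classes(..., method = "posterior")`.

Because thresholds are refit from the data, the entire classification is
invariant to a common positive rescaling of $s$ — and therefore to the
kernel normalization and to the units of the coordinates, as the scale
equivariance $f \mapsto c^{-2} f$ under $x, h \mapsto c\,x, c\,h$ shows.
Absolute $s$ values (and hence the numerical values of cluster means or of
an ITLR cut-off) are only meaningful within one choice of units.

## Physical-distance profile of the classes

`nearest_cancer_distance()` ($d_{\min}$) and `hull_centroid_distance()`
($d_{\mathrm{centroid}}$: distance to the vertex-mean centroid of the
convex hull of the 5 nearest cancer cells) characterise the classes in
plain micrometres. Conventions for degenerate inputs: neighbour ties are
broken by lowest cell index; coincident points are deduplicated before
hull construction; a collinear neighbourhood degenerates to the midpoint
of its two extreme points; a fully coincident one to the shared point. The
hull centroid is the arithmetic mean of the extreme points only — points
lying mid-edge on the hull boundary are not vertices and are excluded —
and the vertex set is sorted canonically before averaging so the result is
independent of input order. Class differences are tested with Welch's
t-test by default; the classic pooled-variance Student test is available
via `var_equal = TRUE`, but class variances differ too clearly for it to
be the default.

## Scores and survival stratification

Per tumour, `compute_scores()` reports ITLR = n(ITL)/n(cancer), its ATL
and DTL analogues, and the class-agnostic lymphocyte abundance Lym, with
ITLR + ATLR + DTLR = Lym by construction. Trend against ordered clinical
categories uses the Jonckheere–Terpstra test (`jt_trend_test()`), exact by
enumeration up to 10 observations and a tie-corrected normal approximation
beyond.

`scan_cutoff()` dichotomizes a score at the percentile grid 20, 21.5, …,
80 (41 candidates; the step is read in percentile units — a value-unit
reading would be scale-dependent), choosing the candidate with the
smallest log-rank p, ties to the lower percentile. The chosen p is a
minimum over 41 correlated tests and is anti-conservative by construction
— the package's own null simulation demonstrates this — which is why the
discovery/validation discipline matters: the cut-off is frozen on a
discovery cohort and re-tested with `apply_cutoff()` on a validation
cohort. Cox models (`cox_model()`, Efron ties, via the survival package)
code the high-score group as 1, so HR < 1 means high scores are
protective; `node` is binary and `size` continuous in cm by default, both
simply columns of the clinical table. Follow-up is administratively
censored at 120 months (`censor_at()`), the 10-year horizon of
disease-specific survival analysis.

`bootstrap_stability()` resamples patients with replacement and reports
the fraction of resamples in which the score term stays significant. This
fraction estimates the stability of the observed effect, not the test's
size: under a true null its expectation across datasets is
$2\Phi(-1.96/\sqrt{2}) \approx 0.17$, not $\alpha$, because resampling
re-draws around the observed estimate rather than around zero. It should
be read as "how often would this conclusion survive a perturbation of the
cohort", the question it was designed for.

## Molecular correlates

`correlate_genes()` computes per-gene Pearson correlation with the score
and the exact t-transform p-value; q-values come from a Storey-type
estimator (`estimate_qvalues()`) with $\lambda = 0.75$ — the upper quarter
of the unit interval is treated as null-dominated when estimating $\pi_0$,
and with $\pi_0$ forced to 1 the q-values reduce exactly to
Benjamini–Hochberg. `find_modules()` clusters the gene–gene correlation
matrix on distance $1 - r$ (keeping anticorrelated genes apart, which
matches clustering positively and negatively score-associated pools
separately), cuts the tree into 100 clusters, and keeps clusters with mean
pairwise $|r| > 0.75$ and at least 6 members. Ward linkage (`ward.D2`) is
the default: in planted-block experiments average linkage absorbs weakly
correlated background genes into tight modules at the 100-cluster cut,
diluting mean $|r|$ below the selection rule, while Ward recovers planted
blocks exactly; average linkage remains available. The "size exceeding
five" rule is read strictly as ≥ 6. Gene-set enrichment is the upper-tail
hypergeometric test with BH adjustment across sets; gene sets load from
GMT via `read_gmt()`. `compare_score_vs_gene()` pairs the dichotomized
score with a rank-based gene grouping (median split, or 25/50/25 with
exact group sizes, expression ties broken by sample order) in one Cox
model per gene, flagging collinear pairings.

## What the synthetic data emulate — and what they do not

`simulate_tumor()` generates cancer nests as a Thomas-type parent–
offspring process (nest centres Poisson, offspring Gaussian around them),
a uniform stromal background, and three planted lymphocyte regimes:
"intra" jittered onto random cancer cells, "adjacent" offset outward from
a nest cell, "distal" uniform but at least three nest spreads from every
nest centre. Defaults reproduce a whole-section scale: 8 × 8 mm, ~80,000
cancer cells, ~15,000 lymphocytes at 32/47/21% composition, ~14,000
stromal cells. Ground-truth labels are geometric regimes, not density
thresholds, so recovery tests of the mixture classifier are non-circular.
The generator does not emulate stromal architecture, anisotropic or
crescent-shaped nests, tissue folds or section artifacts, and its three
regimes are cleaner than real infiltration patterns; a high recovery rate
on synthetic maps therefore validates the machinery, not the biological
classification of any real cohort.

`simulate_survival()` plants a hazard ratio for the high-score group on a
Weibull baseline (shape 1.2, scale 80 months, light exponential censoring,
administrative censoring at 120 months), calibrated so that the default
planted HR of 0.3 yields roughly 49% versus 80% five-year disease-specific
survival — the landscape reported for ITLR-stratified TNBC cohorts.
`simulate_expression()` plants score-correlated genes at an exact
population correlation, latent-factor modules at an exact within-module
correlation, and i.i.d. null genes; real expression data have correlated
noise, batch structure and heavier tails.

## Problem sizes and reproducibility

Every stochastic function takes an explicit seed and is a pure function of
(parameters, seed). The test suite exercises the full pipeline at reduced
but non-trivial sizes chosen to keep the suite fast while leaving each
statistical check well-powered: mixture recovery on pools of 100,000
values with 200 stability repetitions at 20,000; class recovery on 20
tumours with 1,500 lymphocytes each; survival scans over 100 simulated
cohorts of 181 patients; 1,000-instance exact-equality checks for the
geometry and kernel evaluators. `scripts/acceptance.R` reruns a compact
version of the whole study from one seed and writes the headline numbers
as JSON.

## Known limitations

* The mixture model assumes three roughly Gaussian proximity components;
  cohorts with genuinely different infiltration structure may select a
  different K, which `stability_analysis()` makes visible rather than
  hiding.
* The cut-off scan's discovery p-value is optimistic (minimum over 41
  tests) and is not multiplicity-corrected, by design; only the validation
  p-value should be quoted.
* Bootstrap stability fractions are not test sizes (see above).
* Whether lymphocytes were pooled across cohorts for clustering, and
  whether assignment used thresholds or posteriors, are genuinely open
  choices; both are exposed as options (per-cohort refit by subsetting the
  pooled sample, `method = "posterior"` for assignment), with pooled +
  thresholds as defaults.
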