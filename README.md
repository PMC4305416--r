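# immunoscape

Spatial scoring of lymphocyte infiltration from classified cell maps of
H&E tumour sections.

Pathologists score tumour-infiltrating lymphocytes by eye; automated
image analysis can classify every cell nucleus on a whole section, but a
raw lymphocyte count ignores *where* the lymphocytes sit relative to the
cancer. immunoscape is for computational pathology and cancer-immunology
groups who have per-cell coordinate tables (cancer / lymphocyte / stromal,
in µm) and want an objective, spatially aware infiltration score — the
intratumour lymphocyte ratio (ITLR) — together with its downstream
survival and molecular analyses.

## The model

With cancer-cell positions $x_1,\dots,x_n$ and lymphocyte positions
$y_1,\dots,y_m$, the cancer landscape is a quartic-kernel intensity
estimate

$$ f(p) = \frac{1}{h^2}\sum_{i=1}^n K\!\Big(\frac{p-x_i}{h}\Big),
\qquad K(u) = \frac{3}{\pi}\,(1-\lVert u\rVert^2)^2\;[\lVert u\rVert\le 1], $$

and each lymphocyte's spatial proximity to cancer is $s_i = f(y_i)$.
Pooled $s$ values are clustered with a univariate Gaussian mixture (EM,
model choice by $\mathrm{BIC} = 2\log L - d\log N$, resampling stability),
which separates three lymphocyte classes — intratumour (ITL),
adjacent-tumour (ATL) and distal-tumour (DTL) — by two thresholds on $s$
where adjacent weighted component densities cross. Each tumour is then
scored by

$$ \mathrm{ITLR} = \frac{\#\,\mathrm{ITL}}{\#\,\mathrm{cancer\ cells}}, $$

plus ATLR, DTLR and the class-agnostic lymphocyte abundance Lym. Companion
modules characterise classes by physical distances ($d_{\min}$ to the
nearest cancer cell and $d_{\mathrm{centroid}}$ to the vertex-mean
centroid of the convex hull of the 5 nearest cancer cells), dichotomize a
score by a 20th–80th percentile log-rank scan with a frozen-cut-off
validation discipline, fit Kaplan–Meier/Cox models with bootstrap
stability, and correlate scores with expression (Storey q-values,
co-expression module discovery, hypergeometric gene-set enrichment).
Synthetic generators for tumours, survival and expression with planted
ground truth make every stage testable. See the methods vignette
(`vignettes/immunoscape-methods.Rmd`) for assumptions and numerical
details.

## Worked example

```r
library(immunoscape)

# five simulated tumour sections with planted lymphocyte regimes
sims <- lapply(1:5, function(i)
  simulate_tumor(window = c(0, 0, 2500, 2500), nest_rate = 2,
                 offspring_mean = 250, nest_sd = 40, stromal_rate = 100,
                 lymph_counts = c(500, 500, 500), adjacent_offset = 100,
                 regime_jitter = 5, tumour_id = paste0("t", i), seed = i))

# per-lymphocyte spatial proximity to cancer, pooled across tumours
prox <- lapply(sims, function(ts) proximity_to_cancer(ts$map, h = 80))
pooled <- unlist(lapply(prox, `[[`, "s"))

# the three-class Gaussian mixture on pooled proximities
fit <- fit_gmm(pooled, K = 3, seed = 7)
fit
#> <gmm_fit> K = 3, n = 7500, logLik = 63183.65, BIC = 126295.91
#>      weight         mean           sd
#> 1 0.3760332 9.806245e-03 5.839618e-03
#> 2 0.2807705 3.038695e-04 2.985636e-04
#> 3 0.3431962 4.895590e-11 5.899582e-09

th <- class_thresholds(fit)
th
#>        t_low       t_high
#> 2.840436e-08 1.125455e-03

# classify and score the first tumour
cl <- assign_classes(th, prox[[1]]$s, fit)
compute_scores(cl, sum(sims[[1]]$map$cells$class == "cancer"), "t1")
#>   tumour_id n_cancer n_itl n_atl n_dtl     itlr      atlr      dtlr       lym
#> 1        t1     2499   531   448   521 0.212485 0.1792717 0.2084834 0.6002401
#>   p_itl     p_atl     p_dtl
#> 1 0.354 0.2986667 0.3473333

# agreement with the planted regimes
mean(as.character(cl$til_class) ==
     c(intra = "ITL", adjacent = "ATL",
       distal = "DTL")[as.character(sims[[1]]$regime)])
#> [1] 0.896
```

The mixture found a high-proximity component (mean ~9.8e-3 cells/µm²: ITLs
inside nests), a low-proximity one (~3.0e-4: ATLs at nest margins) and a
near-zero one (DTLs outside every kernel's reach); the thresholds split
the proximity axis between them. Tumour `t1`'s ITLR of 0.21 says there
are 21 intratumour lymphocytes per 100 cancer cells, and 89.6% of its
lymphocytes were assigned the regime they were planted in. Absolute
proximity and score values depend on the coordinate units and bandwidth;
classification is invariant to any common rescaling.

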