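# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately use different algorithms from the implementation:
# plain double loops, exhaustive scans and closed forms.

# brute-force quartic kernel intensity: double loop over queries x cells
bf_density <- function(cancer, h, query) {
  vapply(seq_len(nrow(query)), function(j) {
    u2 <- ((query[j, 1] - cancer[, 1])^2 + (query[j, 2] - cancer[, 2])^2) / h^2
    sum(ifelse(u2 >= 1, 0, (3 / pi) * (1 - u2)^2)) / h^2
  }, 0)
}

# brute-force nearest-cancer distance
bf_dmin <- function(cancer, lymph) {
  vapply(seq_len(nrow(lymph)), function(j) {
    sqrt(min((lymph[j, 1] - cancer[, 1])^2 + (lymph[j, 2] - cancer[, 2])^2))
  }, 0)
}

# exact point-in-triangle test (boundary inclusive); integer-safe; a
# degenerate (collinear) triangle falls back to its segments
tri_contains <- function(p, a, b, c) {
  cr <- function(o, u, v) (u[1] - o[1]) * (v[2] - o[2]) - (u[2] - o[2]) * (v[1] - o[1])
  if (cr(a, b, c) == 0)
    return(seg_contains(p, a, b) || seg_contains(p, b, c) ||
           seg_contains(p, a, c))
  d1 <- cr(a, b, p); d2 <- cr(b, c, p); d3 <- cr(c, a, p)
  !((d1 < 0 || d2 < 0 || d3 < 0) && (d1 > 0 || d2 > 0 || d3 > 0))
}

seg_contains <- function(p, a, b) {
  cr <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  if (cr != 0) return(FALSE)
  dt <- (p[1] - a[1]) * (b[1] - a[1]) + (p[2] - a[2]) * (b[2] - a[2])
  dt >= 0 && dt <= (b[1] - a[1])^2 + (b[2] - a[2])^2
}

# p lies in the convex hull of rows of Q (Caratheodory: some triangle or
# segment of Q contains p)
in_hull <- function(p, Q) {
  nq <- nrow(Q)
  if (nq == 0) return(FALSE)
  if (nq == 1) return(all(p == Q[1, ]))
  if (nq == 2) return(seg_contains(p, Q[1, ], Q[2, ]))
  for (i in 1:(nq - 2)) for (j in (i + 1):(nq - 1)) for (k in (j + 1):nq)
    if (tri_contains(p, Q[i, ], Q[j, ], Q[k, ])) return(TRUE)
  # collinear Q: fall back to segments
  for (i in 1:(nq - 1)) for (j in (i + 1):nq)
    if (seg_contains(p, Q[i, ], Q[j, ])) return(TRUE)
  FALSE
}

# oracle vertex-mean hull centroid: exhaustive extreme-point scan
oracle_hull_centroid <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) == 1) return(pts[1, ])
  extreme <- vapply(seq_len(nrow(pts)), function(i) {
    !in_hull(pts[i, ], pts[-i, , drop = FALSE])
  }, TRUE)
  v <- pts[extreme, , drop = FALSE]
  v <- v[order(v[, 1], v[, 2]), , drop = FALSE]
  colMeans(v)
}

# sampler for the three-component proximity mixture reported for TNBC
# lymphocytes (means 0.13/0.06/0.011, sd 0.0045/0.0047/0.002, weights
# 0.32/0.47/0.21, ordered ITL/ATL/DTL)
rmix3 <- function(n) {
  k <- sample(1:3, n, TRUE, prob = c(0.32, 0.47, 0.21))
  rnorm(n, c(0.13, 0.06, 0.011)[k], c(0.0045, 0.0047, 0.002)[k])
}
MIX3_MEANS <- c(0.13, 0.06, 0.011)

# small random integer-coordinate cell map (invites collinear/duplicate
# degeneracies while keeping geometry exact)
random_int_map <- function(n_cancer, n_lymph, lim = 20) {
  cell_map(c(sample(0:lim, n_cancer, TRUE), sample(0:lim, n_lymph, TRUE)),
           c(sample(0:lim, n_cancer, TRUE), sample(0:lim, n_lymph, TRUE)),
           rep(c("cancer", "lymphocyte"), c(n_cancer, n_lymph)))
}

# the well-separated planted-regime scenario used for recovery tests:
# sparse tight nests, adjacent lymphocytes offset well beyond the jitter
sep_tumor <- function(seed, n_each = 500, tumour_id = paste0("t", seed)) {
  simulate_tumor(window = c(0, 0, 2500, 2500), nest_rate = 2,
                 offspring_mean = 250, nest_sd = 40, stromal_rate = 100,
                 lymph_counts = rep(n_each, 3), adjacent_offset = 100,
                 regime_jitter = 5, tumour_id = tumour_id, seed = seed)
}
REGIME2CLASS <- c(intra = "ITL", adjacent = "ATL", distal = "DTL")
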