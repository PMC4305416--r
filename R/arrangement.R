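# Physical-distance characterization of lymphocyte classes: distance to
# the nearest cancer cell (d_min) and distance to the vertex-mean centroid
# of the convex hull of the five nearest cancer cells (d_centroid).

#' Distance from each lymphocyte to its nearest cancer cell
#'
#' @param map A [cell_map] with at least one cancer cell.
#' @return Numeric vector `d_min` (micrometres), one entry per lymphocyte
#'   in map order.
#' @export
nearest_cancer_distance <- function(map) {
  stopifnot(inherits(map, "cell_map"))
  cancer <- cell_xy(map, "cancer")
  if (nrow(cancer) == 0) stop("no cancer cells: d_min is undefined")
  lymph <- cell_xy(map, "lymphocyte")
  if (nrow(lymph) == 0) return(numeric(0))
  cpp_knn(cancer[, 1], cancer[, 2], lymph[, 1], lymph[, 2], 1L)$dist[, 1]
}

# vertex-mean centroid of the convex hull of a small point set;
# duplicates are removed first, a single distinct point is its own
# centroid, and a collinear set degenerates to the mean of its two
# extreme points. Hull vertices are sorted canonically before averaging
# so the result does not depend on input order.
hull_vertex_centroid <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) == 1) return(pts[1, ])
  # collinearity check against the segment between the two most distant
  # points along the dominant axis
  rng <- apply(pts, 2, function(v) diff(range(v)))
  ax <- which.max(rng)
  i1 <- which.min(pts[, ax]); i2 <- which.max(pts[, ax])
  a <- pts[i1, ]; b <- pts[i2, ]
  cross <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
  if (all(cross == 0)) {
    proj <- (pts[, 1] - a[1]) * (b[1] - a[1]) + (pts[, 2] - a[2]) * (b[2] - a[2])
    ends <- rbind(pts[which.min(proj), ], pts[which.max(proj), ])
    return(colMeans(ends))
  }
  v <- pts[chull(pts[, 1], pts[, 2]), , drop = FALSE]
  # chull may keep points lying on a hull edge; vertices are extreme points
  # only, so drop any vertex collinear with its cyclic neighbours
  repeat {
    nv <- nrow(v)
    if (nv <= 2) break
    keep <- vapply(seq_len(nv), function(i) {
      a <- v[if (i == 1) nv else i - 1, ]
      b <- v[i, ]
      cc <- v[if (i == nv) 1 else i + 1, ]
      (cc[1] - a[1]) * (b[2] - a[2]) - (cc[2] - a[2]) * (b[1] - a[1]) != 0
    }, TRUE)
    if (all(keep)) break
    v <- v[keep, , drop = FALSE]
  }
  v <- v[order(v[, 1], v[, 2]), , drop = FALSE]
  colMeans(v)
}

#' Distance to the centroid of the convex hull of the k nearest cancer cells
#'
#' For each lymphocyte, its `k` nearest cancer cells are found (distance
#' ties broken by lowest cell index), coincident points are deduplicated,
#' the convex hull of the remainder is built, and the centroid is the
#' arithmetic mean of the hull vertices (the extreme points). A collinear
#' neighbourhood degenerates to the midpoint of its extreme points; a
#' fully coincident one to the shared point.
#'
#' @param map A [cell_map] with at least `k` cancer cells.
#' @param k Number of nearest cancer cells forming the hull (default 5).
#' @return Numeric vector `d_centroid` (micrometres), one per lymphocyte
#'   in map order.
#' @export
hull_centroid_distance <- function(map, k = 5) {
  stopifnot(inherits(map, "cell_map"))
  cancer <- cell_xy(map, "cancer")
  if (nrow(cancer) < k)
    stop(sprintf("need at least k = %d cancer cells (got %d)", k, nrow(cancer)))
  lymph <- cell_xy(map, "lymphocyte")
  if (nrow(lymph) == 0) return(numeric(0))
  nn <- cpp_knn(cancer[, 1], cancer[, 2], lymph[, 1], lymph[, 2], as.integer(k))
  vapply(seq_len(nrow(lymph)), function(i) {
    cen <- hull_vertex_centroid(cancer[nn$index[i, ], , drop = FALSE])
    sqrt(sum((lymph[i, ] - cen)^2))
  }, 0)
}

#' Pairwise class differences in a distance measure
#'
#' Tests all pairwise differences between lymphocyte classes with a
#' two-sided t-test (Welch by default; `var_equal = TRUE` gives the
#' classic pooled-variance Student test), and reports per-class medians
#' and interquartile ranges. Two identical constant groups are reported
#' as t = 0, p = 1.
#'
#' @param values Numeric per-lymphocyte measure (e.g. d_min).
#' @param labels Class labels (factor or character), same length.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return List with `tests` (data frame: class_a, class_b, t, df, p) and
#'   `summary` (data frame: class, n, median, q25, q75). Pairs with an
#'   absent class are skipped with a warning.
#' @export
class_difference_tests <- function(values, labels, var_equal = FALSE) {
  labels <- as.factor(labels)
  lev <- levels(labels)
  smry <- do.call(rbind, lapply(lev, function(l) {
    v <- values[labels == l]
    data.frame(class = l, n = length(v),
               median = if (length(v)) median(v) else NA_real_,
               q25 = if (length(v)) quantile(v, 0.25, names = FALSE) else NA_real_,
               q75 = if (length(v)) quantile(v, 0.75, names = FALSE) else NA_real_)
  }))
  pairs <- combn(lev, 2)
  tests <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- values[labels == pairs[1, j]]
    b <- values[labels == pairs[2, j]]
    if (length(a) < 2 || length(b) < 2) {
      warning("class '", pairs[which(c(length(a), length(b)) < 2)[1], j],
              "' has fewer than 2 observations; pair skipped")
      next
    }
    if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
      res <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                  p.value = 1)
    } else {
      res <- stats::t.test(a, b, var.equal = var_equal)
    }
    tests[[j]] <- data.frame(class_a = pairs[1, j], class_b = pairs[2, j],
                             t = unname(res$statistic),
                             df = unname(res$parameter),
                             p = res$p.value)
  }
  list(tests = do.call(rbind, tests), summary = smry)
}
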