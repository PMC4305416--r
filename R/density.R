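# Quartic-kernel intensity estimation of the cancer-cell landscape and the
# per-lymphocyte proximity-to-cancer values derived from it.

#' Quartic (biweight) kernel weight
#'
#' The radially symmetric quartic kernel on the plane,
#' `K(u) = (3/pi) (1 - ||u||^2)^2` for `||u|| <= 1` and 0 beyond, which
#' integrates to 1 over the plane. Offsets are in bandwidth units.
#'
#' @param ux,uy Numeric offset components (recycled to common length).
#' @return Kernel weights.
#' @examples
#' quartic_kernel(0, 0)      # 3/pi
#' quartic_kernel(1, 0)      # 0 (compact support)
#' @export
quartic_kernel <- function(ux, uy) {
  r2 <- ux^2 + uy^2
  ifelse(r2 >= 1, 0, (3 / pi) * (1 - r2)^2)
}

as_xy <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2) stop("positions must be a 2-column matrix (x, y)")
  storage.mode(p) <- "double"
  p
}

#' Kernel intensity of cancer cells at query points
#'
#' Evaluates `f(p) = h^-2 * sum_i K((p - x_i)/h)` exactly at each query
#' point (no gridding or interpolation), where `K` is the quartic kernel
#' and the `x_i` are cancer-cell positions. The result is an intensity in
#' cells per square micrometre; no `1/n` factor is applied, which keeps
#' proximity values comparable when lymphocytes are pooled across tumours
#' with very different cancer counts.
#'
#' @param cancer 2-column matrix of cancer-cell positions (micrometres).
#' @param h Bandwidth in micrometres (> 0).
#' @param query 2-column matrix of query positions.
#' @return Numeric vector of intensities, one per query row.
#' @export
estimate_density <- function(cancer, h, query) {
  cancer <- as_xy(cancer)
  query <- as_xy(query)
  if (nrow(cancer) < 1)
    stop("at least one cancer cell is required for density estimation")
  if (!is.numeric(h) || length(h) != 1 || h <= 0) stop("h must be > 0")
  cpp_quartic_density(cancer[, 1], cancer[, 2], query[, 1], query[, 2], h)
}

#' Cancer-density surface on a regular grid
#'
#' Evaluates the cancer-cell kernel intensity at the nodes of a regular
#' grid spanning the map window. Node values are exactly
#' [estimate_density()] at the node coordinates; the grid exists for maps
#' and contour extraction only, never for scoring.
#'
#' @param map A [cell_map] with at least one cancer cell.
#' @param h Bandwidth in micrometres.
#' @param spacing Grid spacing in micrometres (> 0, not larger than the
#'   window extent).
#' @return An object of class `density_field`: list with `origin`,
#'   `spacing`, `x`, `y` (node coordinates) and `values` (matrix, rows
#'   indexed by x, columns by y), plus the bandwidth `h`.
#' @export
density_grid <- function(map, h, spacing) {
  stopifnot(inherits(map, "cell_map"))
  if (spacing <= 0) stop("spacing must be > 0")
  w <- map$window
  if (spacing > (w[3] - w[1]) || spacing > (w[4] - w[2]))
    stop("spacing is larger than the window extent")
  gx <- seq(w[1], w[3], by = spacing)
  gy <- seq(w[2], w[4], by = spacing)
  nodes <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  vals <- estimate_density(cell_xy(map, "cancer"), h, nodes)
  structure(list(origin = c(w[1], w[2]), spacing = spacing,
                 x = gx, y = gy, h = h,
                 values = matrix(vals, nrow = length(gx))),
            class = "density_field")
}

#' Per-lymphocyte spatial proximity to cancer
#'
#' The proximity of lymphocyte i is `s_i = f(y_i)`: the exact quartic-kernel
#' cancer intensity evaluated at the lymphocyte's position. Order follows
#' the lymphocyte rows of the cell map.
#'
#' @param map A [cell_map] with at least one cancer cell.
#' @param h Bandwidth in micrometres (default 50).
#' @return An object of class `proximity_sample`: data frame with columns
#'   `cell_id` (the lymphocyte's id in the map), `row` (its row in
#'   `map$cells`), and `s` (cells per square micrometre); the tumour id and
#'   bandwidth are kept as attributes.
#' @export
proximity_to_cancer <- function(map, h = 50) {
  stopifnot(inherits(map, "cell_map"))
  cancer <- cell_xy(map, "cancer")
  if (nrow(cancer) == 0) stop("no cancer cells: proximity is undefined")
  rows <- which(map$cells$class == "lymphocyte")
  if (length(rows) == 0) {
    warning("no lymphocytes in map '", map$tumour_id, "'")
    s <- numeric(0)
  } else {
    s <- estimate_density(cancer, h,
                          cbind(map$cells$x[rows], map$cells$y[rows]))
  }
  out <- data.frame(cell_id = map$cells$cell_id[rows], row = rows, s = s)
  attr(out, "tumour_id") <- map$tumour_id
  attr(out, "h") <- h
  class(out) <- c("proximity_sample", "data.frame")
  out
}

# leave-one-out point-process least-squares CV score for one map at one h:
# integral of fhat^2 over the window (grid approximation) minus twice the
# sum over points of the leave-one-out intensity at the point
lscv_score <- function(xy, window, h, grid_frac = 0.2) {
  sp <- h * grid_frac
  gx <- seq(window[1], window[3], by = sp)
  gy <- seq(window[2], window[4], by = sp)
  nodes <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  fhat <- cpp_quartic_density(xy[, 1], xy[, 2], nodes[, 1], nodes[, 2], h)
  int_f2 <- sum(fhat^2) * sp^2
  f_at_pts <- cpp_quartic_density(xy[, 1], xy[, 2], xy[, 1], xy[, 2], h)
  loo <- f_at_pts - (3 / pi) / h^2   # remove each point's own kernel
  int_f2 - 2 * sum(loo)
}

#' Bandwidth selection by least-squares cross-validation
#'
#' For each candidate bandwidth the point-process least-squares
#' cross-validation criterion (an unbiased-up-to-constants estimate of the
#' integrated squared error of the intensity estimate) is computed on a
#' random subset of maps and averaged; the bandwidth minimising the average
#' criterion is returned. The integral term is evaluated on a grid of
#' spacing `0.2 * h`.
#'
#' @param maps List of [cell_map] objects.
#' @param h_grid Candidate bandwidths in micrometres.
#' @param n_images Number of maps sampled (without replacement) for the
#'   criterion average.
#' @param seed Integer seed controlling which maps are sampled.
#' @return List with `h` (chosen bandwidth), and `criterion` (data frame
#'   `h`, `score` for inspection).
#' @export
select_bandwidth <- function(maps, h_grid, n_images = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!length(h_grid)) stop("h_grid must be non-empty")
  if (!length(maps)) stop("at least one map is required")
  if (inherits(maps, "cell_map")) maps <- list(maps)
  pick <- sample(seq_along(maps), min(n_images, length(maps)))
  used <- list()
  for (i in pick) {
    xy <- cell_xy(maps[[i]], "cancer")
    if (nrow(xy) < 2) {
      warning("map '", maps[[i]]$tumour_id,
              "' has fewer than 2 cancer cells; skipped")
      next
    }
    used[[length(used) + 1]] <- list(xy = xy, window = maps[[i]]$window)
  }
  if (!length(used)) stop("no usable maps (all have < 2 cancer cells)")
  h_grid <- sort(as.numeric(h_grid))
  score <- vapply(h_grid, function(h) {
    mean(vapply(used, function(u) lscv_score(u$xy, u$window, h), 0))
  }, 0)
  list(h = h_grid[which.min(score)],
       criterion = data.frame(h = h_grid, score = score))
}
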