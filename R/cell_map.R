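#' Construct a cell map
#'
#' A cell map holds the typed cell coordinates of one tumour section (or of
#' several sections pooled per tumour): cancer cells, lymphocytes and stromal
#' cells, with positions in micrometres. Image convention applies (origin
#' top-left, x rightward, y downward), but all geometry in the package is
#' convention-agnostic, so this only matters when plotting.
#'
#' @param x,y Numeric coordinates in micrometres.
#' @param cell_class Character or factor; each entry one of `"cancer"`,
#'   `"lymphocyte"`, `"stromal"`.
#' @param tumour_id Single string identifying the tumour.
#' @param window Numeric length-4 vector `c(xmin, ymin, xmax, ymax)` in
#'   micrometres; defaults to the bounding box of the cells.
#' @param cell_id Optional identifiers (default `1:n`).
#' @param section Optional section labels, preserved when multiple sections
#'   of one tumour are pooled.
#' @return An object of class `cell_map`: a list with elements `tumour_id`,
#'   `cells` (data frame with columns `cell_id`, `x`, `y`, `class`, and
#'   `section` if supplied) and `window`.
#' @examples
#' m <- cell_map(c(0, 10, 20), c(0, 5, 9),
#'               c("cancer", "lymphocyte", "stromal"), "t1")
#' summarize_cell_map(m)
#' @export
cell_map <- function(x, y, cell_class, tumour_id = "tumour",
                     window = NULL, cell_id = NULL, section = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  cell_class <- as.character(cell_class)
  n <- length(x)
  if (length(y) != n || length(cell_class) != n)
    stop("x, y and cell_class must have equal length")
  if (n > 0 && any(!is.finite(x) | !is.finite(y)))
    stop("all coordinates must be finite")
  bad <- which(!cell_class %in% CELL_CLASSES)
  if (length(bad))
    stop(sprintf("unknown cell class '%s' (row %d); expected one of %s",
                 cell_class[bad[1]], bad[1],
                 paste(CELL_CLASSES, collapse = ", ")))
  if (is.null(window)) {
    window <- if (n > 0) c(min(x), min(y), max(x), max(y)) else c(0, 0, 0, 0)
  }
  window <- as.numeric(window)
  if (length(window) != 4 || window[1] > window[3] || window[2] > window[4])
    stop("window must be c(xmin, ymin, xmax, ymax) with xmin <= xmax, ymin <= ymax")
  if (n > 0 && (any(x < window[1] | x > window[3]) ||
                any(y < window[2] | y > window[4])))
    stop("all cells must lie inside the window")
  cells <- data.frame(
    cell_id = if (is.null(cell_id)) seq_len(n) else cell_id,
    x = x, y = y, class = cell_class,
    stringsAsFactors = FALSE)
  if (!is.null(section)) cells$section <- section
  structure(list(tumour_id = as.character(tumour_id)[1],
                 cells = cells, window = window),
            class = "cell_map")
}

#' @export
print.cell_map <- function(x, ...) {
  s <- table(factor(x$cells$class, levels = CELL_CLASSES))
  cat(sprintf("<cell_map '%s'>  %d cells (%d cancer, %d lymphocyte, %d stromal)\n",
              x$tumour_id, nrow(x$cells), s["cancer"], s["lymphocyte"],
              s["stromal"]))
  cat(sprintf("  window: [%g, %g] x [%g, %g] um\n",
              x$window[1], x$window[3], x$window[2], x$window[4]))
  invisible(x)
}

cell_xy <- function(map, class) {
  cc <- map$cells[map$cells$class == class, , drop = FALSE]
  cbind(x = cc$x, y = cc$y)
}

#' Read a cell-coordinate table
#'
#' Reads a comma-separated table with required columns `x`, `y`, `class`
#' (and optional `cell_id`, `section`) into a validated [cell_map].
#' Coordinates recorded in pixels are converted to micrometres via
#' `px_size`.
#'
#' @param path Path to a CSV file with a header row.
#' @param units `"um"` (default) or `"px"`.
#' @param px_size Pixel size in micrometres per pixel; required when
#'   `units = "px"`.
#' @param tumour_id Tumour identifier; defaults to the file name without
#'   extension.
#' @param window Optional window override, `c(xmin, ymin, xmax, ymax)` in
#'   micrometres.
#' @return A [cell_map].
#' @export
read_cell_map <- function(path, units = c("um", "px"), px_size = NULL,
                          tumour_id = NULL, window = NULL) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  if (units == "px" && (is.null(px_size) || px_size <= 0))
    stop("px_size (um per pixel) must be given when units = 'px'")
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("x", "y", "class")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (col in c("x", "y")) {
    v <- d[[col]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      if (anyNA(v2))
        stop(sprintf("non-numeric %s coordinate at row %d",
                     col, which(is.na(v2))[1]))
      d[[col]] <- v2
    }
  }
  scale <- if (units == "px") px_size else 1
  if (is.null(tumour_id))
    tumour_id <- sub("\\.[^.]*$", "", basename(path))
  cell_map(d$x * scale, d$y * scale, d$class, tumour_id = tumour_id,
           window = window,
           cell_id = if ("cell_id" %in% names(d)) d$cell_id else NULL,
           section = if ("section" %in% names(d)) d$section else NULL)
}

#' Write a cell map to CSV
#'
#' Writes the cell table (`cell_id,x,y,class` plus `section` if present) in
#' micrometres with full double precision, so `read_cell_map()` of the
#' output reproduces the coordinates bit-exactly.
#'
#' @param map A [cell_map].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cell_map <- function(map, path) {
  stopifnot(inherits(map, "cell_map"))
  d <- map$cells
  d$x <- format(d$x, digits = 17, scientific = FALSE, trim = TRUE)
  d$y <- format(d$y, digits = 17, scientific = FALSE, trim = TRUE)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize a cell map
#'
#' @param map A [cell_map].
#' @return A list with `tumour_id`, per-class `counts`, `n_total`,
#'   `area_um2` (window area), and per-class `intensity` in cells per square
#'   micrometre.
#' @export
summarize_cell_map <- function(map) {
  stopifnot(inherits(map, "cell_map"))
  counts <- table(factor(map$cells$class, levels = CELL_CLASSES))
  counts <- setNames(as.integer(counts), CELL_CLASSES)
  if (sum(counts) == 0) warning("empty cell map: all counts are zero")
  area <- (map$window[3] - map$window[1]) * (map$window[4] - map$window[2])
  list(tumour_id = map$tumour_id,
       counts = counts,
       n_total = sum(counts),
       area_um2 = area,
       intensity = if (area > 0) counts / area else counts * NA_real_)
}
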