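# Per-tumour infiltration scores and the trend test linking them to
# ordered clinical categories.

#' Per-tumour infiltration scores
#'
#' Summarises one tumour by the ratios of classified lymphocytes to cancer
#' cells: `ITLR = n_ITL / n_cancer` (the intratumour lymphocyte ratio, the
#' prognostic score), likewise ATLR and DTLR, and the class-agnostic
#' lymphocyte abundance `Lym = (n_ITL + n_ATL + n_DTL) / n_cancer`, so that
#' `ITLR + ATLR + DTLR = Lym`. The class composition (proportions of
#' ITL/ATL/DTL among lymphocytes) is reported alongside.
#'
#' @param labels A `classified_lymphocytes` object from [assign_classes()],
#'   or a factor/character vector of ITL/ATL/DTL labels.
#' @param n_cancer Number of cancer cells in the tumour (> 0).
#' @param tumour_id Tumour identifier.
#' @return A one-row data frame with columns `tumour_id`, `n_cancer`,
#'   `n_itl`, `n_atl`, `n_dtl`, `itlr`, `atlr`, `dtlr`, `lym`, `p_itl`,
#'   `p_atl`, `p_dtl`.
#' @examples
#' compute_scores(rep(c("ITL", "ATL", "DTL"), c(110, 300, 90)), 10000, "t1")
#' @export
compute_scores <- function(labels, n_cancer, tumour_id = "tumour") {
  if (inherits(labels, "classified_lymphocytes")) labels <- labels$til_class
  labels <- factor(as.character(labels), levels = TIL_CLASSES)
  if (anyNA(labels)) stop("labels must be ITL, ATL or DTL")
  if (n_cancer <= 0) stop("n_cancer must be > 0: ratios are undefined")
  cnt <- table(labels)
  m <- sum(cnt)
  data.frame(tumour_id = tumour_id,
             n_cancer = n_cancer,
             n_itl = as.integer(cnt["ITL"]),
             n_atl = as.integer(cnt["ATL"]),
             n_dtl = as.integer(cnt["DTL"]),
             itlr = as.numeric(cnt["ITL"]) / n_cancer,
             atlr = as.numeric(cnt["ATL"]) / n_cancer,
             dtlr = as.numeric(cnt["DTL"]) / n_cancer,
             lym = m / n_cancer,
             p_itl = if (m > 0) as.numeric(cnt["ITL"]) / m else NA_real_,
             p_atl = if (m > 0) as.numeric(cnt["ATL"]) / m else NA_real_,
             p_dtl = if (m > 0) as.numeric(cnt["DTL"]) / m else NA_real_,
             stringsAsFactors = FALSE)
}

jt_statistic <- function(x, g) {
  lev <- levels(g)
  J <- 0
  for (i in seq_along(lev)[-length(lev)]) {
    xi <- x[g == lev[i]]
    for (j in (i + 1):length(lev)) {
      xj <- x[g == lev[j]]
      J <- J + sum(outer(xi, xj, "<")) + 0.5 * sum(outer(xi, xj, "=="))
    }
  }
  J
}

jt_exact_upper_p <- function(x, sizes, observed) {
  # full enumeration of assignments of the pooled values to the ordered
  # groups; counts assignments with J >= observed
  total <- 0L
  hits <- 0L
  enum <- function(idx, si, acc) {
    if (si == length(sizes)) {
      acc[[si]] <- idx
      g <- integer(length(x))
      for (k in seq_along(acc)) g[acc[[k]]] <- k
      J <- jt_statistic(x, factor(g, levels = seq_along(sizes)))
      total <<- total + 1L
      if (J >= observed - 1e-9) hits <<- hits + 1L
      return(invisible())
    }
    cs <- combn(idx, sizes[si])
    for (c in seq_len(ncol(cs))) {
      acc[[si]] <- cs[, c]
      enum(setdiff(idx, cs[, c]), si + 1L, acc)
    }
  }
  enum(seq_along(x), 1L, vector("list", length(sizes)))
  hits / total
}

#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone trend of a score across ordered categories. The
#' statistic is the sum over ordered category pairs of Mann-Whitney counts
#' (ties counted 1/2). With 10 or fewer observations the one-sided
#' upper-tail p-value is computed by full enumeration of group
#' assignments; otherwise a normal approximation with the standard tie
#' correction is used.
#'
#' @param score Numeric score per subject.
#' @param category Ordered categories (ordered factor, or anything
#'   coercible; factor level order is taken as the hypothesised order).
#' @param alternative `"two.sided"` (default), `"increasing"` or
#'   `"decreasing"`.
#' @return List with `statistic` (JT), `p`, `alternative`, `method`
#'   (`"exact"` or `"normal"`), and the null `mean` and `sd`.
#' @examples
#' jt_trend_test(c(1, 2, 3, 4, 5, 6), rep(c("absent", "mild", "severe"), each = 2))
#' @export
jt_trend_test <- function(score, category,
                          alternative = c("two.sided", "increasing",
                                          "decreasing")) {
  alternative <- match.arg(alternative)
  g <- if (is.factor(category)) factor(category) else
    factor(category, levels = unique(category))
  g <- droplevels(g)
  if (nlevels(g) < 2) stop("need at least 2 non-empty ordered categories")
  stopifnot(length(score) == length(g))
  sizes <- as.integer(table(g))
  N <- length(score)
  J <- jt_statistic(score, g)

  mu <- (N^2 - sum(sizes^2)) / 4
  tie <- as.numeric(table(score))
  s2 <- (N * (N - 1) * (2 * N + 5) -
         sum(sizes * (sizes - 1) * (2 * sizes + 5)) -
         sum(tie * (tie - 1) * (2 * tie + 5))) / 72 +
        sum(sizes * (sizes - 1) * (sizes - 2)) *
          sum(tie * (tie - 1) * (tie - 2)) /
          (36 * N * (N - 1) * (N - 2)) +
        sum(sizes * (sizes - 1)) * sum(tie * (tie - 1)) /
          (8 * N * (N - 1))
  sdv <- sqrt(s2)

  if (N <= 10) {
    method <- "exact"
    p_up <- jt_exact_upper_p(score, sizes, J)
    # lower tail by symmetry of enumeration on the reflected statistic
    p_dn <- jt_exact_upper_p(-score, sizes, jt_statistic(-score, g))
  } else {
    method <- "normal"
    z <- (J - mu) / sdv
    p_up <- pnorm(z, lower.tail = FALSE)
    p_dn <- pnorm(z)
  }
  p <- switch(alternative,
              increasing = p_up,
              decreasing = p_dn,
              two.sided = min(1, 2 * min(p_up, p_dn)))
  list(statistic = J, p = p, alternative = alternative, method = method,
       mean = mu, sd = sdv)
}
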