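# Unsupervised discovery of lymphocyte classes: univariate Gaussian mixture
# fitted by EM on pooled proximity-to-cancer values, BIC model selection in
# the higher-is-better convention 2*logL - d*logN (d = 3K - 1), resampling
# stability, and interval-threshold assignment to ITL/ATL/DTL.

gmm_quantile_init <- function(s, K, jitter = 0) {
  probs <- (seq_len(K) - 0.5) / K
  if (jitter > 0)
    probs <- pmin(0.999, pmax(0.001, probs + runif(K, -jitter, jitter)))
  mu <- quantile(s, probs, names = FALSE, type = 7)
  v <- rep((sd(s) / K)^2, K)
  list(w = rep(1 / K, K), mu = mu, var = v)
}

#' Fit a univariate Gaussian mixture by EM
#'
#' Fits a K-component mixture to pooled proximity values with
#' expectation-maximization, taking the best of several quantile-spread
#' initializations (each restart runs a short EM; the best continues to
#' full convergence). Components are stored sorted by mean, descending, so
#' component 1 is the highest-proximity (intratumour-like) cluster.
#'
#' @param s Numeric values (pooled proximity-to-cancer sample).
#' @param K Number of components; the sample must satisfy
#'   `length(s) >= 10 * (3K - 1)`.
#' @param seed Integer seed for the restart jitter.
#' @param restarts Number of EM initializations (default 10).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations for the final run.
#' @param var_floor_frac Variance floor as a fraction of `var(s)`.
#' @return Object of class `gmm_fit`: weights `w`, means `mu`, variances
#'   `sigma2` (all sorted by mean descending), `loglik`, `K`,
#'   `d` (= 3K - 1 free parameters), `n`, `bic` (= 2*loglik - d*log(n),
#'   higher is better), `iterations`, `trace` (log-likelihood per EM
#'   iteration of the final run), `converged`, `seed`.
#' @export
fit_gmm <- function(s, K, seed = NULL, restarts = 10, tol = 1e-8,
                    max_iter = 1000, var_floor_frac = 1e-12) {
  if (!is.null(seed)) set.seed(seed)
  s <- as.numeric(s)
  n <- length(s)
  d <- 3 * K - 1
  if (n < 10 * d)
    stop(sprintf("need at least %d observations to fit K = %d (got %d)",
                 10 * d, K, n))
  if (K == 1) {
    mu <- mean(s)
    v <- mean((s - mu)^2)          # MLE variance
    ll <- sum(dnorm(s, mu, sqrt(v), log = TRUE))
    return(structure(list(w = 1, mu = mu, sigma2 = v, loglik = ll, K = 1L,
                          d = 2L, n = n, bic = 2 * ll - 2 * log(n),
                          iterations = 0L, trace = ll, converged = TRUE,
                          seed = seed),
                     class = "gmm_fit"))
  }
  var_floor <- var_floor_frac * var(s)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- gmm_quantile_init(s, K, jitter = if (r == 1) 0 else 0.5 / K)
    fit <- cpp_em_gmm(s, init$w, init$mu, init$var,
                      30L, 1e-6, var_floor)
    if (fit$collapsed) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop("EM collapsed in every restart (component weight -> 0)")
  fit <- cpp_em_gmm(s, best$w, best$mu, best$var, max_iter, tol, var_floor)
  if (fit$collapsed)
    stop("EM collapsed during the final run (component weight -> 0)")
  ord <- order(fit$mu, decreasing = TRUE)
  ll <- fit$loglik
  structure(list(w = fit$w[ord], mu = fit$mu[ord], sigma2 = fit$var[ord],
                 loglik = ll, K = as.integer(K), d = as.integer(d), n = n,
                 bic = 2 * ll - d * log(n),
                 iterations = fit$iterations, trace = fit$trace,
                 converged = fit$converged, seed = seed),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("<gmm_fit> K = %d, n = %d, logLik = %.2f, BIC = %.2f\n",
              x$K, x$n, x$loglik, x$bic))
  print(data.frame(weight = x$w, mean = x$mu, sd = sqrt(x$sigma2)))
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits K = 1..`k_max` and returns the K maximising
#' `BIC = 2*logL - d*log(n)` (higher is better). BIC ties within `1e-6`
#' resolve to the smaller K.
#'
#' @inheritParams fit_gmm
#' @param k_max Largest K considered (default 5).
#' @param ... Passed to [fit_gmm()] (restarts, tol, ...).
#' @return List with `best_k`, `bic` (named vector over K), and `fits`
#'   (list of `gmm_fit` objects).
#' @export
select_k <- function(s, k_max = 5, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(seq_len(k_max), function(K) fit_gmm(s, K, seed = NULL, ...))
  bic <- vapply(fits, `[[`, 0, "bic")
  names(bic) <- seq_len(k_max)
  best_k <- which(bic >= max(bic) - 1e-6)[1]
  list(best_k = as.integer(best_k), bic = bic, fits = fits)
}

#' Resampling stability of the class structure
#'
#' Repeatedly subsamples the pooled proximity values without replacement,
#' reruns BIC model selection, and records the best K together with the
#' sorted component means of the K = 3 fit, summarising how stable the
#' three-class solution is under resampling.
#'
#' @param pooled_s Pooled proximity values.
#' @param sample_size Values drawn per repetition (clipped with a warning
#'   if the pool is smaller).
#' @param reps Number of repetitions (default 200).
#' @param k_max Largest K considered.
#' @param seed Integer seed; same seed, identical report.
#' @param ... Passed to [fit_gmm()].
#' @return Object of class `stability_report`: `best_k` (per repetition),
#'   `means3` (reps x 3 matrix of K = 3 component means, descending),
#'   `modal_k`, `frac_modal`, and `mean_median`/`mean_sd` (per sorted
#'   component, across repetitions).
#' @export
stability_analysis <- function(pooled_s, sample_size = 100000, reps = 200,
                               k_max = 5, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(pooled_s)
  if (sample_size > n) {
    warning("sample_size exceeds pool size; clipped to ", n)
    sample_size <- n
  }
  best_k <- integer(reps)
  means3 <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    sub <- pooled_s[sample.int(n, sample_size)]
    sel <- select_k(sub, k_max = k_max, ...)
    best_k[r] <- sel$best_k
    if (k_max >= 3) means3[r, ] <- sel$fits[[3]]$mu
  }
  tab <- table(best_k)
  modal_k <- as.integer(names(tab)[which.max(tab)])
  structure(list(best_k = best_k, means3 = means3, modal_k = modal_k,
                 frac_modal = max(tab) / reps,
                 mean_median = apply(means3, 2, median),
                 mean_sd = apply(means3, 2, sd),
                 reps = reps, sample_size = sample_size),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d reps at n = %d: modal K = %d (%.1f%%)\n",
              x$reps, x$sample_size, x$modal_k, 100 * x$frac_modal))
  cat("K = 3 component means (median across reps):",
      paste(signif(x$mean_median, 3), collapse = ", "), "\n")
  invisible(x)
}

# crossing of w_a N(t; mu_a, v_a) and w_b N(t; mu_b, v_b) between the means
density_crossing <- function(w_a, mu_a, v_a, w_b, mu_b, v_b) {
  lo <- min(mu_a, mu_b); hi <- max(mu_a, mu_b)
  A <- 0.5 / v_b - 0.5 / v_a
  B <- mu_a / v_a - mu_b / v_b
  C <- mu_b^2 / (2 * v_b) - mu_a^2 / (2 * v_a) +
       log(w_a / w_b) + 0.5 * log(v_b / v_a)
  if (abs(A) < 1e-300) {
    if (abs(B) < 1e-300) return(NA_real_)
    t <- -C / B
    return(if (t > lo && t < hi) t else NA_real_)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(NA_real_)
  roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  roots <- roots[roots > lo & roots < hi]
  if (!length(roots)) NA_real_ else roots[1]
}

#' Class thresholds from a three-component mixture
#'
#' The upper threshold is the crossing point, between their means, of the
#' weighted normal densities of the two highest-mean components; the lower
#' threshold likewise for the two lowest. If a crossing does not exist
#' between the means (pathological fit) the midpoint of the two means is
#' used with a warning. Thresholds always satisfy
#' `mu_DTL < t_low < mu_ATL < t_high < mu_ITL`.
#'
#' @param model A `gmm_fit` with `K = 3`.
#' @return Numeric `c(t_low, t_high)` on the proximity scale.
#' @export
class_thresholds <- function(model) {
  stopifnot(inherits(model, "gmm_fit"))
  if (model$K != 3) stop("class thresholds require a K = 3 mixture")
  # components sorted by mean descending: 1 = ITL, 2 = ATL, 3 = DTL
  t_high <- density_crossing(model$w[1], model$mu[1], model$sigma2[1],
                             model$w[2], model$mu[2], model$sigma2[2])
  if (is.na(t_high)) {
    warning("no density crossing between the top two components; ",
            "using the midpoint of their means")
    t_high <- (model$mu[1] + model$mu[2]) / 2
  }
  t_low <- density_crossing(model$w[2], model$mu[2], model$sigma2[2],
                            model$w[3], model$mu[3], model$sigma2[3])
  if (is.na(t_low)) {
    warning("no density crossing between the bottom two components; ",
            "using the midpoint of their means")
    t_low <- (model$mu[2] + model$mu[3]) / 2
  }
  c(t_low = t_low, t_high = t_high)
}

gmm_posteriors <- function(model, s) {
  K <- model$K
  ld <- vapply(seq_len(K), function(k) {
    log(model$w[k]) + dnorm(s, model$mu[k], sqrt(model$sigma2[k]), log = TRUE)
  }, numeric(length(s)))
  ld <- matrix(ld, ncol = K)
  mx <- apply(ld, 1, max)
  p <- exp(ld - mx)
  p / rowSums(p)
}

#' Assign lymphocytes to ITL/ATL/DTL
#'
#' Interval-threshold assignment: `s >= t_high` is ITL, `t_low <= s <
#' t_high` is ATL, `s < t_low` is DTL. Interval thresholds (adjacent-
#' component density crossings) guarantee contiguous classes on the
#' proximity axis; raw maximum-posterior assignment is available via
#' `method = "posterior"`.
#'
#' @param thresholds `c(t_low, t_high)` from [class_thresholds()], or a
#'   `gmm_fit` with K = 3 (thresholds are then computed from it).
#' @param s Proximity values of the lymphocytes to classify.
#' @param model Optional `gmm_fit` used to report posterior probabilities
#'   (and for `method = "posterior"`).
#' @param method `"threshold"` (default) or `"posterior"`.
#' @return Object of class `classified_lymphocytes`: `til_class` (factor
#'   ITL/ATL/DTL), `thresholds`, and `posterior` (matrix m x 3, or NULL if
#'   no model was given).
#' @export
assign_classes <- function(thresholds, s, model = NULL,
                           method = c("threshold", "posterior")) {
  method <- match.arg(method)
  if (inherits(thresholds, "gmm_fit")) {
    model <- thresholds
    thresholds <- class_thresholds(model)
  }
  post <- if (!is.null(model)) {
    p <- gmm_posteriors(model, s)
    colnames(p) <- TIL_CLASSES[seq_len(ncol(p))]
    p
  } else NULL
  if (method == "posterior") {
    if (is.null(model)) stop("posterior assignment requires a model")
    lab <- TIL_CLASSES[max.col(post)]
  } else {
    lab <- ifelse(s >= thresholds[2], "ITL",
                  ifelse(s >= thresholds[1], "ATL", "DTL"))
  }
  structure(list(til_class = factor(lab, levels = TIL_CLASSES),
                 thresholds = thresholds, posterior = post, s = s),
            class = "classified_lymphocytes")
}
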