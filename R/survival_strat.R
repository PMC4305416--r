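# Dichotomization of a continuous score by a percentile cut-off scan,
# Kaplan-Meier / log-rank stratification, Cox models and bootstrap
# robustness. Model fitting goes through the survival package; the scan,
# the discovery/validation discipline and the cut-off consistency mapping
# are implemented here.

check_clinical <- function(clinical) {
  req <- c("time_months", "event")
  miss <- setdiff(req, names(clinical))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (any(clinical$time_months <= 0)) stop("survival times must be > 0")
  if (!all(clinical$event %in% c(0, 1))) stop("event must be 0/1")
  clinical
}

#' Administrative censoring of a clinical table
#'
#' Truncates follow-up at `months` (default 120, i.e. 10-year
#' disease-specific survival): longer times are censored at the horizon.
#'
#' @param clinical Data frame with `time_months` and `event`.
#' @param months Censoring horizon.
#' @return The clinical table with truncated `time_months`/`event`.
#' @export
censor_at <- function(clinical, months = 120) {
  check_clinical(clinical)
  over <- clinical$time_months > months
  clinical$event[over] <- 0L
  clinical$time_months[over] <- months
  clinical
}

#' Kaplan-Meier estimates and log-rank test
#'
#' @param group Group label per subject (factor or coercible).
#' @param clinical Data frame with `time_months` and `event`.
#' @return List with `fit` (a [survival::survfit] object), `chisq`, `df`
#'   and `p` (log-rank). When every subject is censored in every group the
#'   log-rank p is undefined and reported as `NA`.
#' @export
km_logrank <- function(group, clinical) {
  check_clinical(clinical)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2)
    stop("need at least 2 non-empty groups")
  d <- data.frame(time = clinical$time_months, event = clinical$event,
                  group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  if (sum(d$event) == 0) {
    return(list(fit = fit, chisq = NA_real_, df = nlevels(group) - 1,
                p = NA_real_))
  }
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(lr$n) - 1
  list(fit = fit, chisq = lr$chisq, df = df,
       p = pchisq(lr$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards model for a score group and clinical covariates
#'
#' Fits a Cox model (Efron tie handling) with the high-score group coded 1,
#' so a hazard ratio below 1 means the high score is protective. Optional
#' covariates `node` (binary) and `size` (continuous, cm) give the
#' multivariate model. Non-convergence / monotone likelihood is flagged
#' rather than raised, and shows up as degenerate confidence intervals
#' (e.g. 0 (0-Inf)).
#'
#' @param clinical Data frame with `time_months`, `event`, and any
#'   covariate columns used.
#' @param high Logical/0-1 vector: high-score group indicator.
#' @param covariates Character vector of additional clinical columns
#'   (e.g. `c("node", "size")`).
#' @return List with `table` (data frame: term, hr, lo95, hi95, p),
#'   `concordance`, `converged`, and the fitted `model`.
#' @export
cox_model <- function(clinical, high, covariates = character(0)) {
  check_clinical(clinical)
  d <- data.frame(time = clinical$time_months, event = clinical$event,
                  high = as.numeric(high))
  for (cv in covariates) d[[cv]] <- clinical[[cv]]
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~ high",
                                 if (length(covariates))
                                   paste("+", paste(covariates, collapse = " + "))
                                 else ""))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|Loglik", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  tab <- data.frame(term = rownames(sm$coefficients),
                    hr = sm$conf.int[, "exp(coef)"],
                    lo95 = sm$conf.int[, 3],
                    hi95 = sm$conf.int[, 4],
                    p = sm$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  list(table = tab, concordance = unname(sm$concordance["C"]),
       converged = converged, model = fit)
}

#' Percentile cut-off scan for score dichotomization
#'
#' Scans candidate cut-offs at the score percentiles `lo, lo + step, ...,
#' hi` (defaults 20 to 80 by 1.5: 41 candidates). At each candidate,
#' patients are split into score-low (`< cutoff`) and score-high
#' (`>= cutoff`) and compared by log-rank; the candidate with the smallest
#' p is chosen (ties resolve to the lower percentile). Candidates leaving
#' a group empty are skipped. The scan minimises p over many tests, so the
#' chosen p is optimistically biased; freeze the chosen cut-off in a
#' discovery cohort and re-test it in a validation cohort
#' (see [apply_cutoff()]).
#'
#' @param score Numeric per-patient score.
#' @param clinical Data frame with `time_months` and `event`, same order.
#' @param lo,hi,step Percentile grid (percent units).
#' @return Object of class `cutoff_result`: `scan` (data frame percentile,
#'   cutoff, p), `percentile`, `cutoff`, `p`, `n_low`, `n_high`, `hr`
#'   (with `lo95`/`hi95`, high vs low), and `km` (the chosen split's
#'   [km_logrank()] result).
#' @export
scan_cutoff <- function(score, clinical, lo = 20, hi = 80, step = 1.5) {
  check_clinical(clinical)
  if (length(score) != nrow(clinical))
    stop("score and clinical must align")
  if (length(score) < 20) stop("need at least 20 patients")
  if (sd(score) == 0) stop("score is constant; no cut-off exists")
  pct <- seq(lo, hi, by = step)
  scan <- data.frame(percentile = pct,
                     cutoff = quantile(score, pct / 100, names = FALSE),
                     p = NA_real_)
  for (i in seq_along(pct)) {
    grp <- score >= scan$cutoff[i]
    if (all(grp) || !any(grp)) next
    scan$p[i] <- km_logrank(factor(grp, levels = c(FALSE, TRUE),
                                   labels = c("low", "high")),
                            clinical)$p
  }
  if (all(is.na(scan$p))) stop("no candidate produced two non-empty groups")
  best <- which.min(scan$p)   # ties: first = lowest percentile
  cutoff <- scan$cutoff[best]
  high <- score >= cutoff
  cox <- cox_model(clinical, high)
  structure(list(scan = scan,
                 percentile = scan$percentile[best],
                 cutoff = cutoff,
                 p = scan$p[best],
                 n_low = sum(!high), n_high = sum(high),
                 hr = cox$table$hr[1],
                 hr_lo95 = cox$table$lo95[1], hr_hi95 = cox$table$hi95[1],
                 km = km_logrank(factor(high, levels = c(FALSE, TRUE),
                                        labels = c("low", "high")),
                                 clinical)),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("<cutoff_result> cut-off %.4g at percentile %.1f (low %d / high %d)\n",
              x$cutoff, x$percentile, x$n_low, x$n_high))
  cat(sprintf("  log-rank p = %.3g; HR (high vs low) = %.3g (%.3g-%.3g)\n",
              x$p, x$hr, x$hr_lo95, x$hr_hi95))
  invisible(x)
}

#' Apply a frozen cut-off to a validation cohort
#'
#' @param cutoff Score cut-off chosen in the discovery cohort.
#' @param score,clinical Validation-cohort score and clinical table.
#' @return List with `p` (log-rank), `hr` (+ CI), `n_low`, `n_high`.
#' @export
apply_cutoff <- function(cutoff, score, clinical) {
  high <- score >= cutoff
  if (all(high) || !any(high))
    stop("cut-off leaves an empty group in the validation cohort")
  cox <- cox_model(clinical, high)
  km <- km_logrank(factor(high, levels = c(FALSE, TRUE),
                          labels = c("low", "high")), clinical)
  list(p = km$p, hr = cox$table$hr[1], hr_lo95 = cox$table$lo95[1],
       hr_hi95 = cox$table$hi95[1], n_low = sum(!high), n_high = sum(high))
}

#' Bootstrap stability of the score's prognostic effect
#'
#' Resamples patients with replacement and refits the univariate Cox model
#' (score group only) and the multivariate model (score group + covariates)
#' on each resample, reporting the fraction of resamples in which the score
#' term is significant. Resamples where a model fails are counted as
#' non-significant and tallied separately.
#'
#' @param clinical Clinical table (with covariate columns).
#' @param high High-score group indicator.
#' @param covariates Covariates of the multivariate model.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @return List with `frac_uni`, `frac_multi`, `n_failed_uni`,
#'   `n_failed_multi`, `n_boot`, `alpha`.
#' @export
bootstrap_stability <- function(clinical, high, covariates = c("node", "size"),
                                n_boot = 1000, alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_clinical(clinical)
  n <- nrow(clinical)
  sig_u <- logical(n_boot); sig_m <- logical(n_boot)
  fail_u <- 0L; fail_m <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    cl <- clinical[idx, , drop = FALSE]
    hg <- high[idx]
    if (length(unique(hg)) < 2) { fail_u <- fail_u + 1L; fail_m <- fail_m + 1L; next }
    u <- tryCatch(cox_model(cl, hg), error = function(e) NULL)
    if (is.null(u)) fail_u <- fail_u + 1L
    else sig_u[b] <- isTRUE(u$table$p[u$table$term == "high"] < alpha) && u$converged
    m <- tryCatch(cox_model(cl, hg, covariates), error = function(e) NULL)
    if (is.null(m)) fail_m <- fail_m + 1L
    else sig_m[b] <- isTRUE(m$table$p[m$table$term == "high"] < alpha) && m$converged
  }
  list(frac_uni = mean(sig_u), frac_multi = mean(sig_m),
       n_failed_uni = fail_u, n_failed_multi = fail_m,
       n_boot = n_boot, alpha = alpha)
}

#' Cut-off consistency between two cohorts
#'
#' Each cohort's signature values are centred at 0 and scaled to unit
#' standard deviation; the chosen cut-offs are mapped through the same
#' affine transform, putting them on a common scale. Signatures whose
#' standardized cut-offs are close chose essentially the same threshold in
#' both cohorts.
#'
#' @param sig1,sig2 Signature values in cohort 1 and 2.
#' @param cutoff1,cutoff2 The cut-offs chosen in each cohort (score units).
#' @return List with `z1`, `z2` (standardized cut-offs) and `diff`
#'   (absolute difference).
#' @export
cutoff_consistency <- function(sig1, cutoff1, sig2, cutoff2) {
  if (sd(sig1) == 0 || sd(sig2) == 0)
    stop("zero-variance cohort: standardization undefined")
  z1 <- (cutoff1 - mean(sig1)) / sd(sig1)
  z2 <- (cutoff2 - mean(sig2)) / sd(sig2)
  list(z1 = z1, z2 = z2, diff = abs(z1 - z2))
}
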