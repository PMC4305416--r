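test_that("K = 1 fit is the closed-form Gaussian MLE", {
  set.seed(1)
  s <- rnorm(500, 3, 2)
  f <- fit_gmm(s, 1)
  expect_identical(f$mu, mean(s))
  expect_identical(f$sigma2, mean((s - mean(s))^2))
  expect_equal(f$bic, 2 * f$loglik - 2 * log(500))
})

test_that("EM log-likelihood trace is non-decreasing and converges", {
  set.seed(2)
  s <- rmix3(5000)
  f <- fit_gmm(s, 3, seed = 3)
  expect_true(all(diff(f$trace) >= -1e-7 * abs(f$trace[-length(f$trace)])))
  expect_true(f$converged)
  expect_true(all(diff(f$mu) < 0))      # sorted by mean, descending
  expect_equal(sum(f$w), 1, tolerance = 1e-12)
  expect_error(fit_gmm(rnorm(20), 3), "at least")
})

test_that("mixture agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(4)
  s <- rmix3(8000)
  f <- fit_gmm(s, 3, seed = 5)
  mc <- mclust::Mclust(s, G = 3, modelNames = "V", verbose = FALSE)
  expect_equal(sort(f$mu), sort(as.numeric(mc$parameters$mean)),
               tolerance = 1e-3)
  expect_equal(f$loglik, mc$loglik, tolerance = 1e-6 * abs(mc$loglik))
})

test_that("BIC selects the generating component count", {
  set.seed(6)
  sel3 <- select_k(rmix3(20000), seed = 7)
  expect_identical(sel3$best_k, 3L)
  sel1 <- select_k(rnorm(5000, 0.05, 0.01), seed = 8)
  expect_identical(sel1$best_k, 1L)
  expect_equal(unname(sel1$bic[1]), max(sel1$bic), tolerance = 1e-6)
})

test_that("stability analysis is deterministic and clips oversized samples", {
  set.seed(9)
  pool <- rmix3(6000)
  r1 <- stability_analysis(pool, sample_size = 3000, reps = 3, k_max = 3,
                           seed = 10, restarts = 3)
  r2 <- stability_analysis(pool, sample_size = 3000, reps = 3, k_max = 3,
                           seed = 10, restarts = 3)
  expect_identical(r1[c("best_k", "means3", "modal_k")],
                   r2[c("best_k", "means3", "modal_k")])
  expect_warning(
    stability_analysis(pool, sample_size = 10000, reps = 1, k_max = 3,
                       seed = 1, restarts = 2),
    "clipped")
})

test_that("thresholds solve the weighted-density crossing between means", {
  sym <- structure(list(w = c(0.3, 0.3, 0.4), mu = c(10, 6, 1),
                        sigma2 = c(1, 1, 1), K = 3L), class = "gmm_fit")
  th <- class_thresholds(sym)
  expect_equal(unname(th["t_high"]), 8)   # equal weight/variance: midpoint
  set.seed(11)
  for (i in 1:20) {
    mus <- sort(runif(3, 0, 1), decreasing = TRUE)
    model <- structure(list(w = as.numeric(prop.table(runif(3, 0.2, 1))),
                            mu = mus,
                            sigma2 = runif(3, 1e-4, 2e-2)^2, K = 3L),
                       class = "gmm_fit")
    fell_back <- FALSE
    th <- withCallingHandlers(class_thresholds(model),
                              warning = function(w) {
                                fell_back <<- TRUE
                                invokeRestart("muffleWarning")
                              })
    expect_true(model$mu[3] < th["t_low"] && th["t_low"] < model$mu[2])
    expect_true(model$mu[2] < th["t_high"] && th["t_high"] < model$mu[1])
    if (!fell_back) {
      # crossing residual: weighted densities equal to near machine precision
      for (pair in list(c(1, 2, "t_high"), c(2, 3, "t_low"))) {
        a <- as.integer(pair[1]); b <- as.integer(pair[2]); t0 <- th[pair[3]]
        da <- model$w[a] * dnorm(t0, model$mu[a], sqrt(model$sigma2[a]))
        db <- model$w[b] * dnorm(t0, model$mu[b], sqrt(model$sigma2[b]))
        expect_lt(abs(da - db), 1e-10 * max(da, db, 1))
      }
    }
  }
  expect_error(class_thresholds(fit_gmm(rnorm(100), 1)), "K = 3")
})

test_that("assignment partitions lymphocytes by the threshold intervals", {
  set.seed(12)
  s <- rmix3(2000)
  f <- fit_gmm(s, 3, seed = 13)
  th <- class_thresholds(f)
  cl <- assign_classes(th, s, f)
  expect_equal(length(cl$til_class), 2000)
  expect_false(anyNA(cl$til_class))
  expect_true(all(s[cl$til_class == "ITL"] >= th["t_high"]))
  expect_true(all(s[cl$til_class == "ATL"] >= th["t_low"] &
                  s[cl$til_class == "ATL"] < th["t_high"]))
  expect_true(all(s[cl$til_class == "DTL"] < th["t_low"]))
  expect_equal(rowSums(cl$posterior), rep(1, 2000), tolerance = 1e-12)
  # median proximity strictly decreasing across ITL > ATL > DTL
  med <- tapply(s, cl$til_class, median)
  expect_true(med["ITL"] > med["ATL"] && med["ATL"] > med["DTL"])
})

test_that("class labels are invariant to a common positive rescaling of s", {
  set.seed(14)
  s <- rmix3(4000)
  f1 <- fit_gmm(s, 3, seed = 15)
  f2 <- fit_gmm(s * 0.0625, 3, seed = 15)  # power of two: exact scaling
  l1 <- assign_classes(class_thresholds(f1), s, f1)
  l2 <- assign_classes(class_thresholds(f2), s * 0.0625, f2)
  expect_identical(l1$til_class, l2$til_class)
})
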