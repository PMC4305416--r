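test_that("nearest-cancer distance matches closed forms and brute force", {
  m <- cell_map(c(3, 0), c(4, 0), c("cancer", "lymphocyte"))
  expect_equal(nearest_cancer_distance(m), 5)   # 3-4-5 triangle
  m0 <- cell_map(c(2, 2), c(7, 7), c("cancer", "lymphocyte"))
  expect_equal(nearest_cancer_distance(m0), 0)  # coincident
  expect_error(nearest_cancer_distance(cell_map(1, 1, "lymphocyte")),
               "no cancer cells")
  set.seed(1)
  for (i in 1:50) {
    m <- random_int_map(sample(5:30, 1), sample(1:10, 1))
    cancer <- cbind(m$cells$x[m$cells$class == "cancer"],
                    m$cells$y[m$cells$class == "cancer"])
    lymph <- cbind(m$cells$x[m$cells$class == "lymphocyte"],
                   m$cells$y[m$cells$class == "lymphocyte"])
    expect_identical(nearest_cancer_distance(m), bf_dmin(cancer, lymph))
  }
})

test_that("hull centroid handles interior, collinear and coincident cases", {
  # interior point excluded from the hull; symmetric vertex mean
  m <- cell_map(c(0, 1, 1, 0, 0.5, 0.5), c(0, 0, 1, 1, 0.5, 0.5),
                rep(c("cancer", "lymphocyte"), c(5, 1)))
  expect_equal(hull_centroid_distance(m), 0)
  # collinear cancer: degenerate hull, centroid = midpoint of extremes
  m2 <- cell_map(c(0, 1, 2, 3, 4, 0), c(0, 0, 0, 0, 0, 1),
                 rep(c("cancer", "lymphocyte"), c(5, 1)))
  expect_equal(hull_centroid_distance(m2), sqrt(5))
  # all k coincident: centroid is the shared point
  m3 <- cell_map(c(rep(2, 5), 5), c(rep(2, 5), 6),
                 rep(c("cancer", "lymphocyte"), c(5, 1)))
  expect_equal(hull_centroid_distance(m3), 5)
  expect_error(hull_centroid_distance(cell_map(c(0, 1, 3), c(0, 1, 3),
                                               c("cancer", "cancer",
                                                 "lymphocyte"))),
               "k = 5")
})

test_that("hull centroid equals the exhaustive extreme-point oracle", {
  set.seed(2)
  for (i in 1:200) {
    n_cancer <- sample(5:15, 1)
    m <- random_int_map(n_cancer, sample(1:5, 1), lim = 10)  # many ties
    cancer <- cbind(m$cells$x[m$cells$class == "cancer"],
                    m$cells$y[m$cells$class == "cancer"])
    lymph <- cbind(m$cells$x[m$cells$class == "lymphocyte"],
                   m$cells$y[m$cells$class == "lymphocyte"])
    got <- hull_centroid_distance(m, k = 5)
    want <- vapply(seq_len(nrow(lymph)), function(j) {
      d <- sqrt((cancer[, 1] - lymph[j, 1])^2 + (cancer[, 2] - lymph[j, 2])^2)
      nn <- order(d, seq_along(d))[1:5]   # ties by lowest cell index
      cen <- oracle_hull_centroid(cancer[nn, , drop = FALSE])
      sqrt(sum((lymph[j, ] - cen)^2))
    }, 0)
    expect_identical(got, want)
  }
})

test_that("distance measures are invariant under rigid motions", {
  set.seed(3)
  m <- sep_tumor(4, n_each = 40)$map
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- cbind(m$cells$x, m$cells$y) %*% R
  m2 <- cell_map(xy[, 1] + 500, xy[, 2] - 200, m$cells$class)
  expect_equal(nearest_cancer_distance(m2), nearest_cancer_distance(m),
               tolerance = 1e-9)
  expect_equal(hull_centroid_distance(m2), hull_centroid_distance(m),
               tolerance = 1e-9)
})

test_that("d_min obeys the hull triangle inequality", {
  set.seed(4)
  m <- sep_tumor(5, n_each = 60)$map
  cancer <- cbind(m$cells$x[m$cells$class == "cancer"],
                  m$cells$y[m$cells$class == "cancer"])
  lymph <- cbind(m$cells$x[m$cells$class == "lymphocyte"],
                 m$cells$y[m$cells$class == "lymphocyte"])
  dmin <- nearest_cancer_distance(m)
  dcen <- hull_centroid_distance(m)
  for (j in seq_len(nrow(lymph))) {
    d <- sqrt((cancer[, 1] - lymph[j, 1])^2 + (cancer[, 2] - lymph[j, 2])^2)
    nn <- order(d, seq_along(d))[1:5]
    cen <- oracle_hull_centroid(cancer[nn, , drop = FALSE])
    spread <- max(sqrt((cancer[nn, 1] - cen[1])^2 + (cancer[nn, 2] - cen[2])^2))
    expect_lte(dmin[j], dcen[j] + spread + 1e-9)
  }
})

test_that("class difference tests report t, p, medians and IQRs", {
  # identical constant groups: no difference, p = 1
  r <- class_difference_tests(rep(5, 20), rep(c("ITL", "ATL"), each = 10))
  expect_equal(r$tests$t, 0)
  expect_equal(r$tests$p, 1)
  # huge planted effect
  set.seed(5)
  v <- c(rnorm(1000), rnorm(1000, 2))
  r2 <- class_difference_tests(v, rep(c("a", "b"), each = 1000))
  expect_lt(r2$tests$p, 1e-10)
  # 3-vs-3 toy: Welch statistic matches the closed form
  a <- c(1, 2, 6); b <- c(3, 5, 10)
  r3 <- class_difference_tests(c(a, b), rep(c("a", "b"), each = 3))
  tw <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(r3$tests$t, tw, tolerance = 1e-12)
  # pooled-variance flag matches the classic Student form
  r4 <- class_difference_tests(c(a, b), rep(c("a", "b"), each = 3),
                               var_equal = TRUE)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  expect_equal(r4$tests$t, (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3)),
               tolerance = 1e-12)
  # absent class skipped with warning; summaries intact
  expect_warning(
    r5 <- class_difference_tests(1:5, factor(rep("ITL", 5),
                                             levels = c("ITL", "ATL"))),
    "fewer than 2")
  expect_equal(r5$summary$median[r5$summary$class == "ITL"], 3)
})

test_that("planted regimes order the physical distances ITL < ATL < DTL", {
  ts <- sep_tumor(6)
  dmin <- nearest_cancer_distance(ts$map)
  dcen <- hull_centroid_distance(ts$map)
  md <- tapply(dmin, ts$regime, median)
  mc <- tapply(dcen, ts$regime, median)
  expect_true(md["intra"] < md["adjacent"] && md["adjacent"] < md["distal"])
  expect_true(mc["intra"] < mc["adjacent"] && mc["adjacent"] < mc["distal"])
})
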