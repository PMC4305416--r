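test_that("quartic kernel has the closed form, compact support and unit mass", {
  expect_equal(quartic_kernel(0, 0), 3 / pi)
  expect_equal(quartic_kernel(1, 0), 0)
  expect_equal(quartic_kernel(0.8, 0.9), 0)
  # radial quadrature: int_0^1 (3/pi)(1-r^2)^2 * 2*pi*r dr = 1
  mass <- stats::integrate(function(r) (3 / pi) * (1 - r^2)^2 * 2 * pi * r,
                           0, 1, rel.tol = 1e-10)$value
  expect_lt(abs(mass - 1), 1e-6)
})

test_that("density evaluator matches single-kernel closed forms", {
  expect_equal(estimate_density(cbind(0, 0), 1, cbind(0, 0)), 3 / pi)
  expect_equal(estimate_density(cbind(0, 0), 25, cbind(0, 0)), 3 / pi / 625)
  expect_equal(estimate_density(cbind(0, 0), 10, cbind(11, 0)), 0)
  expect_error(estimate_density(cbind(numeric(0), numeric(0)), 10, cbind(0, 0)),
               "at least one cancer cell")
  expect_error(estimate_density(cbind(0, 0), -1, cbind(0, 0)), "h must be")
})

test_that("fast evaluator equals the brute-force double loop", {
  set.seed(5)
  for (i in 1:20) {
    cancer <- cbind(runif(200, 0, 500), runif(200, 0, 500))
    query <- cbind(runif(50, 0, 500), runif(50, 0, 500))
    h <- runif(1, 10, 120)
    expect_lt(max(abs(estimate_density(cancer, h, query) -
                      bf_density(cancer, h, query))), 1e-9)
  }
})

test_that("adding a cancer cell never decreases the density anywhere", {
  set.seed(6)
  cancer <- cbind(runif(60, 0, 200), runif(60, 0, 200))
  query <- cbind(runif(40, 0, 200), runif(40, 0, 200))
  f1 <- estimate_density(cancer, 40, query)
  f2 <- estimate_density(rbind(cancer, c(100, 100)), 40, query)
  expect_true(all(f2 >= f1))
})

test_that("density grid equals exact evaluation and is translation-equivariant", {
  set.seed(7)
  m <- cell_map(runif(80, 0, 400), runif(80, 0, 400), rep("cancer", 80),
                window = c(0, 0, 400, 400))
  g <- density_grid(m, h = 50, spacing = 40)
  nodes <- cbind(rep(g$x, times = length(g$y)), rep(g$y, each = length(g$x)))
  expect_identical(as.numeric(g$values),
                   estimate_density(cbind(m$cells$x, m$cells$y), 50, nodes))
  expect_lte(max(g$values), (3 / pi) / 50^2 * 80)
  m2 <- cell_map(m$cells$x + 1000, m$cells$y - 300, m$cells$class,
                 window = c(1000, -300, 1400, 100))
  g2 <- density_grid(m2, h = 50, spacing = 40)
  expect_identical(g2$values, g$values)
  expect_error(density_grid(m, 50, 500), "larger than the window")
})

test_that("proximity values are the exact density at lymphocyte positions", {
  m <- cell_map(c(0, 100), c(0, 0), c("cancer", "lymphocyte"))
  p <- proximity_to_cancer(m, h = 50)
  expect_equal(p$s, 0)
  m2 <- cell_map(c(0, 0), c(0, 0), c("cancer", "lymphocyte"),
                 window = c(0, 0, 1, 1))
  expect_equal(proximity_to_cancer(m2, h = 20)$s, (3 / pi) / 400)
  set.seed(8)
  ts <- sep_tumor(1, n_each = 100)
  pr <- proximity_to_cancer(ts$map, h = 80)
  lym <- ts$map$cells[ts$map$cells$class == "lymphocyte", ]
  can <- ts$map$cells[ts$map$cells$class == "cancer", ]
  expect_identical(pr$s, estimate_density(cbind(can$x, can$y), 80,
                                          cbind(lym$x, lym$y)))
  m3 <- cell_map(0, 0, "cancer")
  expect_warning(p3 <- proximity_to_cancer(m3, 10), "no lymphocytes")
  expect_equal(nrow(p3), 0)
  m4 <- cell_map(0, 0, "lymphocyte")
  expect_error(proximity_to_cancer(m4, 10), "no cancer cells")
})

test_that("densities are scale-equivariant: c-scaled coordinates and bandwidth", {
  set.seed(9)
  cancer <- cbind(runif(100, 0, 300), runif(100, 0, 300))
  query <- cbind(runif(30, 0, 300), runif(30, 0, 300))
  f <- estimate_density(cancer, 60, query)
  f4 <- estimate_density(cancer * 4, 240, query * 4)
  expect_equal(f4, f / 16, tolerance = 1e-12)
})

test_that("bandwidth selection minimises cross-validated squared error", {
  # degenerate single-candidate grid
  set.seed(10)
  m <- cell_map(runif(50, 0, 200), runif(50, 0, 200), rep("cancer", 50),
                window = c(0, 0, 200, 200))
  expect_equal(select_bandwidth(list(m), 35, seed = 1)$h, 35)
  # determinism
  maps <- lapply(1:6, function(i) sep_tumor(i, n_each = 5)$map)
  s1 <- select_bandwidth(maps, c(30, 60, 120), n_images = 3, seed = 4)
  s2 <- select_bandwidth(maps, c(30, 60, 120), n_images = 3, seed = 4)
  expect_identical(s1, s2)
  # maps with < 2 cancer cells are skipped, all-skipped errors
  tiny <- cell_map(c(0, 1), c(0, 1), c("cancer", "lymphocyte"))
  expect_warning(sel <- select_bandwidth(list(tiny, m), c(20, 40),
                                         n_images = 2, seed = 1),
                 "fewer than 2 cancer cells")
  expect_error(suppressWarnings(select_bandwidth(list(tiny), 20, seed = 1)),
               "no usable maps")
})

test_that("chosen bandwidth tracks the true integrated squared error", {
  # maps drawn from a known smooth intensity (Gaussian bumps); the LSCV
  # argmin must land within one grid step of the true-ISE argmin
  set.seed(42)
  win <- c(0, 0, 1000, 1000)
  centres <- cbind(runif(8, 100, 900), runif(8, 100, 900))
  sigma <- 60; per_nest <- 120
  lam <- function(xy) {
    rowSums(vapply(1:8, function(j) {
      per_nest / (2 * pi * sigma^2) *
        exp(-((xy[, 1] - centres[j, 1])^2 + (xy[, 2] - centres[j, 2])^2) /
              (2 * sigma^2))
    }, numeric(nrow(xy))))
  }
  maps <- lapply(1:10, function(s) {
    set.seed(s)
    n <- rpois(1, 8 * per_nest)
    j <- sample(1:8, n, TRUE)
    x <- rnorm(n, centres[j, 1], sigma); y <- rnorm(n, centres[j, 2], sigma)
    keep <- x >= 0 & x <= 1000 & y >= 0 & y <= 1000
    cell_map(x[keep], y[keep], rep("cancer", sum(keep)), window = win)
  })
  h_grid <- c(20, 35, 60, 100, 170)
  gx <- seq(5, 995, by = 15)
  gr <- as.matrix(expand.grid(gx, gx))
  lt <- lam(gr)
  ise <- vapply(h_grid, function(h) {
    mean(vapply(maps, function(m) {
      mean((estimate_density(cbind(m$cells$x, m$cells$y), h, gr) - lt)^2)
    }, 0))
  }, 0)
  true_best <- which.min(ise)
  sel <- select_bandwidth(maps, h_grid, n_images = 10, seed = 9)
  expect_lte(abs(which(h_grid == sel$h) - true_best), 1)
})
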