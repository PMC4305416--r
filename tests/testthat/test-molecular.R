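test_that("gene correlation matches closed forms and flags constants", {
  set.seed(1)
  sc <- setNames(rnorm(10), paste0("s", 1:10))
  expr <- rbind(same = sc, neg = -sc, noise = rnorm(10), flat = rep(1, 10))
  colnames(expr) <- names(sc)
  gc <- correlate_genes(sc, expr)
  expect_equal(gc$r[gc$gene == "same"], 1)
  expect_equal(gc$r[gc$gene == "neg"], -1)
  expect_true(gc$constant[gc$gene == "flat"])
  expect_true(is.na(gc$q[gc$gene == "flat"]))
  # p equals the t transform checked against cor.test
  ct <- cor.test(as.numeric(expr["noise", ]), sc)
  expect_equal(gc$p[gc$gene == "noise"], ct$p.value, tolerance = 1e-12)
})

test_that("q-values reduce to BH at pi0 = 1 and stay monotone in p", {
  set.seed(2)
  p <- runif(200)^1.5
  q <- estimate_qvalues(p, pi0 = 1)$q
  expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-14)
  est <- estimate_qvalues(p)
  expect_true(est$pi0 > 0 && est$pi0 <= 1)
  o <- order(p)
  expect_true(all(diff(est$q[o]) >= -1e-15))
  expect_error(estimate_qvalues(numeric(0)), "empty")
  expect_error(estimate_qvalues(c(0.5, 2)), "0, 1")
})

test_that("planted correlated genes are recovered with controlled FDR", {
  set.seed(3)
  sc <- setNames(runif(181), sprintf("s%03d", 1:181))
  es <- simulate_expression(sc, n_genes = 2000, n_correlated = 100,
                            r_target = 0.6, seed = 4)
  gc <- correlate_genes(sc, es$expr)
  planted <- c(es$truth$positive, es$truth$negative)
  sens <- mean(gc$significant[gc$gene %in% planted])
  fdp <- sum(gc$significant & gc$gene %in% es$truth$null) /
    max(1, sum(gc$significant))
  expect_gte(sens, 0.9)
  expect_lte(fdp, 0.1)
  expect_equal(sum(gc$direction[gc$gene %in% es$truth$negative] == "negative"),
               length(es$truth$negative))
})

test_that("module discovery keeps planted blocks and drops violators", {
  set.seed(5)
  sc <- setNames(runif(181), sprintf("s%03d", 1:181))
  es <- simulate_expression(sc, n_genes = 500, n_correlated = 0,
                            module_spec = list(c(8, 0.85), c(10, 0.85),
                                               c(12, 0.85), c(5, 0.9),
                                               c(10, 0.36)),
                            seed = 6)
  mods <- find_modules(es$expr)
  expect_equal(length(mods), 3)
  found <- lapply(mods, function(m) sort(m$genes))
  for (truth in lapply(es$truth$modules[1:3], sort))
    expect_true(any(vapply(found, identical, TRUE, truth)))
  # gene-order permutation leaves the module contents unchanged
  perm <- sample(nrow(es$expr))
  mods2 <- find_modules(es$expr[perm, ])
  expect_setequal(vapply(mods2, function(m) paste(sort(m$genes), collapse = ","), ""),
                  vapply(mods, function(m) paste(sort(m$genes), collapse = ","), ""))
  expect_warning(out <- find_modules(es$expr[1:3, ]), "fewer than")
  expect_length(out, 0)
})

test_that("hypergeometric enrichment has the closed-form tail", {
  universe <- sprintf("g%02d", 1:20)
  sets <- list(hit5 = universe[1:5], none = universe[6:10])
  hits <- universe[1:5]
  e <- hypergeom_enrichment(hits, sets, universe)
  expect_equal(e$p[e$set == "hit5"], 1 / choose(20, 5))
  expect_equal(e$p[e$set == "none"], 1)   # overlap 0: P(>= 0) = 1
  expect_equal(sum(dhyper(0:5, 5, 15, 5)), 1, tolerance = 1e-12)
  expect_error(hypergeom_enrichment(character(0), sets, universe), "empty hit")
  expect_error(hypergeom_enrichment("zzz", sets, universe), "subset")
})

test_that("GMT round-trips through the parser", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tdesc\tg1\tg2\tg3", "SET_B\tdesc\tg2\tg4"), f)
  gs <- read_gmt(f)
  expect_equal(names(gs), c("SET_A", "SET_B"))
  expect_equal(gs$SET_B, c("g2", "g4"))
})

test_that("paired score-vs-gene Cox models separate signal from noise", {
  set.seed(7)
  sc <- runif(180)
  ss <- simulate_survival(sc, hr_high = 0.3, low_fraction = 0.2, seed = 8)
  high <- !ss$truth$low
  expr <- matrix(rnorm(5 * 180), 5, 180,
                 dimnames = list(paste0("g", 1:5), ss$clinical$sample_id))
  r3 <- compare_score_vs_gene(high, expr, ss$clinical,
                              gene_grouping = "p25_50_25")
  # exact 45/90/45 split
  grp <- immunoscape:::rank_groups(expr[1, ], c(0.25, 0.5, 0.25))
  expect_equal(unname(table(grp)), array(c(45L, 90L, 45L)), ignore_attr = TRUE)
  expect_true(mean(r3$p_score < 0.05, na.rm = TRUE) >= 0.8)
  expect_true(mean(r3$p_gene > 0.05, na.rm = TRUE) >= 0.6)
  # collinear gene grouping flagged (median split duplicated exactly)
  high2 <- sc >= stats::median(sc)
  expr2 <- rbind(expr, dup = as.numeric(high2))
  r2 <- compare_score_vs_gene(high2, expr2, ss$clinical, genes = "dup",
                              gene_grouping = "median2")
  expect_true(r2$collinear)
})
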