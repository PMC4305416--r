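# Molecular correlates of the infiltration score: per-gene Pearson
# correlation with Storey-type q-values, co-expression module discovery by
# hierarchical clustering of the gene-gene correlation matrix,
# hypergeometric gene-set enrichment, and paired score-vs-gene Cox models.

#' Correlate a per-sample score with every gene
#'
#' Pearson correlation of the score with each gene (rows of the expression
#' matrix), two-sided p from the t transform of r with n - 2 degrees of
#' freedom, and q-values from [estimate_qvalues()]. Zero-variance genes are
#' flagged and excluded from testing.
#'
#' @param score Named numeric per-sample score; names are matched against
#'   the expression column names when both are present.
#' @param expr Numeric matrix, genes x samples, with row names.
#' @param q_cutoff Significance threshold on q (default 0.05) used for the
#'   `significant` flag.
#' @param lambda Storey lambda passed to [estimate_qvalues()].
#' @return Data frame with `gene`, `r`, `p`, `q`, `direction`
#'   (`"positive"`/`"negative"`), `significant`, `constant` (zero-variance
#'   flag); attribute `pi0` carries the null-proportion estimate.
#' @export
correlate_genes <- function(score, expr, q_cutoff = 0.05, lambda = 0.75) {
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  if (!is.null(names(score)) && !is.null(colnames(expr))) {
    common <- intersect(names(score), colnames(expr))
    if (length(common) < 3) stop("fewer than 3 matched samples")
    score <- score[common]
    expr <- expr[, common, drop = FALSE]
  }
  n <- length(score)
  if (n < 3 || ncol(expr) != n) stop("need >= 3 samples, matched to columns")
  sds <- apply(expr, 1, sd)
  constant <- sds == 0
  r <- rep(NA_real_, nrow(expr))
  r[!constant] <- as.numeric(cor(t(expr[!constant, , drop = FALSE]), score))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tt), df = n - 2)
  q <- rep(NA_real_, length(p))
  qv <- estimate_qvalues(p[!constant], lambda = lambda)
  q[!constant] <- qv$q
  out <- data.frame(gene = rownames(expr), r = r, p = p, q = q,
                    direction = ifelse(r >= 0, "positive", "negative"),
                    significant = !is.na(q) & q < q_cutoff,
                    constant = constant,
                    stringsAsFactors = FALSE)
  attr(out, "pi0") <- qv$pi0
  out
}

#' Storey-type q-values
#'
#' Estimates the null proportion pi0 from the p-values above `lambda`
#' (default 0.75: the upper quarter of the unit interval is treated as
#' null-dominated), clipped to (0, 1], then computes
#' `q_i = pi0 * min_{p_j >= p_i} (m * p_j / rank_j)`, capped at 1. With
#' `pi0` forced to 1 this is exactly Benjamini-Hochberg adjustment.
#'
#' @param p P-values in \[0, 1\].
#' @param lambda Null-window threshold in (0, 1).
#' @param pi0 Optional override of the estimated null proportion.
#' @return List with `q` (same order as `p`) and `pi0`.
#' @export
estimate_qvalues <- function(p, lambda = 0.75, pi0 = NULL) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- mean(p > lambda, na.rm = TRUE) / (1 - lambda)
    pi0 <- min(1, max(pi0, 1 / m))  # clip to (0, 1]
  }
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  qs <- pi0 * pmin(1, rev(cummin(rev(ranked))))
  q <- numeric(m)
  q[o] <- qs
  list(q = q, pi0 = pi0)
}

#' Discover tightly correlated gene modules
#'
#' Hierarchically clusters the gene-gene Pearson correlation matrix on
#' distance 1 - r (which keeps anticorrelated genes apart) and cuts the
#' tree into `n_clusters` clusters (or the gene count, if smaller).
#' Clusters are kept as modules when their mean pairwise absolute
#' correlation exceeds `r_min` and they contain at least `min_size` genes.
#' Ward linkage is the default because it resists absorbing weakly
#' correlated background genes into tight modules, which dilutes the mean
#' pairwise correlation below the selection rule; average linkage is
#' available via `linkage`.
#'
#' @param expr Expression matrix (genes x samples) restricted to the genes
#'   of interest, e.g. the score-associated genes of one sign.
#' @param n_clusters Number of tree cuts (default 100).
#' @param r_min Mean pairwise |r| threshold (default 0.75, strict).
#' @param min_size Minimum module size (default 6).
#' @param linkage Hierarchical linkage (default `"ward.D2"`).
#' @return List of modules, each a list with `genes`, `size`, `mean_abs_r`;
#'   empty (with a warning) when fewer than `min_size` genes are supplied.
#' @export
find_modules <- function(expr, n_clusters = 100, r_min = 0.75, min_size = 6,
                         linkage = "ward.D2") {
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  ng <- nrow(expr)
  if (ng < min_size) {
    warning("fewer than ", min_size, " genes; no modules can satisfy the size rule")
    return(list())
  }
  if (ng < 2) stop("need at least 2 genes")
  C <- cor(t(expr))
  hc <- hclust(as.dist(1 - C), method = linkage)
  k <- min(n_clusters, ng)
  cl <- cutree(hc, k = k)
  modules <- list()
  for (g in sort(unique(cl))) {
    members <- which(cl == g)
    if (length(members) < min_size) next
    sub <- abs(C[members, members])
    mar <- mean(sub[upper.tri(sub)])
    if (mar > r_min) {
      modules[[length(modules) + 1]] <-
        list(genes = rownames(expr)[members],
             size = length(members), mean_abs_r = mar)
    }
  }
  modules
}

#' Read a GMT gene-set file
#'
#' One gene set per line: name, description, then gene ids, tab-separated.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a hit list and
#' each gene set: the probability of observing at least the seen overlap
#' when drawing `|hits|` genes from the universe. Sets are intersected with
#' the universe first; Benjamini-Hochberg adjusted p-values are reported
#' alongside the raw ones.
#'
#' @param hits Character vector of hit genes (must lie in the universe).
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param universe Character vector: all genes considered.
#' @return Data frame with `set`, `set_size` (in-universe), `overlap`, `p`,
#'   `p_adj`.
#' @export
hypergeom_enrichment <- function(hits, gene_sets, universe) {
  if (!length(universe)) stop("empty universe")
  if (!length(hits)) stop("empty hit list")
  universe <- unique(universe)
  hits <- unique(hits)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  N <- length(universe)
  k <- length(hits)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    ov <- length(intersect(set, hits))
    p <- phyper(ov - 1, length(set), N - length(set), k, lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

rank_groups <- function(v, probs) {
  # deterministic grouping by rank with exact group sizes; ties broken by
  # original order
  n <- length(v)
  sizes <- diff(c(0, round(cumsum(probs) * n)))
  g <- integer(n)
  g[order(v)] <- rep(seq_along(sizes), sizes)
  g
}

#' Compare the score's prognostic value against single genes
#'
#' For each gene, fits one multivariate Cox model containing the
#' dichotomized score group and a grouping of the gene's expression:
#' either two equal-sized groups split at the median (`"median2"`) or three
#' groups at the 25th/75th percentiles (`"p25_50_25"`, sizes n/4, n/2,
#' n/4). Gene groupings identical to the score grouping are flagged as
#' collinear and skipped.
#'
#' @param high Score high-group indicator (logical/0-1) per sample.
#' @param expr Expression matrix (genes x samples), columns aligned with
#'   `high` and `clinical`.
#' @param clinical Clinical table with `time_months`, `event`.
#' @param genes Genes to test (default: all rows of `expr`).
#' @param gene_grouping `"median2"` or `"p25_50_25"`.
#' @return Data frame per gene: `gene`, `hr_score`, `p_score`,
#'   `neglog10_p_score`, `p_gene` (smallest gene-term p), `converged`,
#'   `collinear`.
#' @export
compare_score_vs_gene <- function(high, expr, clinical,
                                  genes = rownames(expr),
                                  gene_grouping = c("median2", "p25_50_25")) {
  gene_grouping <- match.arg(gene_grouping)
  check_clinical(clinical)
  high <- as.numeric(high)
  probs <- if (gene_grouping == "median2") c(0.5, 0.5) else c(0.25, 0.5, 0.25)
  rows <- lapply(genes, function(g) {
    grp <- rank_groups(expr[g, ], probs)
    tab <- table(grp, high)
    collinear <- length(unique(grp)) < 2 ||
      (all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
    if (collinear)
      return(data.frame(gene = g, hr_score = NA_real_, p_score = NA_real_,
                        neglog10_p_score = NA_real_, p_gene = NA_real_,
                        converged = NA, collinear = TRUE,
                        stringsAsFactors = FALSE))
    d <- clinical
    d$gene_group <- factor(grp)
    fit <- cox_model(d, high, covariates = "gene_group")
    tb <- fit$table
    ps <- tb$p[tb$term == "high"]
    pg <- suppressWarnings(min(tb$p[tb$term != "high"]))
    data.frame(gene = g, hr_score = tb$hr[tb$term == "high"], p_score = ps,
               neglog10_p_score = -log10(ps), p_gene = pg,
               converged = fit$converged, collinear = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
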