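# End-to-end orchestration: cells -> proximity -> classes -> scores ->
# survival / molecular correlates, from a single configuration with
# explicit seeds, writing plain-text artifacts.

#' Pipeline configuration
#'
#' Builds (and validates the shape of) the configuration consumed by
#' [run_pipeline()]. Paths are checked at run time.
#'
#' @param cells_dir Directory of per-tumour cell CSVs (`x,y,class`), or
#'   NULL when `maps` are passed to [run_pipeline()] directly.
#' @param clinical Path to the clinical table (CSV with `sample_id`,
#'   `time_months`, `event`, optional `node`, `size`, `cohort`) or a data
#'   frame; NULL skips the survival stage.
#' @param expression Path to a genes-x-samples TSV (first column gene id)
#'   or a matrix; NULL skips the molecular stage.
#' @param gene_sets Path to a GMT file or a named list; NULL skips
#'   enrichment.
#' @param h Kernel bandwidth in micrometres.
#' @param sample_size,reps,k_max Class-discovery settings (see
#'   [stability_analysis()]); `reps = 0` skips the stability stage and fits
#'   K = 3 directly.
#' @param restarts EM restarts per fit.
#' @param lo,hi,step Cut-off scan grid (percentiles).
#' @param n_boot Bootstrap resamples (0 skips).
#' @param discovery,validation Cohort identifiers for the scan discipline;
#'   NULL uses all patients as one discovery cohort.
#' @param seed Master seed, stamped into every artifact.
#' @param out_dir Output directory (created); NULL returns results only.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(cells_dir = NULL, clinical = NULL,
                            expression = NULL, gene_sets = NULL,
                            h = 50, sample_size = 100000, reps = 200,
                            k_max = 5, restarts = 10,
                            lo = 20, hi = 80, step = 1.5, n_boot = 1000,
                            discovery = NULL, validation = NULL,
                            seed = 1, out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

pipeline_log <- function(lines, msg) {
  message(msg)
  c(lines, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: read cell maps, compute
#' per-lymphocyte proximity to cancer, discover lymphocyte classes
#' (stability + final mixture fit), assign ITL/ATL/DTL and score every
#' tumour, then (when inputs are present) survival stratification with the
#' discovery/validation cut-off discipline and molecular correlates.
#' Missing optional inputs skip their stage with an explicit log line.
#'
#' @param config A [pipeline_config()].
#' @param maps Optional list of [cell_map] objects, used instead of
#'   `config$cells_dir`.
#' @return List with `model`, `thresholds`, `stability` (or NULL),
#'   `scores` (per-tumour data frame), `labels` (per-tumour classified
#'   lymphocytes), `survival`, `molecular`, `log`, `seed`; artifacts are
#'   written under `config$out_dir` when set.
#' @export
run_pipeline <- function(config, maps = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  set.seed(config$seed)

  if (is.null(maps)) {
    if (is.null(config$cells_dir) || !dir.exists(config$cells_dir))
      stop("cells_dir does not exist: ", config$cells_dir)
    files <- list.files(config$cells_dir, pattern = "\\.csv$",
                        full.names = TRUE)
    if (!length(files)) stop("no cell CSVs in ", config$cells_dir)
    maps <- lapply(files, read_cell_map)
    log <- pipeline_log(log, sprintf("read %d cell maps from %s",
                                     length(maps), config$cells_dir))
  }
  names(maps) <- vapply(maps, `[[`, "", "tumour_id")

  prox <- lapply(maps, proximity_to_cancer, h = config$h)
  pooled <- unlist(lapply(prox, `[[`, "s"), use.names = FALSE)
  log <- pipeline_log(log, sprintf("pooled %d lymphocyte proximities (h = %g um)",
                                   length(pooled), config$h))

  stab <- NULL
  modal_k <- 3L
  if (config$reps > 0) {
    stab <- suppressWarnings(
      stability_analysis(pooled, sample_size = config$sample_size,
                         reps = config$reps, k_max = config$k_max,
                         seed = config$seed, restarts = config$restarts))
    modal_k <- stab$modal_k
    log <- pipeline_log(log, sprintf(
      "stability: modal K = %d in %.0f%% of %d reps",
      modal_k, 100 * stab$frac_modal, config$reps))
  }
  # final production model: one fixed-seed sample at the modal K
  set.seed(config$seed)
  fit_n <- min(config$sample_size, length(pooled))
  s_fit <- pooled[sample.int(length(pooled), fit_n)]
  model <- fit_gmm(s_fit, K = modal_k, restarts = config$restarts)
  if (modal_k != 3) {
    log <- pipeline_log(log, sprintf(
      "modal K = %d != 3; thresholds taken from a K = 3 refit", modal_k))
    model3 <- fit_gmm(s_fit, K = 3, restarts = config$restarts)
  } else model3 <- model
  thresholds <- class_thresholds(model3)
  log <- pipeline_log(log, sprintf("thresholds: t_low = %.4g, t_high = %.4g",
                                   thresholds[1], thresholds[2]))

  labels <- lapply(prox, function(p) assign_classes(thresholds, p$s, model3))
  scores <- do.call(rbind, lapply(names(maps), function(id) {
    nc <- sum(maps[[id]]$cells$class == "cancer")
    compute_scores(labels[[id]], nc, tumour_id = id)
  }))

  clinical <- config$clinical
  if (is.character(clinical)) clinical <- read.csv(clinical)
  surv <- NULL
  if (is.null(clinical)) {
    log <- pipeline_log(log, "no clinical table: survival stage skipped")
  } else {
    clinical <- censor_at(check_clinical(clinical))
    idx <- match(scores$tumour_id, clinical$sample_id)
    if (anyNA(idx)) stop("clinical table missing sample(s): ",
                         paste(scores$tumour_id[is.na(idx)], collapse = ", "))
    clinical <- clinical[idx, , drop = FALSE]
    covars <- intersect(c("node", "size"), names(clinical))
    if (!is.null(config$discovery) && "cohort" %in% names(clinical)) {
      disc <- clinical$cohort == config$discovery
      vali <- if (!is.null(config$validation))
        clinical$cohort == config$validation else !disc
    } else {
      disc <- rep(TRUE, nrow(clinical)); vali <- rep(FALSE, nrow(clinical))
    }
    cut <- scan_cutoff(scores$itlr[disc], clinical[disc, , drop = FALSE],
                       lo = config$lo, hi = config$hi, step = config$step)
    val <- if (any(vali))
      apply_cutoff(cut$cutoff, scores$itlr[vali],
                   clinical[vali, , drop = FALSE]) else NULL
    high <- scores$itlr >= cut$cutoff
    uni <- cox_model(clinical, high)
    multi <- if (length(covars)) cox_model(clinical, high, covars) else NULL
    boot <- if (config$n_boot > 0)
      bootstrap_stability(clinical, high, covariates = covars,
                          n_boot = config$n_boot, seed = config$seed)
      else NULL
    surv <- list(cutoff = cut, validation = val, cox_uni = uni,
                 cox_multi = multi, bootstrap = boot)
    log <- pipeline_log(log, sprintf(
      "survival: cut-off %.4g (percentile %.1f), discovery p = %.3g%s",
      cut$cutoff, cut$percentile, cut$p,
      if (!is.null(val)) sprintf(", validation p = %.3g", val$p) else ""))
  }

  expr <- config$expression
  if (is.character(expr)) {
    e <- read.delim(expr, check.names = FALSE)
    expr <- as.matrix(e[, -1]); rownames(expr) <- e[[1]]
  }
  mol <- NULL
  if (is.null(expr)) {
    log <- pipeline_log(log, "no expression matrix: molecular stage skipped")
  } else {
    itlr <- setNames(scores$itlr, scores$tumour_id)
    gc <- correlate_genes(itlr, expr)
    sig <- gc[gc$significant & !gc$constant, ]
    mods <- list()
    for (sgn in c("positive", "negative")) {
      gs <- sig$gene[sig$direction == sgn]
      if (length(gs) >= 2)
        mods[[sgn]] <- suppressWarnings(
          find_modules(expr[gs, , drop = FALSE]))
    }
    enr <- NULL
    gene_sets <- config$gene_sets
    if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
    if (!is.null(gene_sets) && nrow(sig) > 0) {
      enr <- hypergeom_enrichment(sig$gene, gene_sets, rownames(expr))
    } else {
      log <- pipeline_log(log, "no gene sets (or no hits): enrichment skipped")
    }
    mol <- list(correlations = gc, n_positive = sum(sig$direction == "positive"),
                n_negative = sum(sig$direction == "negative"),
                modules = mods, enrichment = enr)
    log <- pipeline_log(log, sprintf(
      "molecular: %d positive / %d negative genes at q < 0.05; %d modules",
      mol$n_positive, mol$n_negative, sum(lengths(mods))))
  }

  res <- list(model = model, thresholds = thresholds, stability = stab,
              scores = scores, labels = labels, survival = surv,
              molecular = mol, log = log, seed = config$seed)
  if (!is.null(config$out_dir)) write_pipeline_artifacts(res, config)
  res
}

write_pipeline_artifacts <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(file.path(config$out_dir,
                                    c("model.json", "scores.csv",
                                      "survival.json", "genes.csv",
                                      "run.log"))))
  m <- res$model
  jsonlite::write_json(
    list(seed = config$seed, K = m$K, weights = m$w, means = m$mu,
         variances = m$sigma2, bic = m$bic,
         thresholds = as.list(res$thresholds)),
    file.path(config$out_dir, "model.json"),
    auto_unbox = TRUE, digits = NA)
  sc <- res$scores
  sc$seed <- config$seed
  write.csv(sc, file.path(config$out_dir, "scores.csv"), row.names = FALSE)
  if (!is.null(res$survival)) {
    s <- res$survival
    jsonlite::write_json(
      list(seed = config$seed, cutoff = s$cutoff$cutoff,
           percentile = s$cutoff$percentile, p_discovery = s$cutoff$p,
           p_validation = if (!is.null(s$validation)) s$validation$p else NULL,
           hr_uni = s$cox_uni$table$hr[1],
           boot_frac_uni = if (!is.null(s$bootstrap)) s$bootstrap$frac_uni else NULL),
      file.path(config$out_dir, "survival.json"),
      auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$molecular))
    write.csv(res$molecular$correlations,
              file.path(config$out_dir, "genes.csv"), row.names = FALSE)
  writeLines(res$log, file.path(config$out_dir, "run.log"))
  ok <- TRUE
  invisible(config$out_dir)
}
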