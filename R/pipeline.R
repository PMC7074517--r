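#' Configuration of an end-to-end pipeline run
#'
#' Collects every stage's settings into one validated object. A single
#' master seed fans out deterministically to the simulator, the rDCV
#' splits and the permutation streams, so one integer reproduces an
#' entire run.
#'
#' @param n_case,n_control Simulated arm sizes (ignored when `input` is
#'   given).
#' @param input Optional path to a dataset CSV (with its
#'   `.schema.json` sidecar) to analyze instead of simulating.
#' @param panel Analyte panel for simulation.
#' @param effect_overrides Optional overrides passed to
#'   [generate_cohort()].
#' @param repetitions,outer_folds,inner_folds,a_max,threshold rDCV
#'   settings, see [rdcv_config()].
#' @param n_perm Permutation randomizations (0 skips the permutation
#'   stage).
#' @param perm_repetitions rDCV repetitions per permutation.
#' @param k Size of the reported biomarker selection.
#' @param simca_variables `"all"` (full fused panel) or
#'   `"ev_immunoblot"` (restrict the class model to the EV block).
#' @param simca_threshold Acceptance threshold on the combined distance.
#' @param simca_folds Venetian-blinds folds for component selection.
#' @param simca_a_max Largest candidate component count.
#' @param seed Master seed.
#' @param out_dir Optional output directory for the JSON report and CSV
#'   side tables.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_case = 16, n_control = 12, input = NULL,
                            panel = build_default_panel(),
                            effect_overrides = NULL,
                            repetitions = 30, outer_folds = 7,
                            inner_folds = 5, a_max = 10, threshold = 0.5,
                            n_perm = 1000, perm_repetitions = 1, k = 7,
                            simca_variables = c("all", "ev_immunoblot"),
                            simca_threshold = 2, simca_folds = 7,
                            simca_a_max = 10,
                            seed = 1, out_dir = NULL) {
  simca_variables <- match.arg(simca_variables)
  cfg <- list(
    n_case = n_case, n_control = n_control, input = input, panel = panel,
    effect_overrides = effect_overrides,
    repetitions = repetitions, outer_folds = outer_folds,
    inner_folds = inner_folds, a_max = a_max, threshold = threshold,
    n_perm = n_perm, perm_repetitions = perm_repetitions, k = k,
    simca_variables = simca_variables, simca_threshold = simca_threshold,
    simca_folds = simca_folds, simca_a_max = simca_a_max,
    seed = as.integer(seed), out_dir = out_dir
  )
  if (is.null(input)) validate_panel(panel)
  if (n_perm < 0) stop_input("n_perm must be >= 0")
  if (k < 1) stop_input("k must be >= 1")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full fused PLS-DA / SIMCA pipeline
#'
#' Executes, in order: cohort simulation (or dataset loading), repeated
#' double cross-validation of the fused PLS-DA classifier, permutation
#' testing of its figures of merit (optional), biomarker ranking by VIP
#' and rank product, and one-class SIMCA modeling of the case category
#' (controls serve as the out-of-class set). Writes a JSON report plus
#' CSV side tables when `out_dir` is set.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report`; element `report` is the
#'   serializable summary, the other elements carry the stage objects
#'   (`data`, `rdcv`, `permutation`, `final_model`, `vip`, `rp`,
#'   `simca`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  msg <- function(...) message(sprintf(...))

  if (!is.null(config$input)) {
    data <- read_dataset(config$input)
    msg("loaded %d samples x %d analytes from %s",
        nrow(data$x), ncol(data$x), config$input)
  } else {
    data <- generate_cohort(config$n_case, config$n_control,
                            seed = derive_seed(config$seed, 101L),
                            panel = config$panel,
                            effect_overrides = config$effect_overrides)
    msg("simulated %d cases + %d controls x %d analytes (seed %d)",
        config$n_case, config$n_control, ncol(data$x), config$seed)
  }

  rcfg <- rdcv_config(
    repetitions = config$repetitions, outer_folds = config$outer_folds,
    inner_folds = config$inner_folds, a_max = config$a_max,
    seed = derive_seed(config$seed, 102L), threshold = config$threshold
  )
  res <- run_rdcv(data, rcfg)
  summ <- classification_summary(res)
  msg("rDCV: %d repetitions, overall %.1f%% +/- %.1f%% correct",
      config$repetitions, summ$overall_mean, summ$overall_sd)

  perm <- NULL
  if (config$n_perm > 0) {
    perm <- permutation_test(data, rcfg, n_perm = config$n_perm,
                             perm_repetitions = config$perm_repetitions,
                             observed = res)
    msg("permutation test: %d randomizations, p(AUROC) = %.4g",
        config$n_perm, perm$p_values[["auroc"]])
  }

  final <- fit_final_model(data, res)
  vip_res <- vip(final)
  rp_res <- rank_product(res)
  sel <- select_candidates(vip_res, rp_res, k = config$k)
  msg("ranking: %d candidate(s) selected at VIP > 1, k = %d",
      length(sel), config$k)

  simca_cols <- if (config$simca_variables == "ev_immunoblot") {
    colnames(data$x)[data$block == "ev_immunoblot"]
  } else {
    colnames(data$x)
  }
  xin <- data$x[data$labels == 1, simca_cols, drop = FALSE]
  xout <- data$x[data$labels == 0, simca_cols, drop = FALSE]
  npc <- select_npc(xin, xout, cv_folds = config$simca_folds,
                    a_max = config$simca_a_max,
                    threshold = config$simca_threshold)
  smod <- fit_simca(xin, npc$a_pc, threshold = config$simca_threshold)
  cal <- simca_assess(smod, xin, xout, mode = "calibration")
  cv_row <- npc$table[npc$table$a == npc$a_pc, ]
  msg("SIMCA: %d PC(s); calibration sens %.1f%% / spec %.1f%%; CV sens %.1f%% / spec %.1f%%",
      npc$a_pc, cal$sensitivity, cal$specificity,
      cv_row$sensitivity, cv_row$specificity)

  cfg_echo <- config[setdiff(names(config), c("panel", "out_dir"))]
  cfg_json <- jsonlite::toJSON(cfg_echo, auto_unbox = TRUE, digits = NA,
                               null = "null")
  report <- list(
    package_version = as.character(utils::packageVersion("plsfuse")),
    seed = config$seed,
    config = cfg_echo,
    config_digest = config_digest(as.character(cfg_json)),
    n_samples = nrow(data$x), n_analytes = ncol(data$x),
    classification = summ,
    merits = list(nmc = mean(res$merits$nmc),
                  auroc = mean(res$merits$auroc),
                  dq2 = mean(res$merits$dq2)),
    p_values = if (!is.null(perm)) as.list(perm$p_values),
    selected_analytes = as.character(sel),
    simca = list(
      a_pc = npc$a_pc, variables = config$simca_variables,
      calibration = list(sensitivity = cal$sensitivity,
                         specificity = cal$specificity,
                         efficiency = cal$efficiency),
      cross_validation = list(sensitivity = cv_row$sensitivity,
                              specificity = cv_row$specificity,
                              efficiency = cv_row$efficiency)
    ),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  out <- structure(
    list(report = report, data = data, rdcv = res, permutation = perm,
         final_model = final, vip = vip_res, rp = rp_res,
         selection = sel, simca = list(model = smod, npc = npc,
                                       calibration = cal)),
    class = "pipeline_report"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(result$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  utils::write.csv(attr(result$selection, "table"),
                   file.path(out_dir, "ranked_analytes.csv"),
                   row.names = FALSE)
  utils::write.csv(result$rdcv$merits,
                   file.path(out_dir, "rdcv_merits.csv"),
                   row.names = FALSE)
  oof <- as.data.frame(result$rdcv$oof)
  oof <- cbind(rep = seq_len(nrow(oof)), oof)
  utils::write.csv(oof, file.path(out_dir, "oof_predictions.csv"),
                   row.names = FALSE)
  simca_cols <- rownames(result$simca$model$loadings)
  stats_all <- simca_stats(result$simca$model,
                           result$data$x[, simca_cols, drop = FALSE])
  stats_all <- cbind(sample_id = result$data$sample_ids,
                     label = result$data$labels, stats_all)
  utils::write.csv(stats_all, file.path(out_dir, "simca_samples.csv"),
                   row.names = FALSE)
  if (!is.null(result$permutation)) {
    utils::write.csv(result$permutation$null,
                     file.path(out_dir, "permutation_null.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  r <- x$report
  cat("plsfuse pipeline report\n")
  cat(sprintf("  %d samples, %d analytes (seed %d)\n",
              r$n_samples, r$n_analytes, r$seed))
  cat(sprintf("  classification: case %.1f%% +/- %.1f%%, control %.1f%% +/- %.1f%%, overall %.1f%% +/- %.1f%%\n",
              r$classification$case_mean, r$classification$case_sd,
              r$classification$control_mean, r$classification$control_sd,
              r$classification$overall_mean, r$classification$overall_sd))
  if (!is.null(r$p_values)) {
    cat(sprintf("  permutation p: NMC %.4g, AUROC %.4g, DQ2 %.4g\n",
                r$p_values$nmc, r$p_values$auroc, r$p_values$dq2))
  }
  cat(sprintf("  selected analytes: %s\n",
              paste(r$selected_analytes, collapse = ", ")))
  cat(sprintf("  SIMCA (%d PCs): calibration %.1f/%.1f, CV %.1f/%.1f (sens/spec %%)\n",
              r$simca$a_pc,
              r$simca$calibration$sensitivity,
              r$simca$calibration$specificity,
              r$simca$cross_validation$sensitivity,
              r$simca$cross_validation$specificity))
  invisible(x)
}
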