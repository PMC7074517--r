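#' Permutation test of the rDCV figures of merit
#'
#' Estimates the null distribution of NMC, AUROC and DQ2 by repeatedly
#' permuting the class labels and re-running the whole double
#' cross-validated pipeline (fusion scaling refit inside every fold,
#' inner-loop complexity selection, outer-loop prediction). The observed
#' merit of each statistic is its mean across the repetitions of the
#' un-permuted rDCV run; each permutation contributes the mean across
#' `perm_repetitions` repetitions of its own run.
#'
#' P-values use the add-one estimator
#' `p = (1 + #extreme) / (n_perm + 1)`, where "at least as extreme" means
#' `NMC <= observed` and `AUROC, DQ2 >= observed`; p-values therefore lie
#' in `(0, 1]` and can never be exactly zero.
#'
#' @param data A [multiblock_dataset()].
#' @param config An [rdcv_config()] describing the observed pipeline.
#' @param n_perm Number of label randomizations (default 1000).
#' @param perm_repetitions rDCV repetitions per randomization (default 1;
#'   each permutation's merit is an unbiased draw from the null either
#'   way, a larger value only reduces its Monte-Carlo spread at
#'   proportional cost).
#' @param observed Optionally, a precomputed `rdcv_result` for `data` and
#'   `config`, to avoid re-running the observed arm.
#' @return A `permutation_result` with `observed` (named merit means),
#'   `null` (data frame of null merits, one row per randomization),
#'   `p_values`, and counts.
#' @export
permutation_test <- function(data, config = rdcv_config(), n_perm = 1000,
                             perm_repetitions = 1, observed = NULL) {
  stopifnot(inherits(data, "multiblock_dataset"),
            inherits(config, "rdcv_config"))
  if (n_perm < 1) stop_input("n_perm must be >= 1")
  if (perm_repetitions < 1) stop_input("perm_repetitions must be >= 1")
  if (is.null(observed)) observed <- run_rdcv(data, config)
  stopifnot(inherits(observed, "rdcv_result"))
  obs <- c(nmc = mean(observed$merits$nmc),
           auroc = mean(observed$merits$auroc),
           dq2 = mean(observed$merits$dq2))

  null_m <- matrix(NA_real_, n_perm, 3,
                   dimnames = list(NULL, c("nmc", "auroc", "dq2")))
  for (b in seq_len(n_perm)) {
    perm <- with_seed(derive_seed(config$seed, 23L, b),
                      sample(length(data$labels)))
    data_b <- data
    data_b$labels <- data$labels[perm]
    cfg_b <- config
    cfg_b$repetitions <- as.integer(perm_repetitions)
    cfg_b$seed <- derive_seed(config$seed, 29L, b)
    res_b <- run_rdcv(data_b, cfg_b)
    null_m[b, ] <- c(mean(res_b$merits$nmc), mean(res_b$merits$auroc),
                     mean(res_b$merits$dq2))
  }
  extreme <- c(nmc = sum(null_m[, "nmc"] <= obs[["nmc"]]),
               auroc = sum(null_m[, "auroc"] >= obs[["auroc"]]),
               dq2 = sum(null_m[, "dq2"] >= obs[["dq2"]]))
  structure(
    list(observed = obs, null = as.data.frame(null_m),
         p_values = (1 + extreme) / (n_perm + 1),
         n_perm = n_perm, perm_repetitions = perm_repetitions,
         observed_result = observed),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: %d randomizations\n", x$n_perm))
  for (m in names(x$observed)) {
    cat(sprintf("  %-6s observed %8.4f   p = %.4g\n",
                m, x$observed[[m]], x$p_values[[m]]))
  }
  invisible(x)
}
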