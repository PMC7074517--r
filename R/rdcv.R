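#' Configuration for repeated double cross-validation
#'
#' @param repetitions Number of independent double-CV repetitions
#'   (default 30).
#' @param outer_folds Outer (performance-estimation) folds, default 7.
#' @param inner_folds Inner (complexity-selection) folds, default 5.
#' @param a_max Largest candidate latent-variable count, default 10
#'   (capped per fold at `min(n_train - 1, p)`).
#' @param seed Master seed; per-repetition and per-permutation streams are
#'   derived from it deterministically.
#' @param stratified Stratify fold assignment by class (default `TRUE`).
#' @param threshold Classification threshold on the predicted response.
#' @param refit_scaling Refit the fusion scaling inside every training
#'   fold (default `TRUE`). `FALSE` reproduces the variant that scales the
#'   full dataset once before cross-validation; it leaks distributional
#'   information from test folds and exists for strict replication of that
#'   practice only.
#' @return A list of class `rdcv_config`.
#' @export
rdcv_config <- function(repetitions = 30, outer_folds = 7, inner_folds = 5,
                        a_max = 10, seed = 1, stratified = TRUE,
                        threshold = 0.5, refit_scaling = TRUE) {
  cfg <- list(repetitions = as.integer(repetitions),
              outer_folds = as.integer(outer_folds),
              inner_folds = as.integer(inner_folds),
              a_max = as.integer(a_max), seed = as.integer(seed),
              stratified = isTRUE(stratified), threshold = threshold,
              refit_scaling = isTRUE(refit_scaling))
  if (cfg$repetitions < 1) stop_input("repetitions must be >= 1")
  if (cfg$outer_folds < 2 || cfg$inner_folds < 2) {
    stop_input("outer and inner fold counts must be >= 2")
  }
  if (cfg$a_max < 1) stop_input("a_max must be >= 1")
  class(cfg) <- "rdcv_config"
  cfg
}

# Canonical fused column order of a dataset: blocks in first-appearance
# order, analytes in panel order within block.
fused_order_data <- function(data) {
  unlist(lapply(unique(data$block), function(b) {
    colnames(data$x)[data$block == b]
  }), use.names = FALSE)
}

# Lean fused scaling on plain matrices (hot path of the CV loops).
# Returns the combined per-column denominator sd * block_norm so one
# division applies autoscaling and block normalization together. The
# Frobenius norm of an autoscaled training block is sqrt((n - 1) * p_b)
# exactly (every autoscaled column has sum of squares n - 1), so block
# norms need no second pass over the data.
scale_fit_mat <- function(x, block_size_of_col, context = NULL) {
  n <- nrow(x)
  center <- colMeans(x)
  xc <- x - rep(center, each = n)
  sdev <- sqrt(colSums(xc * xc) / (n - 1))
  if (any(sdev <= 0 | !is.finite(sdev))) {
    bad <- colnames(x)[sdev <= 0 | !is.finite(sdev)]
    stop_input("zero-variance analyte(s) ",
               if (!is.null(context)) paste0("in ", context, " "),
               "training data: ", paste(bad, collapse = ", "))
  }
  list(center = center,
       denom = sdev * sqrt((n - 1) * block_size_of_col))
}

scale_apply_mat <- function(sf, x) {
  n <- nrow(x)
  (x - rep(sf$center, each = n)) / rep(sf$denom, each = n)
}

#' Run repeated double cross-validation of the fused PLS-DA pipeline
#'
#' For each repetition: a stratified outer split into `outer_folds`
#' segments; for each outer fold, an inner cross-validation on the outer
#' training set selects the latent-variable count minimizing the summed
#' inner number of misclassifications (ties to the smallest count); the
#' fusion scaling and the PLS-DA model are then refit on the outer
#' training set only and the held-out fold is predicted. Per repetition,
#' the figures of merit (NMC, AUROC, DQ2) are computed on the pooled
#' out-of-fold predictions, in which each sample appears exactly once.
#' The absolute regression coefficients of every outer-fold model (one
#' "segment" per outer fold per repetition) are recorded for rank-product
#' ranking.
#'
#' @param data A [multiblock_dataset()] with both classes present.
#' @param config An [rdcv_config()].
#' @return An `rdcv_result` with elements `oof` (repetitions x samples
#'   continuous predictions), `labels`, `merits` (per-repetition NMC,
#'   AUROC, DQ2), `class_correct` (per-repetition percent correct per
#'   class and overall), `chosen_a`, `segment_coefs`
#'   (segments x variables, absolute coefficients in fused column order),
#'   `analytes`, and the `config`.
#' @export
run_rdcv <- function(data, config = rdcv_config()) {
  stopifnot(inherits(data, "multiblock_dataset"),
            inherits(config, "rdcv_config"))
  y <- check_binary_labels(data$labels)
  n <- length(y)
  ord <- fused_order_data(data)
  xo <- data$x[, ord, drop = FALSE]
  block_of_col <- unname(data$block[ord])
  block_size <- table(block_of_col)[block_of_col]  # block size per column
  block_size <- as.numeric(block_size)
  p <- ncol(xo)
  n_min_class <- min(sum(y == 1), sum(y == 0))
  if (config$stratified && config$outer_folds > n_min_class) {
    stop_input("outer_folds exceeds the smaller class size; ",
               "infeasible stratified split")
  }
  if (config$outer_folds > n) stop_input("outer_folds exceeds sample count")

  reps <- config$repetitions
  k_out <- config$outer_folds
  oof <- matrix(NA_real_, reps, n, dimnames = list(NULL, data$sample_ids))
  chosen_a <- matrix(NA_integer_, reps, k_out)
  seg_coefs <- matrix(NA_real_, reps * k_out, p,
                      dimnames = list(NULL, ord))
  full_sf <- if (!config$refit_scaling) {
    scale_fit_mat(xo, block_size, context = "full-data")
  }

  for (r in seq_len(reps)) {
    with_seed(derive_seed(config$seed, 17L, r), {
      folds <- if (config$stratified) {
        stratified_folds(y, k_out)
      } else {
        sample(rep_len(seq_len(k_out), n))
      }
      for (k in seq_len(k_out)) {
        test <- which(folds == k)
        train <- which(folds != k)
        y_tr <- y[train]
        if (length(unique(y_tr)) < 2L) {
          stop_input(sprintf(
            "outer fold %d of repetition %d has a single-class training set",
            k, r))
        }
        a_star <- select_inner_a(xo, y, train, block_size, config,
                                 full_sf)
        sf <- if (config$refit_scaling) {
          scale_fit_mat(xo[train, , drop = FALSE], block_size,
                        context = sprintf("outer fold %d", k))
        } else full_sf
        ftr <- scale_apply_mat(sf, xo[train, , drop = FALSE])
        fte <- scale_apply_mat(sf, xo[test, , drop = FALSE])
        fit <- pls1_nipals(ftr, y_tr, min(a_star, length(train) - 1L, p))
        path <- pls1_coef_path(fit)
        b <- path$B[, fit$a]
        oof[r, test] <- path$intercepts[fit$a] + drop(fte %*% b)
        chosen_a[r, k] <- fit$a
        # fused-scale coefficients: variables are standardized, so |b| is
        # comparable across analytes within a segment
        seg_coefs[(r - 1L) * k_out + k, ] <- abs(b)
      }
    })
  }

  pred_lab <- (oof > config$threshold) * 1
  merits <- data.frame(
    rep = seq_len(reps),
    nmc = apply(pred_lab, 1, function(pl) sum(pl != y)),
    auroc = apply(oof, 1, function(s) auroc(y, s)),
    dq2 = apply(oof, 1, function(s) dq2(y, s))
  )
  class_correct <- data.frame(
    rep = seq_len(reps),
    case_pc = rowMeans(pred_lab[, y == 1, drop = FALSE] == 1) * 100,
    control_pc = rowMeans(pred_lab[, y == 0, drop = FALSE] == 0) * 100,
    overall_pc = rowMeans(sweep(pred_lab, 2, y, "==") + 0) * 100
  )
  structure(
    list(oof = oof, labels = y, merits = merits,
         class_correct = class_correct, chosen_a = chosen_a,
         segment_coefs = seg_coefs, analytes = ord, config = config),
    class = "rdcv_result"
  )
}

# Inner-loop complexity selection: stratified inner CV on the outer
# training rows; returns the candidate minimizing the summed inner NMC
# (ties to the smallest count). Held-out predictions for every candidate
# component count come from the sequential score recursion
# (t_a = E w_a; yhat += t_a q_a; E -= t_a p_a'), which is algebraically
# identical to predicting with the composite coefficients at each count.
select_inner_a <- function(xo, y, train, block_size, config, full_sf) {
  k_in <- config$inner_folds
  y_tr <- y[train]
  inner <- stratified_folds(y_tr, k_in)
  sizes <- tabulate(inner, k_in)
  a_cap <- min(config$a_max, ncol(xo), length(train) - max(sizes) - 1L)
  if (a_cap < 1L) stop_input("inner folds leave too few training samples")
  miss <- numeric(a_cap)
  for (j in seq_len(k_in)) {
    it <- train[inner != j]
    iv <- train[inner == j]
    if (length(iv) == 0L) next
    if (length(unique(y[it])) < 2L) {
      stop_input("an inner training fold has a single class; ",
                 "reduce inner_folds")
    }
    sf <- if (config$refit_scaling) {
      scale_fit_mat(xo[it, , drop = FALSE], block_size,
                    context = "inner fold")
    } else full_sf
    fit <- pls1_nipals(scale_apply_mat(sf, xo[it, , drop = FALSE]),
                       y[it], a_cap)
    fv <- scale_apply_mat(sf, xo[iv, , drop = FALSE])
    nv <- nrow(fv)
    ev <- fv - rep(fit$xmean, each = nv)
    yhat <- rep(fit$ymean, nv)
    yv1 <- y[iv] == 1
    err_last <- 0
    for (a in seq_len(fit$a)) {
      t_new <- ev %*% fit$W[, a]
      yhat <- yhat + t_new * fit$q[a]
      ev <- ev - tcrossprod(t_new, fit$P[, a])
      err_last <- sum((yhat > config$threshold) != yv1)
      miss[a] <- miss[a] + err_last
    }
    if (fit$a < a_cap) {          # components beyond extraction repeat the last
      miss[(fit$a + 1L):a_cap] <- miss[(fit$a + 1L):a_cap] + err_last
    }
  }
  which.min(miss)                 # first minimum = smallest a on ties
}

#' @export
print.rdcv_result <- function(x, ...) {
  s <- classification_summary(x)
  cat(sprintf(
    "rdcv_result: %d repetitions x %d outer folds on %d samples\n",
    nrow(x$merits), ncol(x$chosen_a), length(x$labels)))
  cat(sprintf("  case    %5.1f%% +/- %.1f%% correct\n",
              s$case_mean, s$case_sd))
  cat(sprintf("  control %5.1f%% +/- %.1f%% correct\n",
              s$control_mean, s$control_sd))
  cat(sprintf("  overall %5.1f%% +/- %.1f%% correct\n",
              s$overall_mean, s$overall_sd))
  cat(sprintf("  mean NMC %.2f, mean AUROC %.3f, mean DQ2 %.3f\n",
              mean(x$merits$nmc), mean(x$merits$auroc),
              mean(x$merits$dq2)))
  invisible(x)
}

#' Summarize rDCV classification performance across repetitions
#'
#' Percent correctly classified per class and overall, computed per
#' repetition on the pooled out-of-fold predictions and then averaged
#' across repetitions (standard deviation with `n - 1` denominator).
#'
#' @param result An `rdcv_result` from [run_rdcv()].
#' @return A list with `case_mean`, `case_sd`, `control_mean`,
#'   `control_sd`, `overall_mean`, `overall_sd` (percent).
#' @export
classification_summary <- function(result) {
  stopifnot(inherits(result, "rdcv_result"))
  cc <- result$class_correct
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  list(case_mean = mean(cc$case_pc), case_sd = sd0(cc$case_pc),
       control_mean = mean(cc$control_pc), control_sd = sd0(cc$control_pc),
       overall_mean = mean(cc$overall_pc), overall_sd = sd0(cc$overall_pc))
}
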