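#' Fit a one-class SIMCA model
#'
#' Builds a class model by principal component analysis of the class-only
#' data: variables are autoscaled within the class, the PC subspace is
#' obtained by singular value decomposition, and two complementary
#' statistics describe each sample's position — Hotelling's T2 (the
#' Mahalanobis distance from the class center within the score space,
#' using per-component score variances) and the Q residual (squared
#' orthogonal distance from the PC subspace). The calibration 95th
#' percentiles of both statistics (linear-interpolation empirical
#' quantiles) are stored so new samples can be scored on the "reduced"
#' scale, in which the two statistics are comparable.
#'
#' @param class_data Numeric matrix of class-only samples (rows) by
#'   variables (columns).
#' @param a_pc Number of principal components; must be below the class
#'   sample count and at most the data rank.
#' @param threshold Acceptance threshold on the combined distance
#'   (default 2).
#' @return A `simca_model` with the within-class `center`/`scale`, the
#'   orthonormal `loadings`, per-component score variances `lambda`,
#'   calibration statistics and their 95th percentiles `t2_95`, `q_95`.
#' @export
fit_simca <- function(class_data, a_pc, threshold = 2) {
  x <- as.matrix(class_data)
  n <- nrow(x)
  p <- ncol(x)
  if (!is.numeric(a_pc) || length(a_pc) != 1L || a_pc < 1 ||
      a_pc != round(a_pc)) {
    stop_input("`a_pc` must be a positive integer")
  }
  if (n <= a_pc) stop_input("class sample count must exceed a_pc")
  center <- colMeans(x)
  sdev <- sqrt(colSums(sweep(x, 2, center)^2) / (n - 1))
  if (any(sdev <= 0 | !is.finite(sdev))) {
    bad <- (colnames(x) %||% paste0("V", seq_len(p)))[sdev <= 0 |
                                                        !is.finite(sdev)]
    stop_input("zero-variance variable(s) within the class: ",
               paste(bad, collapse = ", "))
  }
  z <- sweep(sweep(x, 2, center), 2, sdev, "/")
  sv <- svd(z, nu = 0, nv = min(n, p))
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (a_pc > rank) {
    stop_input(sprintf("a_pc = %d exceeds the class data rank (%d)",
                       a_pc, rank))
  }
  loadings <- sv$v[, seq_len(a_pc), drop = FALSE]
  rownames(loadings) <- colnames(x)
  scores <- z %*% loadings
  lambda <- colSums(scores^2) / (n - 1)
  t2 <- rowSums(sweep(scores^2, 2, lambda, "/"))
  q <- rowSums((z - tcrossprod(scores, loadings))^2)
  structure(
    list(center = center, scale = sdev, loadings = loadings,
         lambda = lambda, a_pc = as.integer(a_pc),
         t2_cal = t2, q_cal = q,
         t2_95 = unname(stats::quantile(t2, 0.95, type = 7)),
         q_95 = unname(stats::quantile(q, 0.95, type = 7)),
         threshold = threshold, variables = colnames(x)),
    class = "simca_model"
  )
}

#' @export
print.simca_model <- function(x, ...) {
  cat(sprintf(
    "simca_model: %d PCs over %d variables (T2_95 %.3g, Q_95 %.3g)\n",
    x$a_pc, length(x$center), x$t2_95, x$q_95))
  invisible(x)
}

# Reduced statistic: divide by the calibration 95th percentile; a
# degenerate percentile (e.g. Q identically zero at full rank) maps
# zero-valued statistics to zero and anything larger to Inf.
reduce_stat <- function(v, v95) {
  if (v95 > 0) return(v / v95)
  ifelse(v <= 1e-12, 0, Inf)
}

#' Per-sample SIMCA statistics
#'
#' Scores samples against a fitted class model: T2, Q, their reduced
#' versions (divided by the calibration 95th percentiles) and the
#' combined distance to the model
#' `d = sqrt(T2_red^2 + Q_red^2)`,
#' which is zero at the class centroid and grows with either departure
#' from the class's score-space spread or from its PC subspace.
#'
#' @param model A `simca_model`.
#' @param x Numeric matrix (samples x variables) or a single sample as a
#'   vector, with the model's variable count.
#' @return `simca_stats()`: data frame with `t2`, `q`, `t2_red`, `q_red`,
#'   `d`, `accepted`. `simca_distance()`: the `d` vector only.
#' @export
simca_stats <- function(model, x) {
  stopifnot(inherits(model, "simca_model"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$center)) {
    stop_input(sprintf("sample has %d variables; model expects %d",
                       ncol(x), length(model$center)))
  }
  if (!is.null(model$variables) && !is.null(colnames(x))) {
    if (!identical(colnames(x), model$variables)) {
      if (!setequal(colnames(x), model$variables)) {
        stop_input("variable names do not match the class model")
      }
      x <- x[, model$variables, drop = FALSE]
    }
  }
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  scores <- z %*% model$loadings
  t2 <- rowSums(sweep(scores^2, 2, model$lambda, "/"))
  q <- rowSums((z - tcrossprod(scores, model$loadings))^2)
  t2_red <- reduce_stat(t2, model$t2_95)
  q_red <- reduce_stat(q, model$q_95)
  d <- sqrt(t2_red^2 + q_red^2)
  data.frame(t2 = t2, q = q, t2_red = t2_red, q_red = q_red, d = d,
             accepted = d < model$threshold)
}

#' @rdname simca_stats
#' @export
simca_distance <- function(model, x) {
  simca_stats(model, x)$d
}

#' Accept or reject samples against a SIMCA class model
#'
#' A sample is accepted by the class when its combined distance is
#' strictly below the threshold (`d < 2` by default); a sample exactly at
#' the threshold is rejected.
#'
#' @inheritParams simca_stats
#' @param threshold Optional override of the model's threshold.
#' @return Logical vector of acceptance flags.
#' @export
simca_classify <- function(model, x, threshold = model$threshold) {
  simca_distance(model, x) < threshold
}

#' Sensitivity, specificity and efficiency of a SIMCA class model
#'
#' Sensitivity is the percentage of samples from the modeled class
#' accepted by the model; specificity the percentage of samples from
#' other classes rejected; efficiency their geometric mean.
#'
#' @param model A `simca_model`.
#' @param in_class_data Samples from the modeled class.
#' @param out_class_data Samples from other classes.
#' @param mode Label recorded in the result (`"calibration"` or
#'   `"cross-validation"`).
#' @return A list of class `simca_assessment` with `sensitivity`,
#'   `specificity`, `efficiency` (percent) and `mode`.
#' @export
simca_assess <- function(model, in_class_data, out_class_data,
                         mode = "calibration") {
  if (NROW(in_class_data) < 1L || NROW(out_class_data) < 1L) {
    stop_input("both in-class and out-of-class data must be nonempty")
  }
  sens <- mean(simca_classify(model, in_class_data)) * 100
  spec <- mean(!simca_classify(model, out_class_data)) * 100
  structure(
    list(sensitivity = sens, specificity = spec,
         efficiency = sqrt(sens * spec), mode = mode),
    class = "simca_assessment"
  )
}

#' @export
print.simca_assessment <- function(x, ...) {
  cat(sprintf(
    "simca_assessment (%s): sensitivity %.1f%%, specificity %.1f%%, efficiency %.1f%%\n",
    x$mode, x$sensitivity, x$specificity, x$efficiency))
  invisible(x)
}

#' Select the SIMCA component count by cross-validated efficiency
#'
#' Splits the in-class samples into venetian-blinds folds (sample `i`
#' goes to fold `((i - 1) mod folds) + 1`). For every candidate component
#' count, each fold's model is fit on the remaining in-class samples;
#' held-out in-class samples contribute to CV sensitivity, and the
#' out-of-class samples — scored against each fold's model and averaged
#' over folds — give CV specificity. The component count maximizing CV
#' efficiency is returned, ties going to the smaller count.
#'
#' @param in_class_data Samples of the modeled class.
#' @param out_class_data Samples of the other class(es).
#' @param cv_folds Number of venetian-blinds folds (default 7).
#' @param a_max Largest candidate component count (capped by fold
#'   training size and data rank).
#' @param threshold Acceptance threshold (default 2).
#' @return A list with `a_pc` (chosen count) and `table` (per-candidate
#'   CV sensitivity, specificity and efficiency, in percent).
#' @export
select_npc <- function(in_class_data, out_class_data, cv_folds = 7,
                       a_max = 10, threshold = 2) {
  xin <- as.matrix(in_class_data)
  n <- nrow(xin)
  if (cv_folds < 2 || cv_folds > n) {
    stop_input("cv_folds must be between 2 and the in-class sample count")
  }
  folds <- ((seq_len(n) - 1L) %% cv_folds) + 1L
  min_train <- n - max(tabulate(folds, cv_folds))
  a_hi <- min(a_max, ncol(xin), min_train - 1L)
  if (a_hi < 1L) stop_input("folds leave too few in-class training samples")
  tab <- data.frame(a = seq_len(a_hi), sensitivity = NA_real_,
                    specificity = NA_real_, efficiency = NA_real_)
  for (a in seq_len(a_hi)) {
    acc_in <- logical(n)
    rej_out <- numeric(cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- xin[folds != f, , drop = FALSE]
      m <- fit_simca(tr, a, threshold = threshold)
      acc_in[folds == f] <-
        simca_classify(m, xin[folds == f, , drop = FALSE])
      rej_out[f] <- mean(!simca_classify(m, out_class_data))
    }
    sens <- mean(acc_in) * 100
    spec <- mean(rej_out) * 100
    tab[a, c("sensitivity", "specificity", "efficiency")] <-
      c(sens, spec, sqrt(sens * spec))
  }
  list(a_pc = tab$a[which.max(tab$efficiency)], table = tab)
}
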