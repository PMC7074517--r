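#' Variable importance in projection (VIP) scores
#'
#' Apportions the response variance explained by a fitted PLS-DA model to
#' the individual predictors:
#' `VIP_j = sqrt(p * sum_a (w_ja / ||w_a||)^2 * SSY_a / sum_a SSY_a)`,
#' where `SSY_a = q_a^2 * t_a' t_a` is the response sum of squares
#' explained by component `a`. The scaling makes the squared scores
#' average one over the `p` predictors (`sum VIP_j^2 = p`), so a
#' "greater than 1" rule flags variables contributing more than an
#' average share.
#'
#' @param model A fitted `plsda_model` (with training scores).
#' @return A data frame with `analyte`, `vip` and `selected`
#'   (`vip > 1`), in the model's variable order.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  if (is.null(model$T)) {
    stop_input("model carries no training scores; VIP needs a model ",
               "fitted in this session")
  }
  p <- nrow(model$W)
  ssy <- model$q^2 * colSums(model$T^2)
  wnorm2 <- colSums(model$W^2)
  scores <- sqrt(p * drop(sweep(model$W^2, 2, wnorm2, "/") %*% ssy) /
                   sum(ssy))
  data.frame(
    analyte = model$variables %||% paste0("V", seq_len(p)),
    vip = scores,
    selected = scores > 1,
    stringsAsFactors = FALSE
  )
}

#' Rank products of regression coefficients across rDCV segments
#'
#' In every resampling segment (one outer-fold model of one repetition),
#' variables are ranked by decreasing absolute regression coefficient:
#' the most discriminant variable gets rank 1, ties receive average
#' ranks. A variable's rank product is the geometric mean of its ranks
#' over all segments (computed as the exponential of the mean log rank);
#' consistently discriminant variables have rank products near 1.
#'
#' @param result An `rdcv_result` from [run_rdcv()], or a numeric matrix
#'   of absolute coefficients (segments x variables).
#' @return A list of class `rp_result` with `rp` (named vector, ascending
#'   is better), `ranks` (segments x variables rank table) and
#'   `n_segments`.
#' @export
rank_product <- function(result) {
  coefs <- if (inherits(result, "rdcv_result")) {
    result$segment_coefs
  } else {
    as.matrix(result)
  }
  if (nrow(coefs) < 1L) stop_input("no segments to rank")
  ranks <- t(apply(coefs, 1, function(b) rank(-abs(b))))
  colnames(ranks) <- colnames(coefs)
  rp <- exp(colMeans(log(ranks)))
  structure(list(rp = rp, ranks = ranks, n_segments = nrow(ranks)),
            class = "rp_result")
}

#' @export
print.rp_result <- function(x, ...) {
  cat(sprintf("rp_result: %d variables over %d segments\n",
              length(x$rp), x$n_segments))
  top <- sort(x$rp)[seq_len(min(10, length(x$rp)))]
  cat("  lowest rank products:\n")
  for (nm in names(top)) cat(sprintf("    %-14s %.2f\n", nm, top[[nm]]))
  invisible(x)
}

#' Select candidate biomarkers from VIP and rank-product scores
#'
#' Candidates are the variables passing the VIP > 1 rule, ordered by
#' ascending rank product (most consistently discriminant first) and
#' truncated to `k`. Both full score tables should always be reported
#' alongside the selection; the returned attribute `"table"` carries the
#' merged scores for all variables.
#'
#' @param vip_result Data frame from [vip()].
#' @param rp_result An `rp_result` from [rank_product()].
#' @param k Maximum number of candidates (default 7).
#' @return Character vector of selected analytes (possibly shorter than
#'   `k`), with the full merged score table as attribute `"table"`.
#' @export
select_candidates <- function(vip_result, rp_result, k = 7) {
  stopifnot(inherits(rp_result, "rp_result"))
  if (!setequal(vip_result$analyte, names(rp_result$rp))) {
    stop_input("VIP and rank-product results cover different analytes")
  }
  if (k < 1) stop_input("k must be >= 1")
  tab <- data.frame(
    analyte = vip_result$analyte,
    vip = vip_result$vip,
    rp = unname(rp_result$rp[vip_result$analyte]),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$rp), ]
  tab$selected <- FALSE
  hits <- tab$analyte[tab$vip > 1]
  sel <- utils::head(hits, k)
  tab$selected[tab$analyte %in% sel] <- TRUE
  rownames(tab) <- NULL
  structure(sel, table = tab)
}

#' Fit the final all-sample PLS-DA model underlying VIP inspection
#'
#' Refits the fusion scaling and the PLS-DA model on all samples at the
#' consensus complexity of a finished rDCV run (the across-segment median
#' of the selected latent-variable counts, rounded to the nearest
#' integer, half up).
#'
#' @param data The [multiblock_dataset()] the rDCV was run on.
#' @param result The corresponding `rdcv_result`.
#' @return A `plsda_model` fitted to the fused full dataset.
#' @export
fit_final_model <- function(data, result) {
  stopifnot(inherits(data, "multiblock_dataset"),
            inherits(result, "rdcv_result"))
  a_med <- as.integer(floor(stats::median(result$chosen_a) + 0.5))
  a_med <- max(1L, min(a_med, nrow(data$x) - 1L, ncol(data$x)))
  sm <- fit_scaling(data)
  fused <- apply_scaling(sm, data)
  fit_plsda(fused, data$labels, a = a_med,
            threshold = result$config$threshold)
}
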