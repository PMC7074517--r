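# NIPALS PLS1 on a centered predictor matrix and centered response.
# No y-deflation: with X-deflation the successive weights are unchanged by
# deflating y, since deflated X columns are orthogonal to earlier scores.
# Returns component matrices trimmed to the number of extractable
# components (a degenerate X'y residual stops extraction early).
pls1_nipals <- function(X, y, a_max) {
  n <- nrow(X)
  p <- ncol(X)
  xmean <- colMeans(X)
  ymean <- mean(y)
  E <- X - rep(xmean, each = n)
  yc <- y - ymean
  W <- matrix(0, p, a_max)
  P <- matrix(0, p, a_max)
  Tm <- matrix(0, n, a_max)
  q <- numeric(a_max)
  a_used <- 0L
  for (a in seq_len(a_max)) {
    w <- crossprod(E, yc)
    nw <- sqrt(sum(w * w))
    if (nw < 1e-12) break
    w <- w / nw
    tt_vec <- E %*% w
    tt <- sum(tt_vec * tt_vec)
    if (tt < 1e-12) break
    pa <- crossprod(E, tt_vec) / tt
    qa <- sum(yc * tt_vec) / tt
    E <- E - tcrossprod(tt_vec, pa)
    W[, a] <- w
    P[, a] <- pa
    Tm[, a] <- tt_vec
    q[a] <- qa
    a_used <- a
  }
  if (a_used == 0L) stop_input("no PLS component could be extracted")
  idx <- seq_len(a_used)
  list(W = W[, idx, drop = FALSE], P = P[, idx, drop = FALSE],
       T = Tm[, idx, drop = FALSE], q = q[idx],
       xmean = xmean, ymean = ymean, a = a_used)
}

# Composite regression coefficients b_A = W (P'W)^{-1} q for every
# component count 1..fit$a; column a of the result predicts with the first
# a latent variables. Intercepts restore the original y scale.
pls1_coef_path <- function(fit) {
  R <- crossprod(fit$P, fit$W)
  B <- matrix(0, nrow(fit$W), fit$a)
  intercepts <- numeric(fit$a)
  for (a in seq_len(fit$a)) {
    ia <- seq_len(a)
    B[, a] <- fit$W[, ia, drop = FALSE] %*%
      solve(R[ia, ia, drop = FALSE], fit$q[ia])
    intercepts[a] <- fit$ymean - sum(fit$xmean * B[, a])
  }
  list(B = B, intercepts = intercepts)
}

#' Fit a PLS-DA model
#'
#' Partial least squares discriminant analysis: a NIPALS PLS1 regression of
#' the binary dummy response (0 = control, 1 = case) on the predictor
#' matrix, followed by threshold classification of the predicted response.
#' Per component, the weight vector is proportional to `X'y` on the
#' deflated predictors (the direction of maximum covariance with the
#' response); scores are `t = X w`; `X` is deflated by `t p'`.
#'
#' @param X Numeric predictor matrix (samples x variables), typically a
#'   fused matrix from [apply_scaling()].
#' @param y Binary response vector (0/1), both classes present.
#' @param a Number of latent variables, `1 <= a <= min(n - 1, p)`.
#' @param threshold Classification threshold on the predicted response;
#'   default 0.5, the midpoint of the 0/1 coding.
#' @return A `plsda_model` with weights `W`, loadings `P`, response
#'   loadings `q`, training scores `T`, composite coefficients `b`,
#'   `intercept`, and `threshold`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 12, 5)
#' y <- rep(c(0, 1), each = 6)
#' m <- fit_plsda(X, y, a = 2)
#' classify(m, X)
#' @export
fit_plsda <- function(X, y, a, threshold = 0.5) {
  X <- as.matrix(X)
  y <- check_binary_labels(y)
  if (length(y) != nrow(X)) stop_input("length(y) must equal nrow(X)")
  if (ncol(X) < 1L) stop_input("X has no predictors")
  a_cap <- min(nrow(X) - 1L, ncol(X))
  if (!is.numeric(a) || length(a) != 1L || a < 1 || a != round(a)) {
    stop_input("`a` must be a positive integer")
  }
  if (a > a_cap) {
    stop_input(sprintf("`a` = %d exceeds min(n - 1, p) = %d", a, a_cap))
  }
  fit <- pls1_nipals(X, y, as.integer(a))
  path <- pls1_coef_path(fit)
  b <- path$B[, fit$a]
  names(b) <- colnames(X)
  structure(
    list(a = fit$a, W = fit$W, P = fit$P, q = fit$q, T = fit$T,
         b = b, intercept = path$intercepts[fit$a],
         xmean = fit$xmean, ymean = fit$ymean,
         threshold = threshold, variables = colnames(X)),
    class = "plsda_model"
  )
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("plsda_model: %d latent variable(s), %d predictors, threshold %g\n",
              x$a, length(x$b), x$threshold))
  invisible(x)
}

#' Predict the continuous response of a PLS-DA model
#'
#' @param model A `plsda_model`.
#' @param x_new Numeric matrix (or single row as a vector) with the
#'   model's predictor count.
#' @return Numeric vector of predicted responses (unbounded).
#' @export
predict_response <- function(model, x_new) {
  stopifnot(inherits(model, "plsda_model"))
  if (is.vector(x_new)) x_new <- matrix(x_new, nrow = 1)
  x_new <- as.matrix(x_new)
  if (ncol(x_new) != length(model$b)) {
    stop_input(sprintf("x_new has %d columns; model expects %d",
                       ncol(x_new), length(model$b)))
  }
  drop(model$intercept + x_new %*% model$b)
}

#' Classify samples with a PLS-DA model
#'
#' A sample is called a case (label 1) when its predicted response is
#' strictly greater than the threshold; a predicted response exactly at
#' the threshold is a control.
#'
#' @inheritParams predict_response
#' @param threshold Optional override of the model's threshold.
#' @return Integer vector of 0/1 labels.
#' @export
classify <- function(model, x_new, threshold = model$threshold) {
  as.integer(predict_response(model, x_new) > threshold)
}

#' Serialize / restore a PLS-DA model as JSON
#'
#' @param model A `plsda_model`.
#' @param path JSON file path.
#' @return `plsda_to_json()` returns `path` invisibly; `plsda_from_json()`
#'   the restored model (training scores are not serialized).
#' @export
plsda_to_json <- function(model, path) {
  stopifnot(inherits(model, "plsda_model"))
  jsonlite::write_json(
    list(a = model$a, W = model$W, P = model$P, q = model$q,
         b = as.list(model$b), intercept = model$intercept,
         xmean = as.list(model$xmean), ymean = model$ymean,
         threshold = model$threshold, variables = model$variables),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname plsda_to_json
#' @export
plsda_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(a = j$a, W = as.matrix(j$W), P = as.matrix(j$P), q = j$q,
         T = NULL, b = unlist(j$b), intercept = j$intercept,
         xmean = unlist(j$xmean), ymean = j$ymean,
         threshold = j$threshold, variables = j$variables),
    class = "plsda_model"
  )
}
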