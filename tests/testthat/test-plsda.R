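test_that("a perfect univariate predictor is reproduced exactly", {
  y <- rep(c(0, 1), each = 5)
  X <- matrix(y - mean(y), ncol = 1, dimnames = list(NULL, "v"))
  m <- fit_plsda(X, y, a = 1)
  expect_equal(predict_response(m, X), y, tolerance = 1e-12)
  expect_equal(classify(m, X), as.integer(y))
})

test_that("the first weight vector is the covariance direction", {
  set.seed(10)
  X <- matrix(rnorm(80), 10, 8)
  y <- rep_len(c(0, 1), 10)
  m <- fit_plsda(X, y, a = 1)
  w_direct <- crossprod(sweep(X, 2, colMeans(X)), y - mean(y))
  w_direct <- w_direct / sqrt(sum(w_direct^2))
  # proportional up to sign (normalization fixes the scale)
  expect_equal(abs(sum(m$W[, 1] * w_direct)), 1, tolerance = 1e-10)
})

test_that("full-rank PLS equals least squares (normal-equations oracle)", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(30), 10, 3)
    y <- rep_len(c(0, 1), 10)
    m <- fit_plsda(X, y, a = 3)
    Xc <- cbind(1, X)
    beta <- solve(crossprod(Xc), crossprod(Xc, y))
    expect_equal(predict_response(m, X), drop(Xc %*% beta),
                 tolerance = 1e-8)
  }
})

test_that("composite coefficients match the sequential LV expansion", {
  set.seed(11)
  X <- matrix(rnorm(150), 15, 10)
  y <- rep_len(c(0, 1), 15)
  m <- fit_plsda(X, y, a = 4)
  Xnew <- matrix(rnorm(50), 5, 10)
  # sequential oracle: deflate the new data through the components
  E <- sweep(Xnew, 2, m$xmean)
  yhat <- rep(m$ymean, 5)
  for (a in seq_len(m$a)) {
    t_new <- E %*% m$W[, a]
    yhat <- yhat + t_new * m$q[a]
    E <- E - tcrossprod(t_new, m$P[, a])
  }
  expect_equal(predict_response(m, Xnew), drop(yhat), tolerance = 1e-10)
})

test_that("score vectors are mutually orthogonal", {
  set.seed(12)
  X <- matrix(rnorm(200), 20, 10)
  y <- rep_len(c(0, 1), 20)
  m <- fit_plsda(X, y, a = 5)
  G <- crossprod(m$T)
  nrm <- sqrt(diag(G))
  off <- abs(G / tcrossprod(nrm))
  diag(off) <- 0
  expect_lt(max(off), 1e-8)
})

test_that("training residuals are non-increasing in model complexity", {
  set.seed(13)
  X <- matrix(rnorm(240), 16, 15)
  y <- rep_len(c(0, 1), 16)
  rss <- vapply(1:8, function(a) {
    m <- fit_plsda(X, y, a = a)
    sum((y - predict_response(m, X))^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("predictions are invariant to predictor permutation at fixed a", {
  set.seed(14)
  X <- matrix(rnorm(120), 12, 10,
              dimnames = list(NULL, paste0("v", 1:10)))
  y <- rep_len(c(0, 1), 12)
  m1 <- fit_plsda(X, y, a = 3)
  perm <- sample(10)
  m2 <- fit_plsda(X[, perm], y, a = 3)
  expect_equal(predict_response(m1, X), predict_response(m2, X[, perm]),
               tolerance = 1e-10)
})

test_that("a zero row predicts the intercept and thresholding is strict", {
  set.seed(15)
  X <- matrix(rnorm(60), 12, 5)
  y <- rep_len(c(0, 1), 12)
  m <- fit_plsda(X, y, a = 2)
  expect_equal(predict_response(m, rep(0, 5)), m$intercept,
               tolerance = 1e-12)

  # strictly-greater rule: a prediction exactly at the threshold is a
  # control; flipping the coding flips every label
  expect_equal(classify(m, X, threshold = 0.5),
               as.integer(predict_response(m, X) > 0.5))
  yh <- predict_response(m, X)
  expect_equal(classify(m, X, threshold = yh[1])[1], 0L)
  flipped <- fit_plsda(X, 1 - y, a = 2)
  expect_equal(classify(flipped, X), 1L - classify(m, X))
})

test_that("invalid inputs are rejected", {
  set.seed(16)
  X <- matrix(rnorm(40), 8, 5)
  expect_error(fit_plsda(X, rep(1, 8), a = 1), "both classes")
  expect_error(fit_plsda(X, rep_len(c(0, 1), 8), a = 8), "exceeds")
  expect_error(fit_plsda(X, rep_len(c(0, 1), 8), a = 0), "positive")
  m <- fit_plsda(X, rep_len(c(0, 1), 8), a = 2)
  expect_error(predict_response(m, matrix(0, 1, 4)), "columns")
})

test_that("a PLS-DA model survives a JSON roundtrip", {
  set.seed(17)
  X <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- rep_len(c(0, 1), 12)
  m <- fit_plsda(X, y, a = 2)
  path <- file.path(tempdir(), "plsda.json")
  plsda_to_json(m, path)
  m2 <- plsda_from_json(path)
  expect_equal(predict_response(m2, X), predict_response(m, X),
               tolerance = 1e-10)
  expect_equal(m2$a, m$a)
  unlink(path)
})
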