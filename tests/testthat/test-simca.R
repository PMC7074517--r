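# Build a class dataset with a known 2-component structure plus noise.
planted_class <- function(seed, n = 40, p = 8, rank = 2, noise = 0.15) {
  set.seed(seed)
  scores <- matrix(rnorm(n * rank), n) %*%
    diag(c(3, 1.5)[seq_len(rank)], nrow = rank)
  load <- qr.Q(qr(matrix(rnorm(p * rank), p)))[, seq_len(rank)]
  5 + scores %*% t(load) + matrix(rnorm(n * p, sd = noise), n)
}

test_that("calibration statistics behave at the centroid and at full rank", {
  x <- planted_class(1)
  m <- fit_simca(x, a_pc = 2)
  centroid <- matrix(colMeans(x), 1)
  st <- simca_stats(m, centroid)
  expect_equal(st$t2, 0)
  expect_equal(st$q, 0)
  expect_equal(st$d, 0)
  expect_true(st$accepted)

  # full-rank model reconstructs perfectly: all Q residuals vanish
  mf <- fit_simca(x, a_pc = 8)
  expect_lt(max(mf$q_cal), 1e-16)
  expect_lt(max(simca_stats(mf, x)$q), 1e-16)
})

test_that("T2 matches an explicit Mahalanobis computation in score space", {
  set.seed(2)
  x <- matrix(rnorm(20 * 6), 20, 6)
  m <- fit_simca(x, a_pc = 3)
  z <- sweep(sweep(x, 2, m$center), 2, m$scale, "/")
  scores <- z %*% m$loadings
  t2_direct <- stats::mahalanobis(scores, rep(0, 3),
                                  diag(colSums(scores^2) / 19))
  expect_equal(simca_stats(m, x)$t2, t2_direct, tolerance = 1e-10)
  # loadings are columnwise orthonormal
  expect_equal(crossprod(m$loadings), diag(3), tolerance = 1e-8)
})

test_that("the combined distance follows the reduced T2/Q geometry", {
  x <- planted_class(3)
  m <- fit_simca(x, a_pc = 2)
  # construct a synthetic sample with prescribed (T2_red, Q_red):
  # in-plane displacement along PC1 sets T2, an orthogonal residual sets Q
  resid_dir <- svd(diag(8) - tcrossprod(m$loadings))$u[, 1]
  make_sample <- function(t2_red, q_red) {
    z <- sqrt(t2_red * m$t2_95 * m$lambda[1]) * m$loadings[, 1] +
      sqrt(q_red * m$q_95) * resid_dir
    matrix(m$center + z * m$scale, 1)
  }
  st <- simca_stats(m, make_sample(1, 1))
  expect_equal(st$t2_red, 1, tolerance = 1e-8)
  expect_equal(st$q_red, 1, tolerance = 1e-8)
  expect_equal(st$d, sqrt(2), tolerance = 1e-8)

  # monotone in each coordinate with the other fixed
  grid <- seq(0, 2.5, by = 0.25)
  d_t <- vapply(grid, function(g) simca_distance(m, make_sample(g, 0.7)),
                numeric(1))
  d_q <- vapply(grid, function(g) simca_distance(m, make_sample(0.7, g)),
                numeric(1))
  expect_true(all(diff(d_t) > 0))
  expect_true(all(diff(d_q) > 0))

  # acceptance region is the quarter-disk of radius 2: d < 2 exactly when
  # t2_red^2 + q_red^2 < 4, checked over a grid of constructed samples
  for (a in seq(0.1, 2.3, by = 0.4)) {
    for (b in seq(0.1, 2.3, by = 0.4)) {
      acc <- simca_classify(m, make_sample(a, b))
      expect_identical(unname(acc), a^2 + b^2 < 4)
    }
  }
})

test_that("acceptance uses a strict inequality at the threshold", {
  x <- planted_class(4)
  m <- fit_simca(x, a_pc = 2)
  d <- simca_distance(m, x[3, ])
  expect_false(simca_classify(m, x[3, ], threshold = d))
  expect_true(simca_classify(m, x[3, ], threshold = d + 1e-9))
})

test_that("calibration percentiles cover 95% of the class", {
  x <- planted_class(5, n = 200)
  m <- fit_simca(x, a_pc = 2)
  st <- simca_stats(m, x)
  expect_gte(mean(st$t2_red <= 1), 0.95)
  expect_gte(mean(st$q_red <= 1), 0.95)
})

test_that("sensitivity, specificity and efficiency combine correctly", {
  x <- planted_class(6)
  m <- fit_simca(x, a_pc = 2)
  out <- x + 40                       # far outside the class
  a <- simca_assess(m, x, out)
  expect_equal(a$specificity, 100)
  expect_equal(a$efficiency, sqrt(a$sensitivity * 100))

  fake <- structure(list(sensitivity = 90, specificity = 40,
                         efficiency = sqrt(90 * 40), mode = "calibration"),
                    class = "simca_assessment")
  expect_equal(fake$efficiency, 60)
  expect_error(simca_assess(m, x[0, ], out), "nonempty")
})

test_that("component selection maximizes cross-validated efficiency", {
  xin <- planted_class(7, n = 42)
  xout <- planted_class(8, n = 20) + 6
  sel <- select_npc(xin, xout, cv_folds = 7, a_max = 6)
  expect_true(sel$a_pc >= 1 && sel$a_pc <= 6)
  expect_equal(nrow(sel$table), 6)
  expect_equal(sel$a_pc,
               sel$table$a[which.max(sel$table$efficiency)])
  # single-candidate case
  expect_equal(select_npc(xin, xout, cv_folds = 7, a_max = 1)$a_pc, 1)
})

test_that("degenerate SIMCA inputs error clearly", {
  x <- planted_class(9, n = 10)
  expect_error(fit_simca(x, a_pc = 10), "exceed")
  expect_error(fit_simca(x, a_pc = 0), "positive")
  xc <- x; xc[, 2] <- 1
  expect_error(fit_simca(xc, a_pc = 2), "zero-variance")
  m <- fit_simca(x, a_pc = 2)
  expect_error(simca_stats(m, x[, 1:5]), "expects")
})
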