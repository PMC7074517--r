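test_that("default panel has the documented composition", {
  panel <- build_default_panel()
  expect_equal(nrow(panel), 37)
  expect_equal(as.integer(table(panel$block)[c(
    "multiplex_panel", "automated_immunoassay", "ev_immunoblot")]),
    c(27L, 4L, 6L))
  expect_equal(sum(panel$discriminant), 7)

  cd9 <- panel[panel$name == "CD9", ]
  expect_equal(cd9$case_median, 82.3)
  expect_equal(cd9$case_iqr, 53.2)
  expect_equal(cd9$control_median, 1133.4)
  expect_equal(cd9$control_iqr, 2710.4)
  expect_true(cd9$discriminant)

  # null analytes carry no between-arm difference
  nulls <- panel[!panel$discriminant, ]
  expect_equal(nulls$case_median, nulls$control_median)
  expect_equal(nulls$case_iqr, nulls$control_iqr)
})

test_that("log-normal moment matching reproduces median and IQR", {
  expect_equal(fit_lognormal(1, 0), c(mu = 0, sigma = 0))
  expect_error(fit_lognormal(0, 1), "positive")
  expect_error(fit_lognormal(-3, 1), "positive")
  expect_error(fit_lognormal(10, -1), "nonnegative")

  # quantile-function oracle: fitted parameters reproduce the inputs
  cases <- list(c(82.3, 53.2), c(1133.4, 2710.4), c(0.5, 0.7),
                c(115, 27.1), c(42.2, 10.2), c(100, 50), c(7, 1e-3))
  for (mi in cases) {
    p <- fit_lognormal(mi[1], mi[2])
    med <- qlnorm(0.5, p[["mu"]], p[["sigma"]])
    iqr <- qlnorm(0.75, p[["mu"]], p[["sigma"]]) -
      qlnorm(0.25, p[["mu"]], p[["sigma"]])
    expect_equal(med, mi[1], tolerance = 1e-6)
    expect_equal(iqr, mi[2], tolerance = 1e-6)
  }

  # median identity holds exactly for arbitrary inputs
  set.seed(41)
  for (i in 1:20) {
    m <- exp(rnorm(1, 2, 2))
    expect_identical(exp(fit_lognormal(m, runif(1, 0, 3 * m))[["mu"]]), m)
  }
})

test_that("cohort generation is seeded, structured, and strictly positive", {
  d <- generate_cohort(n_case = 16, n_control = 12, seed = 7)
  expect_s3_class(d, "multiblock_dataset")
  expect_equal(dim(d), c(28L, 37L))
  expect_equal(sum(d$labels == 1), 16)
  expect_equal(sum(d$labels == 0), 12)
  expect_true(all(d$x > 0))
  expect_equal(length(dataset_blocks(d)), 3)

  d2 <- generate_cohort(n_case = 16, n_control = 12, seed = 7)
  expect_identical(d$x, d2$x)
  d3 <- generate_cohort(n_case = 16, n_control = 12, seed = 8)
  expect_false(identical(d$x, d3$x))

  expect_error(generate_cohort(n_case = 1, n_control = 1), ">= 4")
})

test_that("effect overrides rewrite the case arm only", {
  ov <- list(CD9 = c(1133.4, 2710.4))
  d <- generate_cohort(seed = 3, effect_overrides = ov)
  expect_s3_class(d, "multiblock_dataset")
  expect_error(generate_cohort(effect_overrides = list(XYZ = c(1, 1))),
               "unknown analytes")

  # with the case arm overridden to the control parameters, large-sample
  # medians of the two arms coincide
  big <- generate_cohort(n_case = 2e4, n_control = 2e4, seed = 11,
                         effect_overrides = ov)
  m1 <- median(big$x[big$labels == 1, "CD9"])
  m0 <- median(big$x[big$labels == 0, "CD9"])
  expect_equal(m1 / m0, 1, tolerance = 0.1)
})

test_that("null analytes show no systematic between-arm shift", {
  diffs <- vapply(1:10, function(s) {
    d <- generate_cohort(seed = s)
    log(median(d$x[d$labels == 1, "IL6"])) -
      log(median(d$x[d$labels == 0, "IL6"]))
  }, numeric(1))
  # centered at zero: both signs occur and the mean is small relative to
  # the sampling spread
  expect_true(any(diffs > 0) && any(diffs < 0))
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)) + 0.2)
})

test_that("dataset CSV + sidecar roundtrip preserves everything", {
  d <- generate_cohort(seed = 5)
  path <- file.path(tempdir(), "cohort.csv")
  write_dataset(d, path)
  expect_true(file.exists(paste0(path, ".schema.json")))
  r <- read_dataset(path)
  expect_equal(r$labels, d$labels)
  expect_equal(r$block, d$block)
  expect_equal(r$sample_ids, d$sample_ids)
  expect_equal(unname(r$x), unname(d$x), tolerance = 1e-12)
  unlink(c(path, paste0(path, ".schema.json")))
})
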