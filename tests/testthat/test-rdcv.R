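small_cfg <- function(seed = 1, reps = 3) {
  rdcv_config(repetitions = reps, seed = seed)
}

test_that("rDCV is deterministic and covers every sample once per repetition", {
  d <- generate_cohort(seed = 2)
  r1 <- run_rdcv(d, small_cfg(seed = 5))
  r2 <- run_rdcv(d, small_cfg(seed = 5))
  expect_identical(r1$oof, r2$oof)
  expect_identical(r1$chosen_a, r2$chosen_a)
  expect_identical(r1$segment_coefs, r2$segment_coefs)
  r3 <- run_rdcv(d, small_cfg(seed = 6))
  expect_false(identical(r1$oof, r3$oof))

  # coverage: all 28 samples predicted in every repetition
  expect_false(anyNA(r1$oof))
  expect_equal(dim(r1$oof), c(3L, 28L))
  # segments = repetitions x outer folds, in fused variable order
  expect_equal(nrow(r1$segment_coefs), 3L * 7L)
  expect_equal(colnames(r1$segment_coefs), r1$analytes)
  expect_true(all(r1$chosen_a >= 1 & r1$chosen_a <= 10))
})

test_that("per-repetition merits are consistent with the pooled predictions", {
  d <- generate_cohort(seed = 3)
  r <- run_rdcv(d, small_cfg(seed = 9))
  for (i in seq_len(nrow(r$merits))) {
    pred <- as.integer(r$oof[i, ] > r$config$threshold)
    expect_equal(r$merits$nmc[i], nmc(r$labels, pred))
    expect_equal(r$merits$auroc[i], auroc(r$labels, r$oof[i, ]))
    expect_equal(r$merits$dq2[i], dq2(r$labels, r$oof[i, ]))
    expect_equal(r$class_correct$overall_pc[i],
                 100 * mean(pred == r$labels))
  }
})

test_that("classification summary averages repetitions with n-1 SD", {
  fake <- structure(list(class_correct = data.frame(
    rep = 1:2, case_pc = c(90, 100), control_pc = c(100, 100),
    overall_pc = c(95, 100))), class = "rdcv_result")
  s <- classification_summary(fake)
  expect_equal(s$case_mean, 95)
  expect_equal(s$case_sd, sd(c(90, 100)))
  expect_equal(s$control_sd, 0)
})

test_that("strong synthetic signal yields high per-repetition AUROC", {
  # amplify the case-control separation far beyond the default panel so
  # the qualitative separated regime is unambiguous at 3 repetitions
  ov <- list(CD9 = c(82.3, 10), NDUFS3 = c(96.8, 10), CRP = c(5, 0.5))
  d <- generate_cohort(seed = 4, effect_overrides = ov)
  r <- run_rdcv(d, small_cfg(seed = 1))
  expect_gt(mean(r$merits$auroc), 0.85)
})

test_that("infeasible configurations fail fast", {
  d <- generate_cohort(seed = 5)
  expect_error(run_rdcv(d, rdcv_config(outer_folds = 13)),
               "smaller class")
  expect_error(rdcv_config(outer_folds = 1), ">= 2")
  expect_error(rdcv_config(repetitions = 0), ">= 1")
})

test_that("the full-data scaling variant runs and differs from fold refits", {
  d <- generate_cohort(seed = 6)
  r_refit <- run_rdcv(d, small_cfg(seed = 2))
  cfg <- rdcv_config(repetitions = 3, seed = 2, refit_scaling = FALSE)
  r_full <- run_rdcv(d, cfg)
  expect_false(identical(r_refit$oof, r_full$oof))
  expect_identical(r_full$oof, run_rdcv(d, cfg)$oof)
})

test_that("held-out corruption does not leak into fitted parameters", {
  # module-level no-leakage: scaling and model fitted on training rows
  # are bit-identical whether or not the held-out rows are corrupted
  d <- generate_cohort(seed = 7)
  train <- dataset_subset_rows(d, 1:20)
  m <- fit_scaling(train)
  f_tr <- apply_scaling(m, train)
  fit <- fit_plsda(f_tr, d$labels[1:20], a = 2)

  held <- d$x[21:28, , drop = FALSE]
  corrupted <- held * 1e6
  p_clean <- predict_response(fit, apply_scaling(m, held))
  p_bad <- predict_response(fit, apply_scaling(m, corrupted))
  expect_false(isTRUE(all.equal(p_clean, p_bad)))
  # refitting on the same training rows is unaffected by what is held out
  expect_identical(fit$b, fit_plsda(f_tr, d$labels[1:20], a = 2)$b)
})
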