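# Shared fixtures: all data are generated in code at test time.

# Panel with the case arm forced equal to the control arm everywhere:
# label-independent data for null-calibration checks.
null_panel <- function() {
  panel <- build_default_panel()
  panel$case_median <- panel$control_median
  panel$case_iqr <- panel$control_iqr
  panel$discriminant <- FALSE
  panel
}

null_cohort <- function(seed, n_case = 16, n_control = 12) {
  generate_cohort(n_case, n_control, seed = seed, panel = null_panel())
}

# Small random multiblock dataset with two blocks, for module-level tests.
random_dataset <- function(seed, n = 12, p1 = 4, p2 = 3) {
  set.seed(seed)
  x <- matrix(exp(rnorm(n * (p1 + p2))), n,
              dimnames = list(NULL, paste0("a", seq_len(p1 + p2))))
  multiblock_dataset(
    x, labels = rep_len(c(1, 0), n),
    block = stats::setNames(rep(c("b1", "b2"), c(p1, p2)), colnames(x))
  )
}

dataset_subset_rows <- function(d, idx) {
  multiblock_dataset(d$x[idx, , drop = FALSE], d$labels[idx], d$block,
                     d$sample_ids[idx], d$units)
}

# Brute-force AUROC over all case-control pairs (ties count one half).
auroc_bruteforce <- function(labels, scores) {
  cs <- scores[labels == 1]
  ks <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ks) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ks))
}
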