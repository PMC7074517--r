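#' Simulate a seeded case-control multi-block cohort
#'
#' Draws every analyte independently per sample from the arm-specific
#' log-normal distribution matched to that analyte's median and IQR (see
#' [fit_lognormal()]). The default panel emulates a 28-sample study arm
#' structure (16 cases, 12 controls) over 37 analytes on three platforms;
#' the seven discriminant analytes differ between arms at their published
#' effect sizes while the remaining 30 are exchangeable between arms.
#'
#' Values are strictly positive (log-normal support). Analytes are
#' independent within a sample; assay censoring, batch effects and
#' densitometry noise are deliberately not modeled.
#'
#' @param n_case,n_control Arm sizes (defaults 16 / 12); their sum must be
#'   at least 4.
#' @param seed Integer master seed; the same seed, panel and arm sizes
#'   reproduce the dataset exactly.
#' @param panel Analyte panel data frame as from [build_default_panel()].
#' @param effect_overrides Optional named list `analyte -> c(case_median,
#'   case_iqr)` replacing the case-arm parameters of selected analytes
#'   (e.g. to null out or amplify an effect in recovery experiments).
#' @return A [multiblock_dataset()] with cases first (label 1), then
#'   controls (label 0).
#' @examples
#' d <- generate_cohort(n_case = 16, n_control = 12, seed = 7)
#' dim(d)            # 28 x 37
#' table(d$labels)
#' @export
generate_cohort <- function(n_case = 16, n_control = 12, seed = 1,
                            panel = build_default_panel(),
                            effect_overrides = NULL) {
  validate_panel(panel)
  if (n_case < 0 || n_control < 0 || n_case + n_control < 4) {
    stop_input("need n_case + n_control >= 4")
  }
  if (!is.null(effect_overrides)) {
    bad <- setdiff(names(effect_overrides), panel$name)
    if (length(bad)) {
      stop_input("effect_overrides for unknown analytes: ",
                 paste(bad, collapse = ", "))
    }
    for (nm in names(effect_overrides)) {
      i <- match(nm, panel$name)
      ov <- effect_overrides[[nm]]
      panel$case_median[i] <- ov[[1]]
      panel$case_iqr[i] <- ov[[2]]
    }
    validate_panel(panel)
  }

  n <- n_case + n_control
  labels <- c(rep(1, n_case), rep(0, n_control))
  x <- matrix(NA_real_, n, nrow(panel),
              dimnames = list(NULL, panel$name))
  with_seed(derive_seed(seed, 1L), {
    for (j in seq_len(nrow(panel))) {
      pc <- fit_lognormal(panel$case_median[j], panel$case_iqr[j])
      pk <- fit_lognormal(panel$control_median[j], panel$control_iqr[j])
      if (n_case > 0) {
        x[seq_len(n_case), j] <- stats::rlnorm(n_case, pc[["mu"]],
                                               pc[["sigma"]])
      }
      if (n_control > 0) {
        x[n_case + seq_len(n_control), j] <-
          stats::rlnorm(n_control, pk[["mu"]], pk[["sigma"]])
      }
    }
  })
  ids <- c(sprintf("case_%02d", seq_len(n_case)),
           sprintf("ctrl_%02d", seq_len(n_control)))
  multiblock_dataset(
    x, labels = labels,
    block = stats::setNames(panel$block, panel$name),
    sample_ids = ids,
    units = stats::setNames(panel$units, panel$name)
  )
}
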