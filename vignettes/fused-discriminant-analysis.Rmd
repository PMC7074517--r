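---
title: "Fused multi-platform discriminant analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fused multi-platform discriminant analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Case-control biomarker studies increasingly measure a single serum sample
on several platforms at once — a multiplex bead array for cytokines,
chemokines and growth factors, an automated immunoassay for acute-phase
and neurotrophic proteins, and immunoblot densitometry for markers carried
by circulating small extracellular vesicles. The statistical questions are
(i) whether the joint profile separates cases from controls better than
chance, (ii) which analytes drive the separation, and (iii) how typical a
new sample is of the case category. `plsfuse` implements one coherent
answer: low-level data fusion feeding a PLS-DA classifier validated by
repeated double cross-validation and permutation testing, biomarker
ranking by VIP and rank products, and a one-class SIMCA model of the case
category.

With a few dozen participants and dozens of correlated analytes, naive
reuse of the same samples for model selection and performance estimation
is badly optimistic; the validation design, not the classifier, is the
hard part. Every choice below is therefore stated with its default and
rationale.

# Low-level fusion

Blocks from different platforms live on incommensurate scales (pg/mL,
mg/L, densitometry arbitrary units). Fusion proceeds in three steps,
learned on training samples only:

1. **Autoscaling** — each analyte is centered and scaled to unit variance
   (standard deviation with the $n-1$ denominator, conventional for
   small-$n$ chemometric data).
2. **Block normalization** — each block is divided by the Frobenius norm
   of its autoscaled training submatrix, so every platform contributes
   unit total variance regardless of how many analytes it carries. (For
   an autoscaled training block this norm is exactly
   $\sqrt{(n-1)\,p_b}$, which the cross-validation hot path exploits.)
3. **Concatenation** in a fixed order: blocks in panel order, analytes in
   panel order within each block.

A zero-variance analyte in a training fold raises an error naming the
analyte rather than being silently dropped: silent dropping would
desynchronize variable indices across the VIP and rank-product stages.

The scaling is refit inside every training fold of the cross-validation
by default. Scaling the full dataset once before splitting lets the
held-out samples' locations and spreads leak into the "training"
transform; `rdcv_config(refit_scaling = FALSE)` retains that variant for
strict replication of the common single-pass practice, but it is not the
default.

# PLS-DA

The classifier is a PLS1 regression (NIPALS, X-deflation only) of the
binary dummy response $y \in \{0, 1\}$ (1 = case) on the fused matrix.
Per component, the weight vector is proportional to $X^\top y$ on the
deflated predictors — the direction of maximum covariance with the
response — with scores $t = Xw$, X-loadings $p = X^\top t / t^\top t$ and
response loading $q = y^\top t / t^\top t$. The composite coefficients
are $b = W (P^\top W)^{-1} q$; $y$ is centered during fitting and the
intercept restores its scale. A sample is called a case when its
predicted response strictly exceeds the threshold $\tau$; under 0/1
coding the default is the midpoint $\tau = 0.5$, and ties at the
threshold go to the control class. PLS1 with a single response is the
canonical variant here; SIMPLS would differ negligibly at this scale, but
one variant has to be fixed for reproducibility.

At full rank the fit coincides with least squares, which the test suite
uses as an independent oracle; predictions through the composite
coefficients agree with the sequential latent-variable expansion to
$10^{-10}$, and that identity is also how the inner cross-validation
loop obtains predictions for every candidate component count from one
fit.

# Repeated double cross-validation

Model selection (how many latent variables) and performance estimation
must not use the same held-out data. The double (nested)
cross-validation separates them:

* **outer loop** — 7 stratified folds; each fold in turn is held out
  and predicted by a model that never saw it;
* **inner loop** — 5 stratified folds within each outer training set
  select the latent-variable count $A^\*$ minimizing the summed inner
  number of misclassifications, ties going to the smaller count
  (parsimony under the primary merit);
* **repetitions** — the whole procedure is repeated 30 times over
  re-randomized splits so results do not hinge on one particular split.

Fold counts are defaults, chosen to be feasible for a 16/12 class split
(7 outer folds cannot exceed the smaller class under stratification);
both are configurable. Per repetition, each sample is predicted exactly
once, and the three figures of merit are computed on the pooled
out-of-fold predictions — at two dozen samples, per-fold AUROC would be
meaninglessly unstable. The merits are:

* **NMC** — the number of misclassifications at the threshold;
* **AUROC** — the Mann–Whitney probability that a random case outscores
  a random control, ties counting one half;
* **DQ2** — a discriminant $Q^2 = 1 - \mathrm{PRESSD}/\mathrm{TSS}$ in
  which a prediction beyond its class label (a case predicted above 1, a
  control below 0) is not penalized; DQ2 is therefore never below the
  raw-residual $Q^2$, with equality exactly when nothing overshoots.

Classification summaries report per-class percent correct per repetition,
then mean ± SD across repetitions.

One master seed drives everything; per-repetition and per-permutation
streams are derived from it with a Lehmer-style mixer, so a run is
reproducible from a single integer while streams remain distinct.

# Permutation testing

To exclude chance correlation, class labels are permuted and the entire
pipeline — scaling refits, inner selection, outer prediction — is re-run
per randomization. P-values use the add-one estimator
$p = (1 + \#\{\text{null at least as extreme}\})/(n_{\mathrm{perm}}+1)$
("at least as extreme" meaning null NMC $\le$ observed, null AUROC and
DQ2 $\ge$ observed), which cannot return zero. By default each
randomization runs one rDCV repetition: each null draw is an unbiased
sample from the null merit distribution either way, and only its
Monte-Carlo spread — not the location — depends on the repetition count,
at linear cost. `perm_repetitions` restores the exact observed pipeline
when wanted. Calibration checks in the test suite evaluate the rejection
fraction on the AUROC p-values: with 28 samples the AUROC null
distribution is effectively continuous, whereas NMC takes a few dozen
discrete values, so its add-one p-value is conservative by construction
and a nominal-level check against it would be uninformative.

# Biomarker ranking

Two complementary scores identify candidate analytes.

**VIP** apportions the response variance explained by the model to the
predictors:
$\mathrm{VIP}_j = \sqrt{p \sum_a (w_{ja}/\lVert w_a \rVert)^2\,
\mathrm{SSY}_a / \sum_a \mathrm{SSY}_a}$ with
$\mathrm{SSY}_a = q_a^2\, t_a^\top t_a$. Squared scores average one, so
VIP > 1 flags an above-average contribution. VIP is computed on a final
model fit to all samples at the consensus complexity of the rDCV run —
the across-segment median of the selected counts, rounded half-up to an
integer (segments select small integer counts, so the median is either
an integer or a half; rounding half-up keeps the rule deterministic).

**Rank product**: within every rDCV segment (one outer-fold model of one
repetition; 30 × 7 = 210 segments at the defaults), analytes are ranked
by decreasing absolute regression coefficient — coefficients of
standardized predictors are directly comparable — with average ranks on
ties to avoid index-order artifacts. A variable's RP is the geometric
mean of its ranks across segments, computed as the exponential of the
mean log rank for numerical safety. Consistently discriminant variables
have RP near 1; a variable that shines in a few splits only is pushed
toward the middle.

The reported selection is the VIP > 1 set ordered by ascending RP and
truncated to `k` (default 7); both full score tables are always returned
alongside, because any hard cutoff on these scores is a convention, not
a significance statement.

# SIMCA class modeling

The one-class question — "is this sample compatible with the case
category?" — is answered by PCA on case samples only, after within-class
autoscaling. Two statistics locate a sample relative to the class:
Hotelling's $T^2$ (Mahalanobis distance within the score space, using
per-component score variances) and the $Q$ residual (squared orthogonal
distance from the PC subspace). Each is divided by its calibration 95th
percentile — the linear-interpolation empirical quantile; an estimator
had to be fixed for bit-reproducibility — giving reduced statistics of
comparable magnitude, combined as

$$d = \sqrt{(T^2_{\mathrm{red}})^2 + (Q_{\mathrm{red}})^2},$$

with acceptance when $d < 2$ strictly. In the
$(T^2_{\mathrm{red}}, Q_{\mathrm{red}})$ quarter-plane the acceptance
region is the quarter-disk of radius 2. Out-of-class samples are
transformed with the class model's own scaling — for a one-class method
there is no other legitimate choice. At full rank all $Q$ residuals
vanish; the reduced $Q$ is then defined as 0 for zero residuals (and
infinite otherwise) so the distance degrades gracefully.

The component count is selected by cross-validated efficiency — the
geometric mean of sensitivity (% of class samples accepted) and
specificity (% of out-class samples rejected) — over venetian-blinds
folds of the in-class samples (default 7; deterministic interleaved
folds are the chemometric convention for small ordered calibration
sets). Held-out in-class samples give CV sensitivity; the out-class
samples are scored against each fold's model and the rejection rates
averaged. Ties go to the smaller count. By default the class model sees
the full analyte panel; `simca_variables = "ev_immunoblot"` restricts it
to the vesicle block when the class concept should rest on vesicle cargo
only.

# The synthetic cohort generator

No raw cohort of this kind is publicly deposited, so the package ships a
seeded simulator as a first-class module. Each analyte in each arm is
drawn from a log-normal distribution — strictly positive and
right-skewed, as cytokine and immunoassay concentrations are — matched
in closed form to a median $m$ and interquartile range $i$:
$\mu = \ln m$, $\sigma = \operatorname{asinh}(i/2m)/z_{0.75}$ with
$z_{0.75} = \Phi^{-1}(0.75)$. The default panel has 37 analytes in three
blocks (27 multiplex, 4 automated-immunoassay, 6 EV-immunoblot), default
arm sizes 16 cases / 12 controls. Seven analytes (CD9, NDUFS3, CRP,
FGF21, IL9, MIP-1β, TNF-α) carry published per-arm median/IQR values;
the other thirty are null analytes with identical parameters in both
arms (median 100, IQR 50 — any shared value works, since autoscaling
removes location and scale). Two bookkeeping notes: the multiplex kit is
a 27-plex of which the published listing names 26, so VEGF (the standard
27th member of that panel) completes the block; and the NDUFS3 case-arm
summary was typeset as mean ± SD amid a median(IQR) table and is treated
as median 96.8, IQR 128.0 for consistency with its row.

Analytes are drawn independently within a sample: no covariance
information is published, and inventing a correlation structure would
make recovery results impossible to interpret. Consequences worth
stating plainly: passing recovery tests show the pipeline finds planted
marginal effects among independent nulls; they do not show robustness to
correlated panels, assay censoring at detection limits, batch effects,
or densitometry noise, none of which are modeled. Demographics are not
generated — they are not inputs to this pipeline.

# Numerical choices and degenerate inputs

* NIPALS stops early if the weight or score norm falls below $10^{-12}$
  (response residual orthogonal to the predictors); the model then
  carries the extractable components and inner CV treats the missing
  tail as repeating the last extractable fit.
* Zero-variance analytes are errors everywhere (fusion, SIMCA), named
  explicitly.
* `fit_lognormal` accepts IQR 0 (a point mass) but such an analyte will
  then error in fusion — deliberately.
* Ranks use midranks on ties, both in AUROC (so ties count one half
  pair) and in RP.
* The inner-loop tie-break (smallest count), the RP log-space geometric
  mean, the half-up rounding of the median complexity, and the type-7
  quantile in SIMCA are all fixed conventions chosen once for
  determinism.

# Test and check problem sizes

The suite validates estimators against independent oracles (least
squares at full rank, brute-force pair counting for AUROC, term-by-term
formula evaluation for VIP, literal product-and-root for RP) on small
random problems; calibration properties run at the study's own scale:
5 null cohorts through the full 30-repetition rDCV, 200 null cohorts
through a 99-randomization permutation test (rejection fraction at
$\alpha = 0.05$ checked against its Monte-Carlo band), 20 seeded
cohorts for planted-signal recovery, and $10^5$ draws per arm for
generator quantile calibration. These sizes keep the complete check
suite in the tens of minutes on a single CPU while leaving the
Monte-Carlo bands meaningful. Calibration bands are asserted on means
over seeds, not per draw: a single 28-sample null cohort with 37
analytes routinely contains a chance analyte–label correlation
approaching 0.5 — which honest out-of-fold validation will pick up, and
which only permutation or averaging over cohorts can expose as chance —
and with 16 in-class samples one held-out sample moves SIMCA CV
sensitivity by 6.25 points.

# Known limitations

* **Raw-scale classification under heavy tails.** The fused classifier
  operates on autoscaled raw concentrations (no log transform), matching
  the common practice for this kind of panel. With a median/IQR-matched
  log-normal whose control arm is an order of magnitude broader than the
  case arm — CD9's control parameters imply a log-scale SD of about 1.5
  — low-end control draws fall into the case range, and out-of-fold
  accuracy of any linear raw-scale classifier saturates near 80% at
  these arm sizes (we verified the same ceiling with an independent PLS
  implementation on identically fused folds). Biomarker *ranking* is
  much less affected: the planted analytes separate from the nulls by
  rank product in essentially every seed. A log transform ahead of
  autoscaling would lift the ceiling, but it is deliberately not the
  default because the modeled workflow does not include it.
* The midpoint threshold $\tau = 0.5$ with unbalanced arms (16/12)
  biases calls toward the larger class; per-class accuracies are
  asymmetric by design. $\tau$ is a configuration knob.
* Permutation p-values at the default single repetition per
  randomization have higher Monte-Carlo spread than the observed merit;
  raise `perm_repetitions` for publication-grade nulls.
* SIMCA specificity in component selection averages out-of-class
  rejection over fold models; other averaging conventions exist and
  would differ slightly at these sample counts.
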