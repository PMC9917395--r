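---
title: "Censored-normal trajectory modeling of longitudinal D-dimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censored-normal trajectory modeling of longitudinal D-dimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and its assumptions

`ddtraj` fits a finite mixture of polynomial mean trajectories to
daily-maximum D-dimer series from trauma patients. Each patient $i$ carries
observations $y_{it}$ (mg/L) on an irregular subset of days
$t \in \{0, \dots, 50\}$, with day 0 the day of trauma. Conditional on
latent group $g$, observations are independent draws from a normal
distribution around $\mu_g(t)$, a polynomial of order 2–4 in rescaled time
$s = t/10$, censored to the assay range $[0, 40]$ mg/L: interior values
contribute normal density, values at a bound contribute the corresponding
tail mass (Tobit treatment). The key assumptions are:

* **No within-group heterogeneity.** All patients in a group share one mean
  curve; deviations are iid noise. This is the defining GBTM assumption, in
  contrast to growth-mixture models with random effects.
* **Shared residual SD** $\sigma$ across groups and occasions. This is the
  standard GBTM convention; a per-group $\sigma$ is a plausible alternative
  but is not implemented, and simulation under the shared-σ truth shows the
  shared fit recovers it well.
* **Missingness ignorable given group.** Follow-up length may depend on the
  latent group (tests stop when patients stabilise), which the mixture
  tolerates because each patient's likelihood is evaluated only on observed
  days; missingness that depends on the *residuals* would bias the fit.

## Estimation

The observed-data log-likelihood
$\sum_i \log \sum_g \pi_g \prod_t f(y_{it} \mid \beta_g, \sigma)$
is maximised by EM. Both latent layers — the group label and, for censored
observations, the latent uncensored value — are handled in the E-step:
posterior memberships $p_{ig}$ come from per-patient conditional
log-likelihoods combined by log-sum-exp, and censored observations enter
through their conditional first and second moments under the current
parameters (inverse-Mills-ratio formulas evaluated in log space). The
M-step is then exact and closed-form: $\pi_g$ is the mean posterior,
$\beta_g$ a weighted least-squares fit to the imputed latent values, and
$\sigma^2$ the weighted mean of squared residuals plus conditional
variances. Because both steps are exact, the observed log-likelihood is
non-decreasing across iterations; the test suite asserts this on every
fitted trace at an absolute tolerance of $10^{-8}$.

Numerical choices:

* **Time rescaling** $s = t/10$ keeps the quartic design well conditioned
  over a 50-day horizon; `coef_natural_scale()` converts back to mg/L per
  day$^k$.
* **Initialization.** Start 1 clusters per-patient summary features (mean,
  maximum, early slope over days 0–7) by k-means (25 restarts); further
  starts perturb that labelling (30% reshuffled) or draw labels uniformly.
  Each start runs a short burn-in (15 iterations); the two most promising
  starts are run to convergence and the better kept — burn-in rankings
  occasionally misorder basins of attraction, and the second candidate is
  cheap insurance.
* **Convergence** when the relative log-likelihood change falls below
  `tol = 1e-6`; hitting `max_iter = 500` returns the best iterate with
  `converged = FALSE` and a warning.
* **Degenerate components** with $\pi_g < 1/n$ are pruned with a warning
  and the reduced model re-converged.
* **Guards.** Censored log-masses are evaluated with `pnorm(log.p = TRUE)`
  and floored at $-10^{10}$; $\sigma$ is floored at $10^{-4}$ mg/L; modal
  assignment ties break toward the lowest group index.
* **Relabelling.** After convergence, groups are re-ordered by ascending
  mean fitted level over days 0–10, so "group 1 = stable low" is stable
  across seeds and order vectors attach to groups deterministically.

## Model selection

Stage 1 fits all-quadratic models with 1–6 groups and selects by BIC in the
subject-count convention, $\mathrm{BIC} = \ell - (k/2)\ln n$ (larger is
better), with a parsimony margin: the smallest $G$ within 2 BIC units of
the maximum wins. The margin operationalises "parsimony and plausibility";
it is configurable, and the selection table is always returned for human
review.

Stage 2 enumerates polynomial orders $\{2,3,4\}^G$. Two order vectors that
are permutations of each other describe the same model up to relabelling —
and fitted groups are always relabelled by level — so one representative
per order *multiset* is fitted and its diagnostics are shared across the
permuted rows of the report (15 fits instead of 81 at $G = 4$). Among
combinations passing all three adequacy criteria (entropy $\ge 0.9$, every
assigned group $\ge 5\%$, every APPA $\ge 0.7$) the best-BIC one is
selected; if none passes, the best-BIC combination overall is returned with
an explicit warning. A greedy mode (upgrade one group's order at a time
while BIC improves) is available for very large $G$ but off by default.
Whether the original analyses enumerated exhaustively or greedily is not
documented; both modes agree on well-separated data in our tests.

## The synthetic cohort generator

The generator is first-class, tested code: it produces the latent-class
longitudinal structure the analysis assumes, and its defaults define the
conditions under which the package's recovery claims are made.

* **Four phenotypes** with mixing proportions (0.576, 0.282, 0.084, 0.058)
  taken from the published group sizes: "stable low" (flat 1.4 mg/L),
  "moderate-decline" (quadratic from 12 mg/L), "high-rapid decline"
  (quartic: ~22 mg/L on day 0, minimum near day 10, slight rise, gentle
  late decline) and "high-gradual decline" (quartic: early peak ~18 mg/L,
  gradual decline to a low plateau by day 30). The quartic curves are
  built by least squares against hand-drawn target profiles over the whole
  0–50-day horizon rather than by interpolation, which keeps them bounded
  — unconstrained interpolating quartics oscillate wildly outside their
  anchor range, and those excursions (clipped to the assay bounds) would
  manufacture artefactual sub-populations among rare long-stay patients.
* **Sampling.** Daily tests are observed with probability 0.85; day 0 is
  always tested and at least three distinct days are guaranteed, matching
  the cohort inclusion rule. Follow-up length is $3 + \mathrm{NegBin}$
  with group-specific means (11, 16, 12, 26 days in total): informative
  stopping in which quickly-resolving classes — including "high-rapid
  decline" — stop being tested early. A negative binomial with size 8 is
  used rather than a geometric draw: hospital stays cluster around a
  typical duration, whereas the geometric's mode-at-zero dispersion
  produces extreme span heterogeneity *within* groups, which an
  all-quadratic mixture can exploit by splitting groups into
  follow-up strata.
* **Mortality** is Bernoulli with group-specific logits matching the
  published group mortality rates (4.5%, 9.2%, 7.7%, 27.8%). Covariates
  (age, sex, BMI, SOFA, six-region AIS with ISS derived by the
  three-highest-regions rule, RTS, mechanism, treatment and complication
  flags) are drawn from simple parametric models with a latent severity
  gradient across groups; 8.74% of patients have their AIS profile masked
  to exercise KNN imputation, matching the published missingness rate.
* **What it does not emulate.** Within-group curve heterogeneity, serial
  correlation of residuals, treatment feedback on D-dimer, transfer
  patients with missing early days, assay batch effects, and any realistic
  joint distribution of covariates. Passing recovery tests therefore shows
  the estimator is correct under its own assumptions, not that real
  D-dimer data satisfy them. No attempt is made to reproduce the published
  cohort's fitted entropy, APPA, adjusted odds ratios or AUCs, which would
  require the undeposited data; the published values guided realism only.

## Preprocessing and scores

Raw measurements are split into 1-day blocks keeping the daily maximum
(emphasising the worst pathological state of the day), clipped to
$[0, 40]$ mg/L with censoring flags, and truncated at day 50. "Fewer than
three days" is interpreted as fewer than three *distinct calendar-day
blocks* (not three raw tests), since blocking precedes inclusion in the
modelling cohort. Exclusions apply sequentially — fewer than three D-dimer
days, re-admission, trauma-to-admission interval over 14 days, age ≤ 18,
cancer, pregnancy — so the audit counts and the included count always sum
to the screened total. Missing AIS profiles are imputed from the $k = 5$
nearest complete rows (standardised Euclidean distance over age, BMI,
SOFA, ISS when present, and one-hot mechanism; region-wise neighbour
median rounded into 0–6), and ISS is recomputed from the completed AIS.
TRISS survival probability uses the standard mechanism-specific logistic
equations with the age index switching at 55 years; the coded-RTS helper
(weights 0.9368/0.7326/0.2908) exists for simulation convenience only.

## Association analysis defaults

Univariate screening at $\alpha = 0.1$ uses single-predictor logistic
regression for continuous covariates and chi-square (Fisher when any
expected cell < 5) for categorical ones. Collinearity screening flags
VIF $\ge 10$ or Spearman $|r| > 0.5$ with $p < 0.05$ and drops, from each
flagged pair, the variable with the larger univariate $p$ — the published
analyses state only that variables with "minimum potential collinearity"
were kept, so the drop rule is this package's choice and every drop is
logged. Odds-ratio intervals are Wald (they reconstruct the published
group-4 CI from the count table); quasi-separation is flagged and the CIs
marked unreliable. AUCs are in-sample for both the trajectory-group model
and TRISS, mirroring the original comparison; no optimism correction is
applied.

## Problem sizes used by the test suite

Recovery experiments run at the generator's default size ($n = 400$,
50-day horizon): single-fit parameter recovery and a 20-replicate
two-stage-selection experiment. The shape-recovery property (orders
(2,2,4,4) under strong separation) runs at $n = 250$ over 10 replicates,
and the null-calibration checks of the univariate screen use 80 replicates
of $n = 500$; these sizes were chosen so the full suite stays fast while
keeping Monte-Carlo error well inside the asserted margins.

One adequacy criterion is intrinsically marginal under the default
conditions: with a true group-4 share of 5.8%, the probability that a
multinomial draw of 400 patients gives that group at least the required 5%
of assignments is about 0.78 even for a perfect estimator. Replicates
failing the group-size criterion while recovering parameters and labels
essentially exactly reflect that sampling fact, not estimation error.

## Known limitations

* No covariates on group membership (no multinomial membership model), no
  Poisson or Bernoulli trajectory families, and no random-effect
  growth-mixture alternative.
* Wald inference throughout; profile-likelihood CIs are not implemented.
* The BIC sign convention maximises $\ell - (k/2)\ln n$; analyses that
  compare absolute BIC values from other software should mind the sign.
* The simulator's covariate model is deliberately simple; association
  results on synthetic cohorts exercise the machinery, not clinical
  effect sizes.
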