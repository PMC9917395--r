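# ddtraj

Group-based trajectory modeling of longitudinal D-dimer in trauma cohorts.

After major trauma, plasma D-dimer reflects ongoing activation of coagulation
and fibrinolysis. A single admission value is a noisy prognostic marker; the
*shape* of the daily D-dimer profile over hospitalisation carries more
information — patients whose initially high D-dimer resolves slowly fare
worse than those in whom it falls quickly. `ddtraj` provides the full
analysis chain for studying this: it clusters patients' daily-maximum
D-dimer series into latent trajectory groups, checks the adequacy of the
grouping, and relates group membership to in-hospital mortality. It is aimed
at biostatisticians and clinical researchers working with irregular
longitudinal biomarker panels from electronic medical records.

## The model

Let \(y_{it}\) be patient \(i\)'s daily-maximum D-dimer (mg/L) on day \(t\)
post-trauma (day 0 = trauma day, horizon 50 days). The assay reports values
in a censored range \([0, 40]\) mg/L. A group-based trajectory model (GBTM)
assumes each patient belongs to one of \(G\) latent groups; within group
\(g\) the observations are conditionally independent censored-normal (Tobit)
draws around a polynomial mean curve in rescaled time \(s = t/10\):

\[
\mu_g(t) = \beta_{g0} + \beta_{g1} s + \dots + \beta_{gk_g} s^{k_g},
\qquad
y^*_{it} \sim N(\mu_g(t), \sigma^2),
\qquad
y_{it} = \min(\max(y^*_{it}, 0), 40).
\]

Values at a bound contribute tail probability mass instead of density. The
observed-data likelihood is the mixture
\(\sum_g \pi_g \prod_t f(y_{it}\mid\beta_g,\sigma)\), maximised by an EM
algorithm with multiple starts. Model choice follows Nagin's two-stage
protocol: first the number of groups (all-quadratic fits, \(G = 1\ldots 6\),
BIC with a parsimony margin), then per-group polynomial orders in
\(\{2,3,4\}\) subject to relative entropy \(\ge 0.9\), every group holding
\(\ge 5\%\) of patients, and average posterior probability of assignment
(APPA) \(\ge 0.7\). Patients are assigned to their highest-posterior group,
groups are compared (Kruskal–Wallis / chi-square / Fisher, Benjamini–
Hochberg pairwise), and mortality is modelled by multivariable logistic
regression after univariate screening at \(p < 0.1\) and collinearity
screening (VIF \(\ge 10\) or \(|r| > 0.5\)); discrimination is compared with
TRISS survival probabilities by ROC AUC.

Because real trauma-registry data cannot be redistributed, the package ships
a synthetic cohort generator with the same latent-class structure (four
trajectory phenotypes, censoring, irregular sampling with informative
stopping, class-linked mortality) plus small fixtures encoding published
screening and outcome counts.

## Worked example

```r
library(ddtraj)

bundle <- generate_cohort(sim_config(n_patients = 200, seed = 8))
fit <- fit_gbtm(bundle$measurements, trajectory_spec(4, c(2, 2, 4, 4)),
                n_starts = 5, seed = 1)
print(fit)
#> Censored-normal GBTM: 4 group(s), orders (2,2,4,4), n = 200 patients, 2334 observations
#>   loglik -4672.142 | BIC -4725.125 | entropy 1.000 | sigma 1.808 mg/L
#>  group    pi assigned appa
#>      1 0.545    0.545    1
#>      2 0.290    0.290    1
#>      3 0.105    0.105    1
#>      4 0.060    0.060    1
```

The four recovered groups are, in ascending order of early D-dimer level,
the "stable low", "moderate-decline", "high-rapid decline" and
"high-gradual decline" phenotypes; `pi` are the fitted mixing proportions
(here matching the simulated label counts 109/58/21/12), `sigma` the shared
residual SD in mg/L, and `appa` the average posterior probability among each
group's assigned members (1.00 = perfectly crisp). `predict_mean_curves(fit)`
returns the fitted curves with per-day observed means and 95% bands for
plotting.

Contingency arithmetic from published group-by-outcome death counts:

```r
fx <- make_mortality_fixture()
ct <- odds_ratio_2x2(fx$deaths[4], fx$survivors[4],
                     fx$deaths[1], fx$survivors[1])
#> group 4 vs group 1: OR 8.17 (95% CI 2.34-28.57), p = 0.0010
```

That is: patients in the "high-gradual decline" group had roughly
eight-fold higher odds of in-hospital death than the "stable low" group
before adjustment.

The end-to-end pipeline (simulate → preprocess → score → select → fit →
associate) is driven by `run_pipeline(pipeline_config(out_dir, seed))`,
which writes every artifact (blocked series, completed covariates, TRISS
scores, selection report, fit parameters, posterior matrix, association
tables) plus a JSON manifest with per-stage seeds.

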