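---
title: "Methods: parametric survival extrapolation and semi-Markov remission modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parametric survival extrapolation and semi-Markov remission modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

remex predicts long-term remission in complex Crohn's perianal fistula
(CPF) by pooling a trial-like cohort with a real-world chart-review
cohort, deriving remission and relapse time-to-event outcomes from
visit-level assessments, fitting parametric survival models whose
location *and* shape parameters depend on covariates, and feeding the
fitted transition models into a semi-Markov relapsing–remitting cohort
engine. This vignette records the models, the defaults, and the design
decisions, in that order.

## Outcomes and the observation model

Four outcomes are derived from visit records (`derive_remission()`,
`derive_relapse()`):

* **Clinical remission** — first visit at which all external openings
  (EOs) draining at baseline are closed.
* **CPC remission** — clinical remission *plus* a score of 0 on both the
  pain and the discharge element of the Perianal Disease Activity Index
  (PDAI) at the same visit.
* **Clinical / CPC relapse from CPC remission** — first visit after the
  first CPC remission showing loss of closure (clinical), or loss of
  closure or any positive PDAI pain/discharge score (CPC). The relapse
  clock is reset to the CPC-remission visit.

Time at risk for remission starts at the treatment-initiation week
(week 0); the week-0 visit is the baseline assessment and never
qualifies. Events are timed at the visit at which the state is first
*observed* (right-aligned interval observation) — no midpoint correction,
because the analysed data are assessment-based; the synthetic generator
has an `observation = "exact"` switch so oracle tests can bypass the
interval mechanism. Censoring (loss to follow-up, proctectomy, death)
ends observation; an event at the same week as a censoring event wins
(standard convention). Patients are removed after their first event.
A patient whose CPC remission falls on the last observed week still
contributes a vanishingly short censored relapse sample, so relapse
samples and CPC-remission events stay in one-to-one correspondence.

## The parametric model

For a right-censored sample \((t_i, d_i)\) the log-likelihood is the sum
of \(d_i \log h(t_i) + \log S(t_i)\) over observations. Five families are
supported (`psfit()`), in flexsurv-style parameterizations so every
formula is unambiguous: Weibull, Gompertz, generalized gamma
\((\mu, \sigma, Q)\), log-logistic, log-normal (plus an exponential
convenience family). The location is a linear predictor
\(\mu_i = x_i'\beta\); the first ancillary (shape) parameter is a linear
predictor through its link — log link for positive shapes, identity for
the Gompertz shape, which may legitimately be negative (a *defective*
distribution whose survivor function plateaus: a fraction of patients
never experiences the event). The generalized gamma's \(Q\) stays scalar.

A **lead-in** window (default 4 weeks) encodes the structural absence of
recorded remission events immediately after treatment: fitted times are
shifted by the lead-in before entering the likelihood, fitted curves are
flat at 1 over it, and events inside the window are counted and flagged
as violations of the premise.

Estimation is multi-start BFGS (Nelder–Mead fallback) on unconstrained
parameters with internally standardized covariates (the back-transform to
the original scale is exact, including the covariance). The generalized
gamma additionally starts from its nested Weibull (\(Q = 1\)) and
log-normal (\(Q = 0\)) solutions to tame its likelihood ridge.
Non-convergence across all starts yields a flagged result, not an error.
Study-specific effects are deliberately absent from the default covariate
sets: the pooling assumption is that long-term behaviour, all else equal,
is shared across sources, and study indicators would wall off the two
data sets from each other. Model choice uses AIC/BIC
(`compare_models()`) together with the KM-overlay plot (`plot.psfit()`).
MCMC fitting is not provided; maximum likelihood keeps AIC/BIC
well-defined and every acceptance-grade property of the pipeline testable
without a sampler.

## The semi-Markov engine

Patients enter in the chronic-symptomatic-fistula (CSF) state and
alternate CSF and CPC-remission spells; each sojourn is drawn from the
fitted time-to-remission or time-to-relapse model with the clock reset at
state entry (semi-Markov). Because only first events are identifiable
from the data, re-entry sojourns **reuse the first-event distributions** —
the only self-consistent reading of running a relapsing–remitting model
on first-event fits — and this is deliberately conspicuous in the
documentation. The lead-in applies to the first CSF sojourn only
(it reflects one-off post-treatment assessment absence); a
`lead_in_each` switch exists. Death and proctectomy are not model
states; censoring informs fitting only.

Two engines must agree (and are tested against each other):
`simulate_cohort()` microsimulates patients with covariates drawn from a
covariate table (population-averaged curves are weighted means over
profiles), and `solve_renewal()` solves the alternating-renewal occupancy
equations by discrete convolution on a sub-weekly grid — a deterministic
oracle with \(O(h)\) discretization bias (default `grid_step` 0.25 weeks;
0.1 where it is compared against the microsimulation). The exponential
special case has the closed form
\(P_\text{rem}(t) = \tfrac{\lambda}{\lambda+\mu}(1 - e^{-(\lambda+\mu)t})\),
the module's primary oracle. Occupancy is reported on a monthly grid at
52/12 weeks per month; weeks are the internal unit throughout.
`bias_adjust()` reweights a covariate table to reference moments by
entropy balancing (exponential-tilting dual, solved by BFGS); infeasible
targets (outside the support) are refused, naming the constraints.

## Synthetic cohorts: what they emulate, and what not

`cohort_config()` defaults define the study conditions: 212 trial
patients (12 flagged as lacking any completed post-index assessment; 101
of the 200 assessable on active treatment) and 386 real-world patients
(73 flagged), so the pooled sets reproduce the published patient flow
(200 + 313 = 513; arms 101/412) exactly. Baseline covariates follow the
published marginal summaries (means/SDs for numeric covariates, category
probabilities otherwise, per study); ages and scores are floored at their
natural bounds, so sample moments follow censored-normal formulas, which
is what the tests assert. Item-level baseline missingness mirrors the
published per-item `N`s (notably ~80% missing smoking status in the
trial), and visit-level PDAI scores are missing in 73.5% of real-world
visits versus 0.5% of trial visits. Missingness is MCAR by default with a
MAR option (logit-linear in age); the source analyses never state the
mechanism.

Latent event histories are drawn from configurable true models with
covariate effects through location and shape. The default true models
are Gompertz remission with negative, arm-dependent shape and Weibull
relapse, calibrated so the packaged demo reproduces the published
long-term pattern — roughly half of active-arm and a third of
comparator patients in CPC remission at 24 months, sustained to 48.
Within each clinical/CPC pair the two latent times share one severity
uniform (comonotone coupling): each marginal is exactly its configured
model, orderings (CPC remission never precedes clinical remission; CPC
relapse never follows clinical relapse) hold by construction, and the
closed-but-symptomatic gap stays realistic. Trial visits sit on a fixed
4-weekly grid; real-world visit gaps are log-normal with a median of 8
weeks (an assumption, not a reported fact — the source never states the
chart-review visit-frequency distribution). An assessable patient
censored before the first scheduled visit still receives a closing
assessment at the censoring week, as a registry would record.

What the generator does **not** emulate: the joint covariate
distribution (only the schema and the marginals), informative
missingness tied to unobserved state, assessment-date recording error,
and treatment switching. Green tests therefore demonstrate correctness
of the machinery under the stated data-generating assumptions, not
fidelity of any conclusion about the real cohorts, whose patient-level
data are not public.

## Imputation

Missing baseline covariates and PDAI score categories are multiply
imputed (default \(m = 20\) completions; the pipeline demo uses 5)
before outcome derivation — impute-then-fit; the source does not say
whether imputation was nested inside fitting. Categorical baseline
variables use a Dirichlet–multinomial with partial pooling across
studies (prior strength 10 pseudo-counts spread as the pooled
proportions); the fitted table carries an explicit dummy
missing-pattern category, and draws are taken from the conditional over
the real categories. Numeric variables use a normal regression on
shared predictors with a study intercept — a *fixed* study factor,
because a random-intercept variance over two studies is unidentifiable —
with draws from the asymptotic coefficient distribution and a scaled
inverse-\(\chi^2\) residual variance, truncated at zero for non-negative
scores.

Visit-level PDAI pain and discharge are imputed as a **joint pair**
within study-by-closure-state strata. This matters: the two elements are
strongly dependent, and the closure assessment (always observed) carries
the disease state. Imputing the elements independently and
closure-blind fakes relapses — a patient in true CPC remission whose
scores are missing would be handed positive scores with high
probability, truncating remission spells at roughly one visit gap and
collapsing comparator-arm occupancy. Even the stratified pair model
cannot fully undo the 73.5% missingness: imputed visits are independent
across time given the stratum, so some spurious state churn remains in
the heavily missing arm. This is the same bias the source flags for its
own CPC analyses, and it is the main reason the demo's absolute
percentages should be read qualitatively.

## Numerical choices

* Shifted times are floored at \(10^{-3}\) weeks; hazards are evaluated
  in logs; the Gompertz cumulative hazard uses `expm1` with the
  \(a \to 0\) exponential limit; generalized-gamma tails use
  log-scale incomplete-gamma calls, switching to the log-normal branch
  for \(|Q| < 10^{-7}\).
* Optimizer: BFGS, relative tolerance \(10^{-12}\), up to 500
  iterations, deterministic start list (no RNG in fitting); covariance
  from the numerical Hessian at the optimum.
* Renewal solver: FFT convolutions of per-bin sojourn masses; entry-mass
  iteration stops when the added mass is below \(10^{-12}\).
* Ties: events precede censorings (KM and tests); monthly grids convert
  at 52/12 weeks per month; all stochastic functions take a seed and
  restore the caller's RNG state.

## Problem sizes

The test suite runs the study-scale worked examples (212/386-patient
registries), engine cross-validation at 50,000 simulated patients,
likelihood-vs-quadrature checks at 100 draws per family, recovery at
n = 2000 with 50 replicates, AIC selection at n = 1000 with 200
replicates, and test-size calibration at 2000 null replicates; the
acceptance script uses the same designs with 25 recovery and 100
selection replicates. These sizes make every Monte-Carlo tolerance a
3-standard-error band or better while keeping a full run in minutes.

## Known limitations

* Re-entry sojourns reuse first-event distributions (see above) — an
  assumption, untestable from first-event data.
* The relapse analysis conditions on *observed* CPC remission; with
  sparse real-world visits the remission baseline is detected late, and
  short remission spells can be missed entirely.
* The bias-adjustment method is a moment-reweighting choice; the source
  names no method.
* Absolute demo percentages inherit imputation churn under 73.5%
  missingness; orderings and gaps are the robust quantities.
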