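---
title: "Methods: Bayesian population PK of long-term dexmedetomidine infusion in children"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian population PK of long-term dexmedetomidine infusion in children}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dexpk` models plasma concentrations of dexmedetomidine measured in
critically ill children receiving a long, nurse-titrated intravenous
infusion in intensive care. Such data are observational: few subjects, wide
age and weight ranges, sparse sampling dictated by care, and occasional
grossly outlying concentrations. The package therefore combines a standard
two-compartment infusion model with informative literature priors, a robust
Student-t residual model, and full MCMC inference, and it ships a synthetic
cohort generator that emulates the study design so that every stage of the
pipeline can be exercised and tested without patient data.

## Structural model

Drug amounts in a central (volume $V_1$) and a peripheral (volume $V_2$)
compartment evolve as

$$V_1\frac{dC_1}{dt} = R_0(t) - CL\,C_1 - Q\,C_1 + Q\,C_2,\qquad
  V_2\frac{dC_2}{dt} = Q\,C_1 - Q\,C_2,$$

with $C_1(0)=C_2(0)=0$; $CL$ is metabolic clearance, $Q$ inter-compartmental
clearance, and $R_0(t)$ the total infusion rate plus boluses. Units are
fixed as µg, L and h, so central concentrations come out in µg/L, which is
numerically ng/mL — the unit in which the assay reports. Because the system
is linear with piecewise-constant input, `concentration_profile()` solves it
exactly: the state is propagated through each dosing segment with the
analytic $2\times2$ matrix exponential (Putzer form), which is equivalent to
superposing biexponential responses of all dose events. A numerical ODE
solution exists in the test suite purely as an independent oracle; the
analytic kernel is what the sampler calls, for exactness and speed.

Degenerate cases are handled explicitly: an empty dose list gives an
identically zero profile; observations before the first dose have zero
predicted concentration and are excluded from the likelihood (with a
warning) by `dex_fit()`, mirroring the protocol's pre-dose baseline sample;
an observation falling exactly on an event boundary is evaluated just after
the event (right-continuous dosing); coincident eigenvalues of the rate
matrix fall back to the $t e^{\lambda t}$ limit.

## Covariate model

Individual parameters are lognormal around allometrically scaled typical
values:

$$\ln P_i = \ln\theta_P + \ln f_P\,[\text{occasion 2}]
  + K \ln(BW_i/70) + \eta_{P,i},$$

with fixed theory-based exponents $K = 0.75$ for the clearances and $K = 1$
for the volumes, relative to a 70 kg adult. Clearance additionally carries a
maturation factor, a Hill function of postmenstrual age,
$PMA^{Hill}/(PMA^{Hill}+TE_{50}^{Hill})$: the fraction of adult clearance
reached at a given $PMA$, with half-maturation at $TE_{50}$ weeks. When only
postnatal age is available, $PMA$ assumes term gestation
(40 weeks + postnatal age); this is configurable per subject but cannot be
verified without gestational ages.

The two study occasions are the infusion itself (occasion 1) and the hours
after cessation (occasion 2). Every parameter may shift by a multiplicative
fraction $f_P$ on occasion 2 ($f_P = 1$ on occasion 1). The switch point is
taken as the infusion cessation time, with compartment amounts carried over
continuously — physical continuity forces this choice even though the
original protocol does not state it. Random effects
$\eta_i \sim \mathrm{MVN}(0,\Omega)$ are carried by $CL$, $Q$, $V_1$, $V_2$
only; $TE_{50}$, Hill, the fractions and the residual parameters have no
between-subject variability.

## Residual model

Log-concentrations are observed with additive Student-t noise:
$\ln C_{obs} = \ln C_{pred} + \varepsilon$,
$\varepsilon \sim t(0, \sigma_C, \nu)$. The normality parameter $\nu$ is
estimated (constrained above 1); small values fatten the tails and make the
fit robust to the occasional concentrations that are several-fold off, which
is exactly what sparse ICU data contain. As $\nu \to \infty$ the likelihood
reduces to the usual lognormal error model (verified numerically in the
tests).

## Informative priors and their construction

The priors are rebuilt, not transcribed. From a published pooled analysis of
four paediatric intravenous-dexmedetomidine studies (95 children) the
package takes point estimates with bootstrap 95% CIs for the six fixed
effects and %CVs for the four between-subject variabilities
(`literature_prior_summary()`, shipped as a plain-text YAML fixture), and
derives:

* $\ln\theta \sim \mathrm{MVN}(\ln\bar\mu, \Sigma)$ with
  $\bar\mu$ the point estimates and diagonal
  $\Sigma_{PP} = ((\ln hi - \ln lo)/(2\cdot1.96))^2$
  (`log_variance_from_ci()`);
* $\Omega^{-1} \sim \mathrm{Wishart}(\rho\,\Omega_0, \rho)$ (BUGS
  parameterisation, so $E[\Omega^{-1}] = \Omega_0^{-1}$) with diagonal
  $\Omega_{0,PP} = \ln((\%CV/100)^2+1)$ (`iiv_variance_from_cv()`);
* $\sigma_C \sim \mathrm{Uniform}(0.001, 1000)$,
  $\nu \sim 1 + \mathrm{Exponential}(0.1)$,
  $\ln f_P \sim N(0, \sigma_{f_P}^2)$.

The Wishart degrees of freedom control how much the between-subject
covariance may move away from $\Omega_0$. `calibrate_rho()` reproduces the
published calibration by simulation: each diagonal element of a Wishart
precision draw has coefficient of variation $\sqrt{2/\rho}$ regardless of
the scale matrix, so "about 25% variability" corresponds to $\rho = 30$
($\sqrt{2/30} = 25.8\%$). Read strictly as "the smallest integer $\rho$ with
CV $\le 25\%$" the search returns 32; the package keeps the published
$\rho = 30$ as the default and exposes the calibration. Alternative readings
of the 25% target (CV of the $\Omega$ diagonal, or of $\omega$) do not
reproduce $\rho = 30$ and were rejected.

Only the diagonal of $\Omega_0$ is specified (as published); the posterior
$\Omega$ is nevertheless a full covariance matrix, because the Wishart has
support on all positive-definite matrices — off-diagonal posterior mass such
as a $Q$–$V_1$ correlation arises from the data alone.

The fraction-prior scale $\sigma_{f_P}$ is the one genuinely open tuning
constant: 0.01 amounts to asserting no occasion difference, 0.6 is vague.
The default 0.2 is the most parsimonious scale beyond which predictive
accuracy stops improving; `fraction_sensitivity()` refits over a grid
(default 0.01–0.6) and tabulates DIC, MDPE/MDAPE and the fraction posteriors
so that choice can be re-examined on any dataset.

## Posterior sampling

`dex_fit()` runs an adaptive Metropolis-within-Gibbs sampler written for
this posterior (any correct MCMC would do; no external engine is used):

* a joint block update of $(\ln\theta, \ln f)$ with a Haario-style
  empirical-covariance proposal, repeated four times per sweep — the fixed
  effects are strongly correlated ($CL$ with $TE_{50}$/Hill through
  maturation, $\theta$ with $f$), so an aligned proposal is needed to move
  along the posterior ridges; a small isotropic component guards against a
  mis-learned covariance;
* per-subject random-walk updates of $\eta_i$, preconditioned by the current
  Cholesky factor of $\Omega$, with occasional five-fold kicks, plus an
  independence move that redraws a random one- or two-coordinate subset of
  $\eta_i$ from its conditional prior (accepted on the likelihood ratio
  alone) — together these let chains hop between well-separated conditional
  modes, e.g. the outlier-vs-shifted-$\eta$ explanations that heavy-tailed
  residuals admit for an extreme subject;
* likelihood-invariant interweaving moves that shift $\ln\theta_P$ and all
  $\eta_{P,i}$ in opposite directions, accepted on the prior ratio alone —
  these decouple each typical value from the mean of its random effects (the
  funnel direction that otherwise mixes very slowly);
* a conjugate Gibbs draw of $\Omega^{-1}$ from
  $\mathrm{Wishart}(\rho+N, (\rho\Omega_0 + \sum_i\eta_i\eta_i^\top)^{-1})$;
* log-scale random walks for $\sigma_C$ (with its uniform bounds) and
  $\nu - 1$ (with the exponential prior), reusing cached predictions since
  neither changes the kinetics.

All proposal scales adapt by Robbins–Monro toward standard acceptance
targets during burn-in only and are frozen afterwards, so retained draws
come from a fixed transition kernel. Scales are clamped to $[10^{-3}, 20]$
and proposals extreme enough to underflow the parameter exponentials are
treated as rejected states rather than errors. Initial values are
$\ln\theta = \ln\bar\mu$ jittered with SD 0.1 under the chain-indexed seed
(overdispersed starts), $\eta = 0$, $\Omega = \Omega_0$, $\sigma_C = 0.2$,
$\nu = 5$, $f = 1$.

The default protocol is 3 chains × 6000 iterations, burn-in 3000, thinning
3 — i.e. 3000 retained draws. Convergence is declared when every
Gelman–Rubin $\hat R$ (classic formula, computed per scalar parameter
including all $\eta$) is below 1.2; a failing fit is flagged and warned
about, never silently accepted. Chains that are numerically constant get
$\hat R = 1$ with a warning. Two fits with the same seed are bit-identical;
chain seeds derive from the master seed.

## Model assessment

**DIC.** `dic()` reports $\bar D$ (posterior mean deviance), $\hat D$
(deviance at the posterior means of all parameters, *conditional* on the
subject-level $\eta$ — the node-based focus BUGS uses), $p_D = \bar D -
\hat D$ and $DIC = \bar D + p_D$. The conditional focus is stated in the
output.

**Posterior predictive check.** `posterior_predictive_check()` simulates
replicate datasets from retained draws — each subject's own posterior
$\eta_i$, dosing and sampling design, with fresh t noise — and compares
observed 10th/50th/90th percentiles per time bin against 95% intervals of
the same percentiles across replicates. Bins follow the nominal protocol
times (1, 4, 8, 12, 16, 20, 24 h during infusion; 0, 5, 10, 20 min and 1,
2, 4, 6 h after cessation), assigning each observation to the nearest
nominal time within its occasion; the exact bin edges used in the original
analysis are unstated, so this protocol-time binning is a reasoned
reconstruction. Bins with fewer than three observations are dropped with a
warning.

**Prediction errors.** `prediction_errors()` implements
$PE = 100(\text{observed}-\text{predicted})/\text{predicted}$ per
observation, a median per subject, and MDPE/MDAPE as medians of the
per-subject (absolute) medians. Population predictions set $\eta = 0$ while
keeping covariates and occasion fractions — the usual population-prediction
convention, stated in the output. MDPE is a median of medians: its
cohort-level sampling spread is several percentage points even when
predictions use the generating parameters, so bias checks in the test suite
are paired (fitted vs generating-parameter MDPE on the same cohort).

**Covariate screen.** `eta_covariate_screen()` tabulates Spearman rank
correlations of posterior-mean $\eta$ against age, weight, total dose,
infusion duration and PRISM, and a standardised mean difference for sex —
a plot-ready screen, not a formal test, mirroring how such relationships are
examined graphically. The flag threshold $|\rho| \ge 0.4$ is configurable
and always reported; constant covariates are reported as undefined.

**Occasion-shift probabilities.** `fraction_effect_probability()` reports
$\Pr(|\ln f_P| > \ln 1.2)$ from the retained draws — the share of posterior
mass beyond a 20% clinically significant change. Whether the original
definition was one- or two-sided is not stated; the two-sided version is the
default and the one-sided variant is an option.

## Synthetic cohorts

`generate_dataset()` emulates the study design so the whole pipeline is
testable:

* **Demographics.** 38 children, ages 1.4–188.6 months. A plain log-uniform
  age over that range has median ~16 months, far below the study's median of
  70, so ages are drawn piecewise log-uniform below/above a 70-month anchor
  (half the cohort on each side), which reproduces both the range and the
  median. Weight follows a smooth paediatric growth approximation
  ($(age+9)/2$ kg in infancy, linear at 2 kg/year above one year) with
  15% lognormal spread, clamped to 4.7–60 kg; sex is 23:15 male:female;
  PRISM scores are geometric-tailed over 0–11 with median ≈ 0–1.
* **Dosing.** Infusions start at 0.8 µg/kg/h and are stepped ±0.2 µg/kg/h
  (bounds 0.2 and 1.4) at 12-hourly reviews by a two-state latent
  sedation-adequacy process (step-up and step-down probabilities 0.15 each).
  The clinical sedation scoring itself is out of scope; only the resulting
  piecewise-constant dose trajectory matters for identifiability. Durations
  are log-uniform over 45–229.2 h (median ≈ 102 h, matching the study's
  97.3 h).
* **Sampling.** Pre-dose, then 1, 4, 8, 12, 16, 20, 24 h during infusion;
  at cessation and 5, 10, 20 min, 1, 2, 4, 6 h after — 16 scheduled samples,
  with optional small lognormal time jitter to emulate deviation from
  nominal times. A full default cohort yields on the order of 570
  observations, the same order as the study's 470.
* **Parameters and noise.** Generating values default to the final-model
  posterior means (CL 41.6, Q 56.8, V1 52.0, V2 70.4 per 70 kg; TE50 42.5
  weeks; Hill 2.45; fractions 1.31, 1.02, 1.50, 0.86; IIV 56/83/152/68 %CV).
  The residual scale and normality parameter are not reported for the final
  model, so the generator uses $\sigma_C = 0.2$ and $\nu = 5$ — a residual
  spread of roughly 20% with visibly heavy tails, a realistic regime for
  sparse ICU concentration data — plus a 3% chance per observation of a
  gross 5–10× multiplicative shock, emulating the few outliers such
  datasets contain. All values are overridable; everything is reproducible
  from one seed.

What passing tests on these cohorts do **not** show: the generator draws
independent diagonal random effects, titration is a memoryless proxy for
clinical sedation management, co-medication, assay error structure and
below-LOQ censoring are absent (the assay's detection limit is pg/mL,
negligible here). Recovery results on synthetic cohorts therefore validate
the machinery, not the clinical conclusions.

A deliberate feature of the default study conditions is prior–data conflict:
the prior centres $Q$ at 78.3 L/h while the generating value is 56.8 L/h,
about 1.9 prior SDs away, and the Wishart prior concentrates the IIV well
below the generating 83–152 %CV. With 38 sparse subjects the posterior for
$Q$ remains prior-dominated, so its 90% interval does not always cover the
generating value — the same tension the informative-prior design resolves in
favour of the literature when the new data are weak. The recovery tests
accordingly require coverage for at least five of the six typical values
plus the strongly identified $f_{V_1}$.

## Data interchange

Datasets are NONMEM-flavoured but self-describing CSVs: a `# units:` header,
one row per dose event or observation, an explicit `DUR` column instead of
rate codes, `DV` blank on dose rows, positive on observations and exactly 0
on pre-dose design rows, and absolute hours from first dose. Numbers are
written with enough digits to round-trip doubles exactly. Priors serialise
to JSON (`write_priors()`), and `write_manifest()` captures everything
needed to re-execute a fit (seeds, configuration, priors, convergence, DIC,
package version). The package's interface is its exported functions; the
reproduction script `scripts/acceptance.R` is the only command-line entry
point.

## Problem sizes used by the test suite

The shipped tests run the full pipeline at reduced but honest sizes chosen
to keep a complete run in minutes on one core: kinetics are checked against
the ODE oracle on dozens of random schedules at $10^{-6}$ relative
tolerance; prior arithmetic is exact; the prior-reproduction
(no-observation) fit uses 2 × 1200 iterations; the study-scale recovery fit
uses the full 38-subject design at 3 chains × 2000 iterations (burn-in 1000,
thin 2), the reduced protocol also used for the DIC model comparison and the
predictive-check calibration. The full 3 × 6000 protocol remains the
default for real analyses.

## Known limitations

* The sampler is random-walk based; posteriors much sharper than the study
  conditions (e.g. near-noiseless data) mix slowly and will be flagged by
  $\hat R$ rather than silently mis-summarised. Subjects whose heavy-tailed
  data admit two explanations (an outlier vs a strongly shifted random
  effect) have genuinely bimodal $\eta$ posteriors; the mode-hopping moves
  traverse them, but their $\hat R$ can sit near the 1.2 threshold at the
  default run length.
* DIC uses the conditional ($\eta$-level) focus only.
* No covariate model building beyond the screen; no nonlinear elimination,
  transit absorption, metabolite or interaction kinetics; no below-LOQ
  handling; no prediction-corrected VPC or NPDE.
* $PMA$ from postnatal age assumes term gestation.
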