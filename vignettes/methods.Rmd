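---
title: "Models and methods behind aaascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aaascreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aaascreen)
```

This vignette is the package's own account of its models: what is assumed,
which parameters matter, what the synthetic data do and do not emulate, and
where genuinely open design choices were settled.

## 1. The scientific question

Abdominal aortic aneurysm (AAA) — dilatation of the abdominal aorta beyond
3 cm — is usually silent until rupture, which is fatal in the large
majority of cases. One-off ultrasound screening of 65-year-old men reduces
rupture deaths, but population prevalence has fallen below 1%, so the
question has shifted from *whether* to screen to *whom* and *when*. The
package evaluates invitation policies stratified by polygenic risk score
(PRS) tertile and smoking status, in both sexes, on an incremental net
benefit (INB) scale. The pipeline has four stages: a synthetic cohort
generator, survival/competing-risks estimation, a discrete event simulation
(DES) of AAA natural history and screening, and health-economic
aggregation.

## 2. The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of a large
prospective biobank test set (about 92,000 individuals, an approximately
1:1 sex ratio, entry ages 40–70, a standard-normal PRS, three smoking
classes, competing outcomes of hospital-recorded AAA versus non-AAA death,
censoring at age 80 or after a 12-year administrative window). The
cause-specific AAA hazard is Gompertz-like in age,

$$\lambda_1(a) = \lambda_0 \, e^{\gamma (a - 60)} \, e^{x^\top\beta},$$

with multiplicative subgroup effects on the *cause-specific* (not
subdistribution) hazard, matching the Cox model that is later fitted. The
default log hazard ratios encode the association structure the pipeline is
designed to recover (tertiles 2.13/3.70; smoking 2.36/7.74; male 4.56;
1.77 per SD in the continuous parameterisation). Non-AAA mortality comes
from the supplied life table, independent of PRS and smoking — the working
assumption throughout is that PRS and smoking act on AAA incidence only.

Choices that are *ours*, labelled illustrative because no reference
values are published for the emulated test set: the smoking mixture (55% never / 35% ex / 10%
current, typical of UK cohorts of this vintage), the baseline hazard
$\lambda_0 = 4\times10^{-5}$/yr at age 60 with slope $\gamma = 0.08$/yr
(calibrated so that roughly 0.8% of the cohort records an AAA over a
12-year median follow-up, about 1.3% of men and 0.3% of women), and the
built-in Gompertz–Makeham life table (about 0.8%/yr male mortality at 60).
Latent AAA ages are drawn by closed-form inversion of the Gompertz
cumulative hazard; the test suite cross-checks the generator against an
independent discrete-time Bernoulli simulator at $n = 200{,}000$.

What the generator does **not** emulate: covariate correlations (PRS is
independent of smoking and sex by construction), secular trends, the
"healthy volunteer" selection of real cohorts, loss to follow-up (about 0.2% in
the emulated test set; default 0 here), and the full clinical covariate block.
Tests passing on this cohort therefore demonstrate *internal* statistical
correctness (estimators recover what was simulated), not external validity.

## 3. Survival estimation on the age scale

`fit_cox_age_scale()` maximises the left-truncated partial likelihood with
**Breslow** tie handling — chosen over Efron because it admits a
hand-computable oracle and the difference is negligible at the tie rates
simulated; the choice is stated so results are reproducible bit for bit.
Age is the time-scale (risk set: `entry_age < t <= exit_age`), which is the
natural scale when incidence is age-driven; a calendar-time analysis is
deliberately not offered. Newton–Raphson iterates to a score sup-norm below
1e-8 with step-halving; risk-set sums at all event ages are assembled from
prefix sums over exit-sorted and entry-sorted weighted covariate columns,
so one iteration is O(n log n) and a 500,000-person fit takes a few
seconds. Monotone likelihoods (complete separation) are flagged as
non-converged — the flag fires when any per-SD log hazard ratio exceeds 10 —
instead of silently returning a huge coefficient. Per-SD PRS effects
standardise the score to unit variance in the analysis sample before
fitting.

`aalen_johansen_cif()` is the standard product-limit estimator with
cause-specific increments $S(t^-) d_k(t)/n(t)$ and delayed entry. The
identity $S + \sum_k \mathrm{CIF}_k = 1$ holds to 1e-10 by construction and
is asserted in tests.

`fit_fine_gray()` maximises the IPCW-weighted subdistribution partial
likelihood. Individuals with a competing event remain in the risk set with
weight $g(t)\,v_i$, where $v_i = S(T_i^-)/n(T_i)$ and $g(t) = n(t)/S(t^-)$
are expressed through the all-cause Kaplan–Meier and the observed risk-set
size. This is the Geskus formulation of the classical censoring-KM weights;
its virtue is exactness: with no covariates the weighted product-limit CIF
*equals* the Aalen–Johansen estimator to machine precision, with or without
left truncation, which the suite asserts at 1e-8. Coefficients agree with
`cmprsk::crr` to about 1e-5 on shared-convention data. Standard errors use
the model-based information and treat the weights as fixed — a known
simplification (the sandwich variance of `crr` differs in the fourth
decimal on our test problems). The time-scale for the Fine–Gray model is
age, for consistency with the Cox fit; published analyses of this design
are often ambiguous on this point, so the choice is recorded here.

**Prevalence calibration.** Hospital-recorded AAA captures only part of
what ultrasound screening finds. The ratio of screening-observed to
modelled prevalence in 65-year-old men (0.91%/0.41% = 2.2 for the published
benchmark) is used as a multiplicative factor `F` on subgroup CIFs taken at
the index age — 60 in men, 65 in women (the ages at which the DES starts);
the same `F` is applied to women because no female screening benchmark
exists. Prevalences are capped at 1 with a warning. Tertile ties go to the
lower group (deterministic and order-independent); tertile cut points are
the order statistics at `round(n/3)` and `round(2n/3)`.

## 4. Natural history and the discrete event simulation

A *susceptible* individual carries a log-linear latent diameter,
$d(t) = \exp(b_0 + b_1 t)$ with $(b_0, b_1)$ bivariate normal; measurement
error (SD 0.2 cm) affects observed scans only, never the latent state.
Rupture is an inhomogeneous Poisson process with rate
$\lambda(t) = m_{\text{sex}} \exp(\alpha + \beta d(t))$, sampled by
thinning against yearly-segment bounds; the thinning sampler is verified
against numerical inversion of the cumulative hazard by Kolmogorov–Smirnov
tests. Non-susceptible individuals hold a constant 2 cm aorta and can never
rupture. The susceptible mixture weight is calibrated so that
$w \Pr[d(0) \ge 3\,\text{cm}]$ equals the target point prevalence at the
index age; because $d(0)$ is log-normal this equation is solved in closed
form (exact, rather than the Monte-Carlo root-finding one might use with a
non-analytic diameter model). The mixture also produces *late-developing*
AAAs — susceptibles below 3 cm at the index age who cross the threshold
later — which pure cross-sectional seeding would miss; they are the reason
a one-off screen cannot capture all eventual disease.

All natural-history defaults are calibration values of this package, not
published estimates (the upstream screening simulation models document
their parameters in separate technical reports). They were chosen once so that the simulation
reproduces the qualitative cost-effectiveness pattern of published UK
evaluations — INB versus no invitation negative below roughly 0.2%
baseline prevalence, positive well above it, monotone in prevalence, with
invitation around 60–62 optimal for high-prevalence male subgroups:

| parameter | default | units / meaning |
|---|---|---|
| `mean_intercept` | log(2.6) | median susceptible diameter at index age (cm, log scale) |
| `re_cov` | SDs 0.40, 0.030; cov −5e-4 | heterogeneity of level and relative growth |
| `mean_slope` | 0.03 | relative growth per year (≈1 mm/yr at 3 cm) |
| `measurement_sd` | 0.2 | ultrasound error (cm) |
| rupture `alpha`, `beta` | −13.0, 1.6 | ≈0.03%/yr at 3 cm, 1.5%/yr at 5.5 cm, 80%/yr at 8 cm |
| `female_rupture_multiplier` | 1.5 | higher female rupture risk at a given diameter |
| `incidental_detection_rate` | 0.05/yr | opportunistic detection while an AAA is present |
| `surveillance_dropout_rate` | 0.02/yr | loss from monitoring |

The screening pathway follows the UK programme: one-off invitation
(attendance 75% men / 72% women), discharge below 3 cm, surveillance at
3.0–4.5 cm yearly and 4.5–5.5 cm quarterly, referral at 5.5 cm, elective
repair with 3% 30-day mortality, 33% of ruptures reaching emergency surgery
with 37% 30-day mortality, simulation from 60 (men) or 65 (women) to 95.
Women share the male bands and threshold by default (configurable; the
evidence for sex-specific thresholds is unsettled). Re-screening and
re-intervention are not modelled; elective survivors exit AAA risk. People
already under surveillance or repaired are not re-screened at the
invitation age. Individuals who drop out of surveillance re-enter only via
incidental detection. Scan counts reported "per 10,000 invited" include the
invitation scan and surveillance initiated by it, but not monitoring that
began with an incidental detection — so a no-invite arm reports zero
programme scans while still incurring the costs of incidental care.

**Event-queue mechanics.** Events are processed in age order with lazily
(re)drawn clocks; the latent rupture age is drawn *once* per person from
the unrepaired trajectory, which is exact because nothing before repair
alters that trajectory, and it doubles as the common-random-numbers (CRN)
coupling: all natural-history randomness (susceptibility uniforms, growth
effects, death age, rupture age, attendance uniform) derives from
per-person seeds independent of policy, so arms differing only in policy
share identical natural histories, and raising prevalence enlarges the
susceptible set monotonically — the INB-versus-prevalence curve is monotone
by coupling rather than by sample size. Same-age clinical chains (scan,
referral, operation, 30-day operative death) are recorded at the same age
in clinical order; trace ages are therefore non-decreasing rather than
strictly increasing, and operative deaths carry no sub-month resolution
because the life tables are annual.

## 5. Health economics

QALYs integrate an age-banded utility step function (0.80 to 65, 0.78 to
75, 0.73 to 85, 0.65 beyond) over survival, discounted mid-year at 3.5%/yr;
costs (scan £50 including screening-episode administration, surveillance
scan £70, elective repair £9,500, emergency repair £14,500) are discounted
from the event age. Both the discount rate and all unit values are
conventional placeholders, stated here because nothing forces any
particular value, and sit in
`econ_config()` where every results artifact records them. INB is
λ·ΔQALY − ΔCost against the no-invite arm of the same seed (CRN cancels
most Monte-Carlo noise). Strategies are evaluated per subgroup, aggregated
by observed subgroup weights (no-invite subgroups contribute 0), and the
population net gain multiplies the INB difference versus the current
strategy by the eligible population size.

"100 bootstrap PSA samples" in this literature can mean nonparametric
resampling of simulated individuals or probabilistic re-sampling of input
parameters; the package implements the latter (`psa_intervals()` with
declared distributions per parameter — beta for probabilities, gamma for
costs, normal/lognormal for rates) because it is the standard probabilistic
sensitivity analysis and the more informative of the two readings; the
interval is the nearest-rank 5th/95th centile over the re-evaluations.
Whether published mean QALYs are discounted is unstated; we discount both
QALYs and costs and say so.

Genotyping is free in the base case (the futuristic scenario in which
population genomic profiles already exist); sensitivity values of £23–£31
per test are applied once per person — per genotyped person by default, or
per invited person via the `genotyping_charge` switch — and only to
strategies that actually use the PRS, so the net gain is exactly linear and
decreasing in the genotyping cost.

## 6. Numerical choices and test scales

Degenerate inputs are rejected at construction time (band gaps, probability
ranges, non-PSD covariances, non-contiguous life tables), never mid-run.
Ties: Breslow in both partial likelihoods; tertile ties to the lower group;
invitation-age ties to the earliest age. The acceptance-style checks run at
the sizes a single CPU handles comfortably while keeping Monte-Carlo error
far below the effects tested: 500,000-person cohorts for hazard-ratio
recovery (events ≈ 4,000; CI half-width ≈ 10% of the HR), 50 replicates of
100,000 for Wald coverage, 60,000 per arm for the INB-prevalence curve,
200,000 for the low-prevalence sign check, and 100,000 for the two-arm
death-reduction comparison; the published evaluations use 1,000,000-person
arms, which the same code runs in minutes when wanted.

## 7. Known limitations

The natural-history and economic defaults are calibration values: absolute
INBs, event rates and net gains from this package characterise the model
world, not the NHS programme, and only their qualitative structure (signs,
orderings, monotonicities, linearities) should be compared with published
results. Fine–Gray standard errors ignore weight estimation. The DES has no
waiting-list dynamics, no EVAR/open distinction, no re-intervention, and no
smoking or PRS effect on growth, rupture or non-AAA mortality (the conventional
assumption that these are consistent across strata). PRS enters
as a phenotypic z-score; no genotypes are simulated. Value-of-information
analysis is out of scope.
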