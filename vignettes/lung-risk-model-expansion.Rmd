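---
title: "Expanding lung cancer risk models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expanding lung cancer risk models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lungrisk)
```

`lungrisk` implements an analysis pattern from cancer-screening
epidemiology: take a risk-prediction model built from conventional
questionnaire predictors, expand it with candidate low-cost measurements
(a liver blood test panel and urate, spirometry, alcohol status, waist
circumference), quantify how much prognostic information the expansion
adds, and translate the change in who gets referred for low-dose CT
(LDCT) screening into a cost per lung cancer case detected. Because the
motivating cohort data (a UK population biobank of ~500,000 adults with
~0.5% incident lung cancer over a ~7-year median follow-up) are access
controlled, the package ships a synthetic cohort generator that emulates
the relevant structure, so the whole pipeline is testable end to end.

## The survival model

The core model is a flexible parametric (Royston–Parmar) proportional
hazards model on the log cumulative hazard scale,

$$\log H(t \mid x) \;=\; s(\log t;\gamma) \;+\; x'\beta
\;+\; \textstyle\sum_k z_k\, s_k(\log t;\gamma_k),$$

where $s(\cdot;\gamma)$ is a restricted cubic spline of log time that
carries the baseline, $x$ collects covariate and interaction columns,
and the optional $z_k\,s_k(\log t)$ products let selected covariates
have time-dependent (non-proportional) effects through their own 2-df
log-time sub-basis. With a 1-df baseline ($s = \gamma_0 + \gamma_1 \log
t$) the model is exactly Weibull, which the tests exploit as a closed
form.

With event indicator $d_i$ and $\eta_i = \log H(t_i \mid x_i)$, the log
likelihood is

$$\ell = \sum_i \Big\{ d_i\big[\log \tfrac{\partial \eta_i}{\partial
\log t} - \log t_i + \eta_i\big] - e^{\eta_i} \Big\},$$

the standard form for models specified on the log cumulative hazard
scale. A parameter point where $\partial\eta/\partial\log t \le 0$ at an
event time implies a non-positive hazard and gets $\ell = -\infty$ —
reported, never clipped. On censored rows a locally decreasing
$\eta$ is harmless and deliberately does not enter the likelihood.

### Spline conventions

Restricted cubic splines use the truncated-power natural basis: $k$
knots give $k-1$ columns, the first being the variable itself, each
nonlinear column normalised by $(k_{\max}-k_{\min})^2$ for conditioning
(fits are invariant to this affine choice). Covariate splines place
knots at Harrell's default percentiles (10/50/90 for 2 df, 5/35/65/95
for 3 df, 5/27.5/50/72.5/95 for 4 df), computed with linear
interpolation between order statistics (`quantile()` type 7 — the
convention had to be fixed somewhere and is documented here). Knots are
computed on the analysis sample *after* complete-case exclusion. The
baseline log-time spline puts boundary knots at the extremes of the
uncensored log event times and internal knots at equally spaced
centiles of the same distribution; time-dependent effects use a
separate 2-df sub-basis whose 3 knots follow the same rule. The
baseline df is configurable with default 3 (the value is not dictated
by the emulated analysis; 2–4 are all common practice, and the
scenario presets expose it).

A time-dependent effect multiplies the *first* column of a covariate's
main-effect block (the transformed variable itself) by the log-time
sub-basis, so each selected "timescale" interaction costs exactly 2 df.

### Fitting

The likelihood above is concave in the coefficients wherever the hazard
is positive at the event rows: its Hessian is
$-M_p'\,\mathrm{diag}(d/D^2)\,M_p - M'\,\mathrm{diag}(e^{\eta})\,M$,
a sum of two negative-semidefinite terms ($M$ and $M_p$ are the design
for $\eta$ and its log-time derivative, $D = M_p\theta$). The package
therefore fits by damped Newton–Raphson on the analytic Hessian rather
than quasi-Newton: full Newton steps, a closed-form fraction-to-boundary
cap (the largest step keeping $D>0$ at every event row, available
because $D$ is linear in $\theta$), and step halving. Three numerical
safeguards matter in practice:

* all non-intercept design columns are centred and scaled internally —
  an exact reparameterisation (the intercept absorbs constant shifts
  and the derivative design is unchanged by centring) that removes the
  severe scale anisotropy of columns like age (~58) next to spline
  terms (~0.1);
* the Newton solve is Jacobi preconditioned;
* the baseline spline coefficients are initialised from a least-squares
  fit of $\log(-\log \hat S_{KM})$ on the time basis at event times,
  with covariate coefficients at zero — deterministic, so refits are
  bit-stable.

Convergence requires a relative log-likelihood change below 1e-9 and a
relative max gradient below 1e-6 (cap 200 iterations). Monotonicity of
$\eta$ in log time is checked at event times after fitting and flagged,
not constrained. Standard errors come from the inverse analytic Hessian,
delta-transformed back to the raw parameterisation. The model has no
delayed entry: the timescale is time since cohort entry, with everyone
entering at 0, matching the emulated design. Reported model degrees of
freedom count all estimated coefficients except the baseline intercept.

## Model selection

Functional forms of continuous variables (linear, log, spline with 2 or
3 df) and interactions (sex, age, smoking status, timescale) are chosen
by information criterion. The search is deliberately simple and fully
deterministic: transforms are selected one variable at a time with the
other variables held at their current forms, then interactions are
added by forward steps in the fixed order sex, age, smoking status,
timescale, keeping a partner only if it lowers the criterion; ties go
to fewer parameters. AIC is the default; BIC uses the number of
*events* as the effective sample size (the conventional choice for
rare-event survival data; rows are available as an option). A
split-sample mode selects on one random half and leaves the other for
estimation. Since the emulated analysis reports only the criterion, not
its search order, the order here is a documented package choice.

The four screening scenarios are preset specs: Scenario 1 the
conventional predictors; Scenario 2 adds FEV1 (linear + 3-df spline),
alcohol status and log waist; Scenario 3 adds the blood panel (all
log-transformed, with sex/age/smoking interactions and 2-df
time-dependent effects for selected analytes); Scenario 4 everything.
They are nested by construction, which downstream statistics rely on.

## Performance statistics

*Harrell's c-index* is computed over comparable pairs (the earlier time
must be an event; tied times with exactly one event are comparable with
the event ranked riskier). Tied scores count 1/2, and tied-time
both-event pairs — whose ordering is undefined — are included at 1/2
under the same convention. This inclusion differs from some
implementations (e.g. `survival::concordance` excludes them), so the
package's own exhaustive pair-enumeration oracle anchors the tests and
the cross-check against `survival` uses tie-free data. The default
confidence interval uses a leave-one-subject-out jackknife computed
from per-subject pair sums in the same $O(n^2)$ pass; a seeded
bootstrap is available. On large cohorts the pipeline caps the c-index
sample by keeping every event and subsampling censored rows, which
leaves the estimate unbiased (pair counts scale uniformly in a ratio)
while bounding the quadratic cost; the cap is configurable.

*Fraction of new information* is $1 - \chi^2_{\text{ref}} /
\chi^2_{\text{alt}}$ on model likelihood-ratio chi-squares versus a
shared null; the *heuristic shrinkage factor* is $(\chi^2 -
\text{df})/\chi^2$. Both are exact arithmetic and are exercised against
published values. P-values between scenarios come from likelihood-ratio
tests on the identical complete-case rows (the functions refuse fits on
different row sets).

## The screening economic model

Eligibility is ever-smokers with age in whole years inclusively within
55–74 (floored at contact). Everyone eligible is telephone-screened
(£20.57); those whose *reference-model* 6-year risk meets the 1.51%
threshold receive the scenario's follow-up tests (spirometry £63.42,
blood panel £7.16, both £70.58 — 2022 unit costs consumed as given, no
inflation adjustment); those also meeting the threshold under the
scenario's own model are referred for LDCT (£92.77). Cases are referred
participants diagnosed within the horizon; a single screen is assumed
to detect 20% of them. The cost-per-case denominator uses the
*unrounded* expected detections $0.2 \times n_{\text{cases}}$ — this is
what reproduces the published £26,944 (4,079,330/151.4) rather than
£27,015 (÷151) — while the reported case count is rounded separately.
Intermediate totals are kept at full precision; only final figures are
rounded (£ to the pound). Zero detected cases yield an explicit missing
value, never infinity. Threshold and subgroup sensitivity re-run the
same arithmetic per threshold or per group (contact costs allocated by
group size); incidental-findings rates flag AST/ALT > 2 and FEV1/FVC
< 0.7 among participants without a baseline lung disease diagnosis,
with zero/missing denominators excluded and counted.

## The synthetic cohort

`cohort_config()` defaults emulate the motivating cohort's published
baseline table: category probabilities renormalised over non-missing
values; right-skewed blood measurements log-normal with location/spread
matched to medians and IQRs (log-normality is also why the selected
models log-transform every analyte); age truncated normal on 40–70.
Only a small set of dependencies is modelled explicitly — pack-years by
smoking status, FEV1 declining in age and pack-years, FVC as
FEV1/ratio with the ratio centred near 0.75 and lower for older
heavier smokers, AST–ALT correlated 0.75 on the log scale so the
AST/ALT>2 flag fires at a realistic ~4.5%, emphysema prevalence rising
with smoking. A full copula of the real cohort's joint distribution is
deliberately out of scope; passing tests therefore demonstrate
correctness of the *machinery*, not that real-data c-indexes or risk
distributions are reproduced (the synthetic truth is in fact more
discriminative than the real predictors, and c-indexes run higher).

Event times are drawn by inverse-transform sampling from the configured
true hazard: solve $\eta(\log t) = \log(-\log U)$ by vectorised
bisection (60 iterations over $\log t \in [\log 10^{-8}, \log 600]$),
after verifying on a grid that $\eta$ is increasing in log time for
every subject — a non-invertible configuration is rejected with a
diagnostic. Censoring is administrative — entry uniform over a 4-year
recruitment span with one fixed end date, giving potential follow-up
uniform on [5, 9] years and a median of 7.0 — plus independent
exponential mortality (rate 0.006/yr). A uniform 4-year recruitment
window cannot also reproduce the published follow-up IQR of 6.4–7.7
(the real recruitment curve was not uniform); the median is matched and
the IQR is wider, a known and accepted discrepancy. The default
baseline intercept was calibrated once by Monte Carlo so the marginal
event fraction is ~0.5% like the emulated cohort, and frozen.
Missingness is injected per variable, completely at random, at the
published per-variable rates; because real blood-panel missingness is
jointly assayed, independent MCAR yields ~50–55% complete cases versus
the real 77% — accepted, since the analysis only needs a
complete-case sample of realistic composition. The default
data-generating hazard uses a 2-df spline baseline, conventional risk
factors, a log-bilirubin effect with sex interaction and a 2-df
time-dependent effect, log-urate by smoking status, and linear FEV1,
so every model feature is exercised. With the default ~0.5% event
fraction, parameter-recovery studies would need enormous cohorts, so
the test suite uses the same structure with the intercept raised
(~4–5% events, ~1,000 events at n = 20,000) — the recovery study runs
50 such cohorts and requires every coefficient's mean estimate within
3 Monte-Carlo standard errors of truth.

## Problem sizes and reproducibility

All randomness flows from explicit seeds; `run_pipeline()` derives
distinct sub-seeds for cohort generation, missingness, subsampling and
selection from one master seed, and identical configuration gives
byte-identical artifacts. The shipped acceptance script simulates
120,000 participants (≈650 events), fits the four scenario models plus
the null on the complete-case sample, evaluates the c-index on a
20,000-row event-preserving subsample, and runs the economic model on
the eligible ever-smokers — sizes chosen as a good
precision/turnaround compromise for a single workstation core; all are
configurable upward.

## Known limitations

* MCAR-only missingness; no imputation (the emulated analysis's
  multiple-imputation sensitivity check is out of scope).
* No delayed entry, cure fraction, competing risks or penalised
  estimation.
* The interaction search is marginal and ordered, not exhaustive; a
  different order can select a different set when candidates are
  correlated.
* The c-index confidence interval method (jackknife) is a package
  choice; published interval widths are not a reproduction target.
* Synthetic cohorts do not reproduce the real cohort's joint covariate
  distribution, only its margins and a few key dependencies.
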