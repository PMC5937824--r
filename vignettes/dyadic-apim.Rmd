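---
title: "Dyadic analysis of depression and quality of life with the Actor-Partner Interdependence Model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dyadic analysis with the Actor-Partner Interdependence Model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadkit)
```

## The problem and the model

Couple data are interdependent: when both partners of a dyad report an
outcome, the two reports correlate within the dyad, and a person's outcome
may depend on the *partner's* characteristics as much as their own.
Individual-level regression ignores both facts. The Actor-Partner
Interdependence Model (APIM) for distinguishable dyads takes the dyad as
the sampling unit and estimates both kinds of influence simultaneously.
With predictor $X$ (here PHQ-9 depression) and outcome $Y$ (here FertiQoL
quality of life) measured on both members of a male-female dyad, the model
is the pair of structural equations

$$Y_m = a_m X_m + p_{mf} X_f + E_m, \qquad
  Y_f = a_f X_f + p_{fm} X_m + E_f,$$

where $a_m, a_f$ are **actor effects** (own depression on own QoL),
$p_{mf}, p_{fm}$ are **partner effects** (the spouse's depression on one's
own QoL), the exogenous covariance $\Phi = \mathrm{Cov}(X_m, X_f)$ carries
the partners' "compositional" similarity, and the residual covariance
$\Psi = \mathrm{Cov}(E_m, E_f)$ carries the non-independence the paths do
not explain. The equations carry no intercepts: all quantities of interest
are functions of the covariance matrix, so means are left saturated.

## Estimation

dyadkit fits the model by maximum-likelihood covariance-structure
analysis. Writing $B$ for the $2 \times 2$ slope matrix, the model-implied
covariance over $(X_m, X_f, Y_m, Y_f)$ is

$$\Sigma(\theta) = \begin{pmatrix} \Phi & \Phi B' \\ B \Phi & B \Phi B' + \Psi \end{pmatrix},$$

and the ML discrepancy against a sample covariance $S$ is
$F_{ML} = \log|\Sigma| + \mathrm{tr}(S \Sigma^{-1}) - \log|S| - p$.

The unconstrained APIM has 10 parameters against 10 observed moments: it
is *saturated*, fits $S$ exactly ($\chi^2 = 0$ on 0 df), and its ML
estimates have closed form — each outcome regressed on both predictors
from the covariance matrix, $\Phi$ the sample predictor covariance, $\Psi$
the residual covariance of the two equations. `fit_apim()` therefore uses
no optimizer at all; the optimizer is reserved for constrained models.
The closed form requires the two predictors not to be collinear
($|r_{X_m X_f}| < 1 - 10^{-10}$); past that the fit fails loudly rather
than silently pseudo-inverting.

Because all estimates are functions of $S$ alone, `fit_apim()` accepts
either a raw wide dyad table (one row per couple, listwise-deleted) or a
`moment_summary` of means, SDs (denominator $n-1$), correlations and $n$ —
exactly what published descriptive tables provide. The two routes agree
identically by construction, which `match_moments()` makes testable: it
manufactures raw data whose sample moments equal a target summary to
numerical precision (random normal draws, empirically whitened, recolored
by the Cholesky factor of the target covariance, shifted to the target
means).

### Scales, standard errors and their conventions

Standardized coefficients are $\beta = b \cdot \sigma_x / \sigma_y$ with
model-implied SDs (equal to the sample SDs in the saturated model).
Two SE conventions are reported side by side and must not be conflated:

* unstandardized slopes get expected-information SEs — the inverse Hessian
  of $(c/2)\,F_{ML}$ at the estimate, with $c$ the $\chi^2$ multiplier;
* standardized slopes get delta-method SEs, propagating the full parameter
  covariance through $\beta(\theta)$.

These differ numerically (on the embedded study, $\approx 0.060$ vs
$\approx 0.049$ for the actor paths' standardized scale) because the
standardized coefficient's denominator is itself estimated. Published
dyadic analyses rarely state which convention their software printed, so
dyadkit labels both. Hessians and Jacobians are evaluated numerically
(central differences via pracma); for this 10-parameter smooth problem
that is accurate to far below the Monte-Carlo noise of any realistic SE.

The $\chi^2$ multiplier defaults to $n - 1$ (Wishart likelihood
convention); $c = n$ is available via `apim_spec(multiplier = "n")`. The
choice only moves fit statistics in the third decimal but is recorded and
enforced to match across fits entering a difference test.

## Equality-constraint tests

Four 1-df hypotheses are standard for this design: equal actor effects
($a_m = a_f$), equal partner effects ($p_{mf} = p_{fm}$), and actor =
partner within each role's equation. `fit_constrained()` reparameterizes —
the constrained pair literally shares one free parameter, no penalty — and
minimizes $F_{ML}$ over the 9 remaining parameters by BFGS with numeric
gradients, $\Phi$ and $\Psi$ on the log-Cholesky scale so every iterate is
a proper covariance matrix. Convergence demands a relative $F$ change
below $10^{-10}$ or a gradient norm below $10^{-8}$ within 500 iterations;
up to three seeded, jittered restarts follow a failed start, and the
`converged` flag reports what actually happened. `chisq_difference()` then
forms $\chi^2_{\text{diff}} = \chi^2_{\text{constrained}} -
\chi^2_{\text{unconstrained}}$, $df_{\text{diff}}$ likewise, with p from
$\chi^2(df_{\text{diff}})$. Differences in $(-10^{-6}, 0)$ are numerical
noise and clamp to zero; anything more negative is treated as a user error
(non-nested fits).

Equality can be imposed on the raw slopes (default, standard SEM practice)
or on the standardized coefficients (`scale = "standardized"`), which
differ whenever the roles' SDs differ — as they do in the embedded study
(male vs female depression SDs 5.47 vs 5.78). For the standardized actor-
and partner-equality constraints the shared parameter is the standardized
value itself (mapped through $\tanh$ to stay in $(-1,1)$), and the implied
slope solves a quadratic in the model-implied outcome SD; for the
within-role constraint the equality reduces to a linear relation between
the two slopes because they share an outcome SD.

## The embedded study and what the package reproduces

`infertile_couples_moments()` embeds the descriptive summary of a
cross-sectional study of 180 infertile male-female dyads (PHQ-9 and core
FertiQoL from both partners): means, SDs and the 12-variable correlation
matrix, printed to two decimals. From these moments the package reproduces
the study's analysis chain: paired role comparisons (t = 3.61 for
depression, |t| = 4.09 for total FertiQoL), the correlation report, the
saturated APIM per outcome (standardized actor effects about −0.59 for
both roles on total FertiQoL, partner effects about −0.10 and −0.12), and
the four constraint tests (actor and partner equality far from
significance; actor-vs-partner within each role overwhelmingly
significant). Two-decimal input rounding means reproduction is exact only
to that resolution — which is why the package's checks compare at absolute
bands of ±0.015 on standardized paths and ±0.02 on t statistics, and why
the constraint-test chi-squares are checked for direction and
significance rather than digit-for-digit.

## What the simulator emulates — and what it does not

`simulate_dyads()` is the literal forward model: bivariate-normal
predictors, residuals bivariate normal and independent of the predictors,
outcomes from the two equations. Called through `simulation_config()` with
no arguments it reproduces the study conditions — 180 couples, predictor
moments equal to the published depression moments, slopes and residual
covariance equal to the ML estimates implied by the published summary for
total FertiQoL. Those defaults are the package's definition of "realistic"
for this design and are not tuned per analysis.

Real questionnaire data are not multivariate normal: PHQ-9 totals are
skewed counts with a floor at 0, FertiQoL scores are bounded and
discretized, and real couples are missing items. Passing recovery and
calibration tests on the simulator therefore demonstrates correctness of
the estimator under its own assumptions — consistency, SE calibration
($\chi^2(1)$ behaviour of the difference test at n = 200, 95% CI coverage
at n = 1000), not robustness to non-normality.

## Numerical choices and degenerate inputs

* Published correlation matrices rounded to 2 decimals can be marginally
  indefinite. `moment_summary()` tolerates eigenvalues down to −10⁻⁸
  (configurable) and offers clip-and-rescale repair, off by default so
  data are never silently altered; the embedded 12-variable study matrix
  is accepted under a wider documented tolerance as printed.
* `match_moments()` needs $n \ge p + 1$ to whiten; at $n = p$ it errors.
* A paired difference with zero SD yields an `infinite_t` flag, not a
  crash; McNemar with $b + c = 0$ returns $\chi^2 = 0$, $p = 1$ by
  convention and applies no continuity correction by default.
* FertiQoL items are consumed pre-oriented (4 = best QoL). The instrument
  has reverse-keyed items, but no keying table is assumed; a user-supplied
  `reverse_keyed` mask recodes as $4 - x$. Missing-item policy: PHQ-9
  prorates up to a configurable cap (default 0 missing); FertiQoL scores a
  subscale when at least 3 of 6 items are answered, and the total is the
  answered-item-weighted mean × 25, not the mean of subscale scores.
* Monte-Carlo problem sizes in the test suite (1000 null replicates at
  n = 200 for calibration, 500 replicates at n = 1000 for coverage, single
  n = 10⁵ draws for consistency) were chosen so sampling noise sits well
  inside the asserted bands.

## Known limitations

Only distinguishable two-member dyads are supported; indistinguishable
designs, k > 2 groups, latent measurement models, the k-ratio
(partner/actor) parameterization, and the multilevel or pooled-regression
estimation routes are out of scope. SE conventions beyond the two
implemented (e.g. observed-information or robust SEs) are not provided,
and no multiple-testing adjustment is applied across the four equality
tests.
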