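# dyadkit

Dyadic analysis of couple data with the **Actor–Partner Interdependence
Model (APIM)** for distinguishable dyads, fitted by maximum-likelihood
covariance-structure analysis — from raw one-row-per-couple tables *or*
directly from published summary statistics (means, SDs, correlations, n).

It is written for researchers analysing paired questionnaire data — the
motivating application is depression (PHQ-9) and fertility-specific
quality of life (core FertiQoL) in infertile male–female couples, whose
published summary tables ship with the package — but the machinery is
generic to any distinguishable-dyad predictor/outcome design.

## The model

For a dyad with roles *m* and *f*, predictor X and outcome Y:

    Y_m = a_m X_m + p_mf X_f + E_m
    Y_f = a_f X_f + p_fm X_m + E_f

with predictor covariance Φ and residual covariance Ψ. The `a` paths are
**actor effects** (own predictor → own outcome), the `p` paths **partner
effects** (spouse's predictor → own outcome). The unconstrained model is
saturated (χ² = 0, 0 df) and estimated in closed form; equality
constraints (a_m = a_f, p_mf = p_fm, actor = partner within a role) are
fitted by numerical ML and judged by χ² difference tests,
χ²_diff = χ²_constrained − χ²_unconstrained on df_diff = 1.

The toolkit around the model covers the full analysis chain:
questionnaire scoring (`score_phq9()`, `score_fertiqol_core()`), paired
t tests from raw vectors or summary moments, McNemar tests, correlation
reports with significance stars, Cronbach's α, moment-matched synthetic
data (`match_moments()`), forward-model simulation and parameter-recovery
experiments. Results are tibbles; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

Refit the embedded couple study (180 dyads) from its summary statistics:

```r
library(dyadkit)

fit <- fit_apim(infertile_couples_moments("total"),
                apim_spec(y_var = "fertiqol_total"))
fit
#> <apim_fit: saturated, n = 180 dyads, chi-square = 0 on 0 df>
#>        path estimate    se std_estimate std_se        p
#>     actor_m   -1.723 0.174       -0.591 0.0488 4.01e-23
#>  partner_mf   -0.286 0.165       -0.104 0.0596 8.29e-02
#>  partner_fm   -0.366 0.175       -0.124 0.0593 3.68e-02
#>     actor_f   -1.638 0.166       -0.588 0.0488 5.19e-23
```

Each additional PHQ-9 point of a man's own depression predicts a 1.72-unit
drop in his total FertiQoL (standardized β ≈ −0.59); his wife's depression
adds a smaller partner effect (β ≈ −0.10). The female equation mirrors
this (actor β ≈ −0.59, partner β ≈ −0.12, the latter significant at
p = 0.037). Are actor and partner effects symmetric across roles?

```r
run_all_equality_tests(infertile_couples_moments("total"),
                       apim_spec(y_var = "fertiqol_total"))
#>         constraint role          scale chi_sq_diff df_diff        p significant
#> 1      actor_equal <NA> unstandardized       0.121       1 7.28e-01       FALSE
#> 2    partner_equal <NA> unstandardized       0.106       1 7.44e-01       FALSE
#> 3 actor_eq_partner    m unstandardized      28.187       1 1.10e-07        TRUE
#> 4 actor_eq_partner    f unstandardized      22.141       1 2.53e-06        TRUE
```

Actor and partner effects are statistically indistinguishable *between*
roles, but *within* each role the actor effect clearly dominates the
partner effect. Raw data work identically — `fit_apim()` takes any wide
table with `depression_male`, `depression_female`, `<outcome>_male`,
`<outcome>_female` columns — and `match_moments()` manufactures raw data
matching any summary exactly, so both routes are interchangeable.

See the vignette (`vignettes/dyadic-apim.Rmd`) for the estimation details,
SE conventions, constraint parameterizations and the simulator's scope.

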