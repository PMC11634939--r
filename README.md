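# cmlrisk

Constrained maximum likelihood (cML) for developing well-calibrated risk
models for binary outcomes.

## The problem

You have a validated base risk model φ(X) on conventional predictors
(think of an absolute breast-cancer risk tool), a candidate new
predictor Z ∈ (0, 1) measured only in a convenience cohort (a biobank,
say), and a target population in which the new model must be calibrated.
The cohort's predictor distribution, outcome prevalence, and even its
outcome model may differ from the target population, so an ordinary
logistic refit transports badly — and the apparent added value of Z is
confounded with that bias.

cML fits the logistic working model

    P(Y=1 | x, z) = expit(β₀ + β_Xᵀ x + β_Z z)

together with a truncated log-normal model for Z | X (log Z normal,
truncated above at 0), by maximizing the observed-data likelihood
**subject to calibration constraints**: within risk intervals
(a_r, b_r] of the base model, the fitted model's average predicted risk
in the target population must stay within a relative tolerance d_r of
the base model's average P^e_r:

    | E_r(θ) − P^e_r | ≤ d_r · P^e_r ,
    E_r(θ) = Σ_{x∈r} δ(x) · E_{Z|x}[ g(β; x, Z) ] / Σ_{x∈r} δ(x) ,

where δ(x) is the known distribution of the conventional predictors in
the target population. The solver returns a verified KKT point; standard
errors come from the active-set projected sandwich covariance
V 𝓘 Vᵀ / N with V = Ξ (Ξᵀ H Ξ)⁻¹ Ξᵀ, where Ξ spans the null space of
the active-constraint Jacobian — constraints that bind at the solution
contribute zero asymptotic variance along their gradients.

The package provides the fitting front end `cml()` (formula interface,
S3 methods `summary`, `coef`, `vcov`, `predict`, `plot`, ...),
calibration diagnostics (`expected_cases()`, `decile_calibration()`,
`calibration_report()`, `oe_adjust()`), a synthetic-data engine for
covariate-shift simulation studies (`scenario_spec()`,
`simulate_cohort()`, `run_replication_study()`), delimited-text
readers/writers, and a small command-line wrapper
(`inst/cli/cmlrisk.R`).

## A worked example

Fit a model on a cohort whose predictor distribution is shifted relative
to the target population (simulation scenario II), constraining to
quartile intervals of a base model with tolerance d = 0.1:

```r
library(cmlrisk)
spec <- scenario_spec("II")          # covariate-shifted source population
set.seed(7)
pop  <- target_population(spec)      # delta(x), known exactly here
base <- fit_base_model(spec, 1e6)    # phi(x): logistic fit on a target draw
dat  <- simulate_cohort(spec, 2000, "source")

fit <- cml(y ~ x1 + x2 + x3 + x4, data = dat, z = "z",
           population = pop, base_model = base, d = 0.1)
summary(fit)
```

```
                estimate    ase      z        p
beta0            -2.4097 0.2039 -11.82 3.12e-32
beta_x1          -0.4373 0.0608  -7.20 6.21e-13
beta_x2           0.3339 0.1101   3.03 2.42e-03
beta_x3           0.4193 0.0977   4.29 1.77e-05
beta_x4           0.7943 0.1234   6.44 1.23e-10
beta_z            0.1095 0.0600   1.82 6.83e-02
...
Calibration by risk interval:
 interval  mass  target model_risk ratio active
        1 0.268 0.04545    0.04999 1.100  upper
        2 0.296 0.07642    0.08072 1.056
        3 0.250 0.11513    0.12000 1.042
        4 0.186 0.19674    0.21642 1.100  upper
```

The constrained intercept (−2.41) sits at the true target value (−2.38)
while the unconstrained fit on the same data gives −2.31 drifting with
the source population; the calibration table shows every interval's
model-averaged risk within the 10% band of its target, with the binding
intervals flagged. `expected_cases(fit, pop)` reports 10,748 expected
cases per 100,000 in the target population against the base model's
10,011 — within the tolerance, as enforced.

`plot(fit)` draws the decile calibration plot (expected vs "observed"
counts derived from the base model), and
`run_replication_study(scenario_spec("II"), n_reps = 200)` reproduces
the full bias/efficiency simulation layout (mean estimate, percent
bias, empirical SE, mean asymptotic SE per parameter and method).

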