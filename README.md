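# t2gwg — Type 2 Gumbel Weibull-G survival distributions

`t2gwg` is an R package for building, fitting and comparing lifetime
distributions from the **exponentiated odds-ratio generator**: given a
baseline cdf `H(x, ψ)` with survival `H̄ = 1 − H`, an outer cdf `R` is
applied to a power of the failure odds,

    F(x) = R( α · [H(x,ψ) / H̄(x,ψ)]^β ),      α, β > 0.

Its main subject is the branch with a Type 2 Gumbel outer transform,
the **T2GWG family**

    F(x) = exp{ −α · [H(x,ψ)/H̄(x,ψ)]^(−β) },

whose hazard can be increasing, decreasing, or bathtub-shaped depending
on the baseline and `(α, β)` — the shape that classical exponential,
gamma and Weibull models cannot express. Three special cases ship
ready-made: exponential (`t2gwe`), uniform (`t2gwu`) and Pareto
(`t2gwp`) baselines; further baselines and outer transforms can be
registered at run time.

The package is aimed at reliability engineers and biostatisticians who
need flexible parametric survival models for *uncensored* lifetime data,
and at methodologists studying the estimators themselves.

## What's inside

* **Distribution surface** — `dt2gwg`, `pt2gwg`, `qt2gwg`, `rt2gwg`,
  hazard `ht2gwg` and reverse hazard `rht2gwg`, all numerically stable in
  both tails (log-space odds, closed-form log-survival, survival-side
  quantiles).
* **Generic generator** — `compose()` pairs any registered outer
  transformer (uniform, Weibull, Lomax, Fréchet, Type 2 Gumbel) with any
  baseline and returns a validated cdf/pdf pair.
* **Analytic properties** — moments, incomplete/conditional moments,
  mgf/cf, Rényi and Shannon entropy (quadrature-first, with divergence
  flags), series-expansion diagnostics, order-statistic densities,
  likelihood-ratio stochastic ordering.
* **Six estimation criteria** — maximum likelihood, least squares,
  weighted least squares, maximum product spacing, Cramér–von Mises and
  Anderson–Darling, each with analytic gradients for the T2GWG families,
  behind one optimizer front-end (`fit()`), plus six comparison families
  (EGT, WGE, LGT, Type 2 Gumbel, Weibull, gamma).
* **Goodness of fit** — `gof_report()` / `compare_models()` with
  −2logL, AIC/BIC/CAIC/HQIC, W, A, K-S + p-value; TTT transform,
  Kaplan–Meier and ECDF diagnostics.
* **Monte Carlo harness** — `run_mc_study()` computes bias and MSE of
  any subset of the six estimators over seeded replications, with Monte
  Carlo standard errors and per-cell reproducibility.
* **I/O and CLI** — `read_lifetimes()`, `make_fixture()`, and a thin
  command-line front-end at `inst/cli/t2gwg.R`
  (`fit | compare | simulate | ttt | fixture`).

Three classic benchmark datasets (Aarset device lifetimes,
Meeker–Escobar running times, Bekker et al. chemotherapy survival times)
are bundled as plain text under `inst/extdata/`.

## Worked example

Fit the uniform-baseline family to the Aarset bathtub data and compare
it with competitors:

```r
library(t2gwg)

aarset <- read_lifetimes(system.file("extdata", "aarset.txt",
                                     package = "t2gwg"))
fit(aarset$values, "t2gwu", "mle", seed = 1)
#> T2GWG fit: family = t2gwu, method = mle
#>   estimates: alpha = 0.755407, beta = 0.261082, gamma = 86
#>   objective at optimum: 163.8498  (n = 50, converged = TRUE)

compare_models(aarset$values, c("t2gwu", "wge", "weibull", "gamma"),
               standard_errors = FALSE, seed = 1)
#>   family  converged params                                   neg2logl aic
#> 1 t2gwu   TRUE      alpha=0.7554, beta=0.2611, gamma=86.0000 327.6995 333.6995
#> 2 wge     TRUE      alpha=0.1741, theta=0.3847, gamma=0.0779 451.2370 457.2370
#> 3 gamma   TRUE      alpha=0.7991, beta=0.0175                480.3804 484.3804
#> 4 weibull TRUE      k=0.9490, lambda=44.9125                 482.0036 486.0036
```

Reading the output: `gamma = 86` is the sample maximum — for this family
the uniform upper bound is a boundary estimate, and with `beta < 1` the
likelihood keeps improving as the bound approaches the largest
observation (see the methods vignette for why reported `-2logL` values
in this regime depend on the stopping rule). The T2GWU family wins the
AIC ranking by ~120 points over the nearest competitor, reflecting the
bathtub hazard the others cannot produce; the TTT diagnostic
(`ttt_scaled(aarset$values)`) shows the tell-tale convex-then-concave
polyline.

A simulation study in one line:

```r
run_mc_study(c(alpha = 2.5, beta = 0.8, gamma = 1.3),
             sample_sizes = c(50, 250, 1000), n_reps = 200,
             methods = c("mle", "mps"), master_seed = 1)
```

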