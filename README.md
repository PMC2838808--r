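# iterid

Iterative identification of nonlinear dynamic biochemical models:
structural identifiability from power-series coefficients, global
parameter ranking, hybrid global–local calibration, Monte-Carlo
practical identifiability, and Fisher-information optimal experimental
design — packaged with the NF-κB regulatory-module ODE model (15
states, 30 parameters) as the built-in case study.

## Who this is for

Modellers of signalling and metabolic pathways who need to know, before
and after fitting, *which* parameters of an ODE model their data can
actually determine, and *which experiment to run next* to determine the
rest.

## The methods in brief

For a control-affine system `dx/dt = f(x, θ) + Σᵢ uᵢ gᵢ(x, θ)` with
discrete observations `y = g(x(tₛ), θ)`:

* **Structural identifiability.** The observables are expanded at
  `t = 0⁺`; the series coefficients are iterated Lie derivatives
  `L_f L_g … h(x₀)` (Taylor series along the single stimulated field,
  generating series over all words in the drift and stimulus fields).
  With `x₀` known, each coefficient is a function of θ alone; full rank
  of `∂s/∂θ` certifies (local) structural identifiability. An
  *identifiability tableau* (binary coefficient-by-parameter dependency
  matrix) is reduced iteratively: single-mark rows pin parameters,
  remaining equation sets are solved from many starts to count solution
  multiplicity (unique / finitely-multiple / unresolved).
* **Global ranking.** Relative sensitivities
  `s_rel = (θⱼ / max(|y|, floor)) ∂y/∂θⱼ` are pooled over Latin-hypercube
  parameter samples into importance factors, e.g.
  `δ_msqr = sqrt(mean(s_rel²))`; insensitive parameters are fixed before
  calibration.
* **Calibration.** Weighted least squares
  `J(θ) = Σ (ỹ − y(θ))² / σ²`, minimised by a scatter-search-style
  global phase plus bounded Levenberg–Marquardt with
  forward-sensitivity Jacobians, in log₁₀ parameter space.
* **Practical identifiability.** Hundreds of seeded noisy
  pseudo-replicates are refitted; the solution cloud is trimmed to its
  [0.05, 0.95] quantile box, normalised, and summarised by a
  principal-axis ellipsoid: expected uncertainties `C_θ`/`C%` per
  parameter, pairwise eccentricities (parameter correlation), and a
  pseudo-volume.
* **Optimal experimental design.** The Fisher information
  `F = Σ (∂y/∂θ)(∂y/∂θ)ᵀ / σ²` of earlier experiments is the prior;
  pulse switch times, duration and sampling times of the next
  experiment are optimised for `max λ_min(F)` (E-optimality) or
  `max det(F)` by a seeded evolutionary search.
* **The loop.** `run_identification_loop()` chains the stages, freezes
  well-estimated parameters (bias < 1%, expected uncertainty < 10%)
  and designs the next experiment until all parameters are resolved.

## Worked example

```r
library(iterid)

nf <- build_nfkb_model()          # model + parameter space (13 free)
theta <- nf$space$nominal

## structural identifiability of the 13 free parameters
x0 <- resting_state(nf$model, theta)
st <- structural_identifiability(nf$model, x0, nf$space,
                                 method = "generating")
st$rank$rank
#> [1] 13                         # full rank: structurally identifiable

## Monte-Carlo practical identifiability of the reference scheme
theta_k <- setdiff(nf$space$free, c("t1", "t2", "e2a"))
cloud <- monte_carlo_cloud(nf$model, nfkb_es1_designs(), nf$space,
                           theta_k, theta_true = theta,
                           n_reps = 60, master_seed = 2026)
print(uncertainty_report(cloud, theta_true = theta))
#> <uncertainty_report> 60 replicates
#>  parameter        mu delta_pct  C_theta C_pct
#>        c3a 3.998e-04      0.04 1.30e-05   3.2
#>        c4a 4.995e-01      0.09 2.35e-02   4.7
#>         c5 2.999e-04      0.05 4.04e-05  13.5
#>         k1 2.655e-03      6.21 1.43e-03  54.0
#>         k2 1.009e-01      0.88 5.06e-02  50.2
#>         k3 1.499e-03      0.06 1.10e-04   7.3
#>      kprod 2.512e-05      0.46 1.20e-05  47.6
#>       kdeg 1.257e-04      0.60 5.78e-05  45.9
#>         i1 2.496e-03      0.15 2.43e-04   9.7
#>        i1a 1.010e-03      1.03 6.86e-05   6.8
#> most correlated pair: kdeg - kprod eccentricity 16.7
#> pseudo-volume: 6.56e-16
```

The table reads: `mu` is the mean of the trimmed cloud of replicate
estimates, `delta_pct` its relative distance to the generating truth,
`C_theta`/`C_pct` the expected maximum uncertainty (half-width of the
[0.05, 0.95] interval). The IKK production and degradation rates
(`kprod`, `kdeg`) compensate each other and form the most correlated
(most eccentric) pair — exactly the pathology the optimal-design step
then targets:

```r
prior <- fisher_information(nf$model, theta, nfkb_es1_designs(), theta_k)
oed <- optimize_design(nf$model, theta, theta_k, prior_fim = prior,
                       criterion = "E",
                       constraints = list(observables =
                         c("NFkBn", "total_IkBa_cyt"),
                         max_pulses = 2, max_samples = 15),
                       seed = 1)
oed$design                        # pulse-wise TNF + 15 optimised samples
```

A thin CLI over the same functions lives in `inst/cli/iterid.R`
(subcommands `calibrate`, `oed`, `loop`; byte-reproducible given
`--seed`).

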