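# ftsratchet

Stochastic simulation and analysis of the Brownian ratchet that couples
septal peptidoglycan (sPG) synthases to treadmilling FtsZ filaments
during bacterial cell division.

FtsZ polymers at the division septum treadmill — subunits leave the
shrinking end and add at the growing end while interior subunits stay
stationary — and sPG synthases such as *E. coli* FtsI move directionally
around the septum at the treadmilling speed, without any motor activity
of their own. The package implements the ratchet explanation: an enzyme
diffusing on the membrane (diffusion constant *D*) binds any filament
subunit through a short-ranged harmonic well (depth *U₀* in k\_BT,
half-width 2.5 nm on a 5 nm subunit lattice) and follows the shrinking
end because each subunit loss deletes the well under the enzyme and
leaves the next one ~5 nm ahead. The enzyme obeys the overdamped
Langevin equation

    λ dx/dt = f(x) + ξ(t),   λ = k_BT / D,   f = −∂U/∂x,

integrated with an exact Ornstein–Uhlenbeck propagator inside wells and
Euler–Maruyama steps outside, while the filament treadmills on a
deterministic clock (one subunit exchanged every L₀/(V_Z Δt) steps).
On top of the simulator sit:

* ensemble analysis: persistent end-tracking classification (100 nm /
  4 s criteria plus drop-event and ride-fraction follow gates),
  propensity phase diagrams over (D, U₀, V_Z), run-length/duration
  curves, bound lifetimes and normalized off-rate (activity) curves,
  binding-potential bracketing against activity data;
* the closed-form ratchet theory: per-step probability
  P = exp(−(τ_Z/τ_D + τ_C/τ_Z)), mean step count, run length
  ⟨L⟩ = L₀ τ_D τ_Z/(τ_Z² + τ_C τ_D), duration ⟨T⟩ = ⟨N⟩ τ_Z, and the
  optimum V_Z\* = L₀/√(τ_C τ_D), with τ_D/τ_C estimated from targeted
  micro-simulations;
* a single-molecule-tracking pipeline (localization filtering, track
  linking, septal-circle fitting, trajectory unwrapping, processive
  segment classification by R = r/d ≤ 0.4, log-normal mixture
  deconvolution of speed distributions, anomalous-diffusion MSD fits);
* synthetic-data generators that emulate every input the pipeline
  consumes, so everything is testable offline.

All user-facing functions take and return tibbles and compose with the
pipe; fitted objects have `tidy()`/`glance()` methods and result types
have `autoplot()` methods.

## A worked example

```r
library(ftsratchet)

p <- ratchet_params(D = 0.04, U0 = 10, v_z = 25, t_max = 30)
traj <- simulate_trajectory(p, seed = 1)
cl <- classify_end_tracking(traj)
cl$runs
#> # A tibble: 4 × 7
#>   t_start t_end duration distance speed ride_fraction persistent
#>     <dbl> <dbl>    <dbl>    <dbl> <dbl>         <dbl> <lgl>
#> 1    0     3.25     3.25     73.3  22.5         0.985 FALSE
#> 2    3.35  8.4      5.05    114.   22.7         0.951 TRUE
#> 3    8.5  22.8     14.3     354.   24.7         0.983 TRUE
#> 4   23.2  23.2      0         0     0           0     FALSE
```

The enzyme rides the shrinking end at close to the treadmilling speed
(25 nm/s), falls off at failed catch-ups (the run boundaries), recatches,
and runs again — up to 14 s and ~350 nm at a stretch: exactly the
stochastic, interrupted processivity the ratchet predicts. The two runs
longer than 4 s are scored persistent. `autoplot(traj)` draws the enzyme between the two
filament-end trajectories. The analytic side of the same physics:

```r
analytic_processivity(seq(10, 100, 10), tau_D = 60, tau_C = 3e-4) |>
  attr("v_opt")
#> [1] 37.2678    # nm/s, the run-length-optimal treadmilling speed
```

A command-line wrapper for batch use ships in
`inst/scripts/ftsratchet` (subcommands `simulate`, `phase-diagram`,
`processivity`, `lifetime`, `fit-potential`, `analytic`, `analyze-smt`,
`make-fixtures`; every output directory gets a `provenance.json`
sidecar sufficient to re-run bit-identically).

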