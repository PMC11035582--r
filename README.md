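# alleeSensor

Simulation and analysis toolkit for an **Allee-effect-based distributed
detection algorithm** in engineered microbial whole-cell sensors.

## The problem and the model

A population of engineered cells is deployed to detect a rare analyte.
Each cell holds a binary vote: state **L** ("analyte absent") or state
**H** ("analyte present"), with densities `L(t) + H(t) = P` (the total
population density; replication and death are neglected). Three reactions
move cells between states:

* **Set / Detect / Error** — an L cell switches to H at the *rare-event
  detection rate* `σ = σ_A·A + σ_err` (true detections at rate `σ_A` per
  unit analyte concentration `A`, plus spurious switching at `σ_err`);
* **Hold** — an L cell switches to H at rate `κ · Hⁿ/(Hⁿ + Kⁿ)`, a
  quorum-sensing-driven positive feedback with Hill kinetics
  (half-activation density `K`, cooperativity `n > 1`);
* **Reset** — an H cell relaxes back to L at rate `ρ`.

The mean-field population dynamics are

```
dH/dt = σ (P − H) + κ · Hⁿ/(Hⁿ + Kⁿ) · (P − H) − ρ H .
```

When `max_{H∈[0,P]} [ κ Hⁿ/(Hⁿ+Kⁿ)(P−H) − ρH ] > 0` the undriven system
(`σ = 0`) is bistable: equilibria at `0`, an unstable threshold `α_i P`,
and a detected state `α_f P` — an engineered Allee effect. As `σ`
increases, the low and middle equilibria approach each other and merge at
the **critical rate `σ_c`** (a saddle-node bifurcation): below `σ_c`,
spurious detections die out; above it, the whole population tips into the
detected state and *stays* there even if the analyte is removed
(hysteresis = memory). The toolkit:

* finds and classifies all equilibria (companion-matrix roots of the
  cleared-denominator polynomial for integer `n`, bracketed scanning
  otherwise) — `find_equilibria()`, `theorem1_condition()`,
  `alpha_bounds()`, `critical_point()`;
* locates `σ_c` by bisection on the equilibrium count, and sweeps it over
  `(κ, ρ)` grids — `binary_search_sigma_c()`, `sweep_sigma_c()`;
* integrates the dynamics under constant or piecewise-constant analyte
  profiles, measuring steady states, 95% convergence times, and analyte
  memory — `integrate_model()`, `steady_state()`, `convergence_time()`,
  `memory_experiment()`;
* compares the algorithm against three alternatives (set-reset,
  broadcasting, distributed amplification through a reporter molecule) —
  `dose_response()`;
* tests false-positive robustness by feeding an exact Gillespie
  birth–death simulation of spurious-detection noise into the
  deterministic dynamics — `simulate_birth_death()`,
  `hybrid_simulation()`, `robustness_ensemble()`.

Default parameters are literature-derived rates for a LuxI/LuxR
quorum-sensing implementation in *E. coli*: `κ = 35 h⁻¹`, `ρ = 14 h⁻¹`,
`n = 4`, `K = 8·10⁷ mL⁻¹`, `P = 1.5·10⁸ mL⁻¹`.

## Worked example

```r
library(alleeSensor)
p <- allee_params()               # LuxI/LuxR literature defaults

theorem1_condition(p)
#> Bistability feasibility: satisfied
#>   max g(H) = 1.05305e+08 mL^-1 h^-1 at H = 7.93018e+07 mL^-1
#>   alpha_i = 0.4367, alpha_f = 0.6148

binary_search_sigma_c(p)
#> Critical detection rate sigma_c = 3.05524 h^-1
#>   bracket [3.05481, 3.05566], 14 iterations, terminated by precision

for (s in c(0, 1.5, 3.04, 4, 5)) {
  ss <- steady_state("allee", p, s)
  tr <- integrate_model("allee", p, s, t_end = 2)
  cat(sprintf("sigma=%.2f  steady=%.3g  t95=%.2f h\n", s,
      as.numeric(ss), if (as.numeric(ss) > 0)
        convergence_time(tr, as.numeric(ss)) else 0))
}
#> sigma=0.00  steady=0         t95=0.00 h
#> sigma=1.50  steady=1.49e+07  t95=0.21 h
#> sigma=3.04  steady=3.58e+07  t95=0.60 h
#> sigma=4.00  steady=1.01e+08  t95=0.43 h
#> sigma=5.00  steady=1.03e+08  t95=0.29 h

robustness_ensemble(p, n_runs = 5, t_end = 100, base_seed = 1)
#> Robustness ensemble: 5 runs x 100 h (beta=0.5, gamma=2)
#>   false-positive rate: 0.000
```

Reading the numbers: the feasibility check certifies bistability and puts
the undriven threshold at `α_i P ≈ 0.65·10⁸ mL⁻¹` and the detected-state
floor at `α_f P ≈ 0.92·10⁸ mL⁻¹`. The saddle-node sits at
`σ_c ≈ 3.055 h⁻¹` (about 22% of the slowest rate constant `ρ`). Constant
rates below `σ_c` settle on low densities (a negative vote), rates above
it on ≈`1.0·10⁸ mL⁻¹` (a positive vote), with 95% convergence times
longest near the bifurcation (critical slowing down). Stochastic
spurious-detection noise (birth rate 0.5 h⁻¹, per-capita death rate
2 h⁻¹) never tips the detector.

## Command line

```sh
Rscript inst/scripts/allee-sensor sigma-c --out sigma_c.json
Rscript inst/scripts/allee-sensor table2 --out table2.csv
Rscript inst/scripts/allee-sensor sweep --nk 64 --nr 64 --out sweep.csv
Rscript inst/scripts/allee-sensor robustness --runs 20 --seed 1 --out rob.json
```

All commands accept `--config params.yaml` (see
`inst/extdata/default_params.yaml`) and embed parameter provenance in
their outputs.

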