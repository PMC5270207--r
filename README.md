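# diatherm

Interface heating in layered tissue phantoms under 1 MHz therapeutic
ultrasound: a simulation and analysis toolkit for the classic bench-top
question of how much extra heat a nearby bone surface drives into the soft
tissue above it — and how much heating the soft-tissue interfaces see even
without bone.

The package models a cylindrical calorimeter: a 10 mm + 20 mm soft-tissue
phantom (optionally backed by a 1 mm synthetic cortical-bone disc) in a
36 °C water bath, insonated by a stationary calibrated therapy head
(4.18 W over 3.36 cm² ERA → 1.24 W cm⁻² effective, continuous, 120 s), with
six thermocouples at the 10 mm and 30 mm interfaces (`TP1`–`TP6`, centre
probes `TP2`/`TP5` on the beam axis).

## What it computes

* **Acoustic field** — normal-incidence, incoherent multiple-reflection
  energy model inside a top-hat beam column: per-layer forward/backward
  fluxes `F, B` with interface reflectance `R = ((Z₂−Z₁)/(Z₂+Z₁))²`,
  transducer-face re-reflection, and heating `q = 2 α_Np I`.
* **Bioheat solver** — perfusion-free Pennes equation
  `ρc ∂T/∂t = ∇·(k∇T) + q` on an axisymmetric finite-volume grid
  (explicit stepping via a small compiled kernel, harmonic-mean
  conductances at material boundaries, Dirichlet 36 °C bath, zero-flux
  transducer face), returning temperature maps and probe time series.
* **Trapped energy** — classical fluid/solid half-space reflectance with
  longitudinal and shear branches
  (`Z_tot = Z_L cos²2θₛ + Z_S sin²2θₛ`), giving the fraction of source
  energy reflected back toward the transducer on first arrival at the bone,
  swept over 0–15° of incidence.
* **Synthetic experiment + inference** — seeded Gaussian endpoint
  measurements matching the reported per-arm summaries (n = 20 each), and
  the arm comparison: Lilliefors normality screen, pooled t with 95 % CI,
  Mann–Whitney U with exact small-sample p, prospective sample size.

## Worked example

```r
library(diatherm)

# heat the with-bone phantom for 120 s and read the thermocouples
sim <- simulate_heating(phantom_stack(bone = TRUE))
probe_endpoints(sim)
#>   probe temp_c
#> 1 TP1     38.7
#> 2 TP2     41.5
#> 3 TP3     38.7
#> 4 TP4     40.0
#> 5 TP5     43.6
#> 6 TP6     40.0
```

The bone arm heats everywhere above the no-bone arm (whose central probes
reach 39.6 °C at 10 mm and 37.4 °C at 30 mm): reverberation between bone
and transducer raises the shallow interface, and absorption in the disc
heats the deep one. `autoplot(sim)` and `autoplot(sim$field)` draw the
probe series and the (r, z) temperature map.

```r
# how much energy shuttles between transducer and bone?
trapped_sweep()
#> <trapped-energy sweep: 31 angles, 0.0-15.0 deg>
#>   trapped fraction 17.4% to 18.4%
```

About 17–18 % of the emitted energy returns from the bone on first arrival
across clinically plausible incidence angles — inside the 12–45 %
reverberation band documented for this geometry.

```r
# the one thermocouple whose arms are statistically indistinguishable
pooled_t_from_summaries(42.01, 0.47, 20, 42.37, 0.96, 20)
#>     method estimate statistic df p_value conf_low conf_high
#> 1 pooled t    -0.36     -1.51 38    0.14   -0.844     0.124
```

The central 10 mm thermocouple (TP2) differs by only −0.36 °C between arms
(t(38) = −1.51, p = 0.14, CI spanning zero), while every other probe
separates decisively — run `compare_arms()` on
`simulate_measurements(calorimeter_summaries(), seed = 1)` to see the full
table with the normality-gated choice between t and U.

`run_study(run_config())` executes both arms, the sweep, the generator and
the comparison in one call and writes every artifact (delimited text plus
the verbatim YAML config) to an output directory.

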