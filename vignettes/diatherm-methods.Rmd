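---
title: "Interface heating under therapeutic ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface heating under therapeutic ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diatherm)
```

## The problem

Physiotherapeutic ultrasound deposits heat wherever tissue absorbs the beam,
and layer interfaces complicate the deposition pattern: impedance mismatch
reflects energy, a nearby bone surface reverberates it back through the soft
tissue, and mode conversion in the bone strengthens absorption there.
`diatherm` models the canonical bench-top version of this situation — a
cylindrical calorimeter holding a 10 mm + 20 mm soft-tissue phantom, with or
without a 1 mm synthetic cortical-bone disc behind it, immersed in a 36 °C
water bath and insonated by a stationary 1 MHz therapy head (4.18 W over an
ERA of 3.36 cm², i.e. 1.24 W cm⁻² effective intensity, continuous mode,
120 s) — and the analysis of the endpoint temperatures recorded by six
type-K thermocouples: three at the 10 mm interface and three at the 30 mm
interface, 10 mm apart laterally, the centre one of each triplet on the
beam axis (`TP2`, `TP5`).

Everything is driven by the constants in `builtin_material()` and
`transducer_spec()`; there is no external data.

## The acoustic model

The beam is a uniform top-hat column of radius $\sqrt{\mathrm{ERA}/\pi}
\approx 10.34$ mm carrying the effective intensity $I_0 = P/\mathrm{ERA}$.
Within the column the package solves a normal-incidence, *incoherent*
(energy) multiple-reflection balance for the layered stack: each layer $j$
attenuates one-way intensity by $a_j = e^{-\mu_j d_j}$ with $\mu_j =
2\alpha_j^{\mathrm{Np}}$, each interface reflects the energy fraction
$R = \left((Z_2 - Z_1)/(Z_2 + Z_1)\right)^2$, and the transducer face
re-reflects returning energy with reflectance 1 by default (the face
impedance is not characterised; the parameter is exposed).  The
forward/backward fluxes per layer solve a small linear system whose solution
equals the summed geometric series of all reflected passes — the test suite
checks this against an explicit 1000-pass summation to $10^{-10}$ relative.
Absorption converts intensity to volumetric heating as $q = 2\alpha^{\mathrm
{Np}} I$.

Two deliberate simplifications, both visible in the results:

* **Incoherent summation.** Phase is discarded, so sub-wavelength
  standing-wave ripple and plate resonances of the 1 mm bone disc do not
  modulate the deposition.  The coherent plate reflectance is available
  separately (`plate_reflectance()`, ≈ 0.53 at normal incidence vs ≈ 0.26
  for the half-space) for sensitivity checks.
* **Top-hat beam.** The calibrated BNR (3.91) is recorded but not used to
  shape a hotspot; the model targets the mean deposition, not peak
  non-uniformity.

## The thermal model

Temperature evolves by the perfusion-free Pennes equation
$\rho c\,\partial T/\partial t = \nabla\!\cdot\!(k \nabla T) + q$ on an
axisymmetric $(r, z)$ grid — the calorimeter is a cylinder, so axisymmetry
is the natural reduction even though a planar 2-D section would be an
equally defensible reading of the original set-up.  The solver is a
cell-centred finite-volume scheme with harmonic-mean conductances across
material interfaces (grid faces are aligned with the layer boundaries, so
every cell is a single medium), explicit forward-Euler stepping with the
time step auto-computed from the assembled operator with a 0.9 safety
factor, and these boundaries:

* outer radius (32.5 mm, the ring's internal radius) and distal $z$:
  Dirichlet 36 °C (the stirred bath; convective enhancement at exposed
  faces is deliberately omitted),
* transducer face ($z = 0$): zero flux (transducer self-heating is an
  experimental artifact, not part of the model),
* initial condition 36 °C everywhere.

Defaults are $dr = dz = 0.5$ mm with local axial refinement to 0.1 mm
inside the bone disc, a 10 mm water margin behind the stack, and 1 s probe
sampling.  A 120 s with-bone run takes a few thousand steps on a
65 × 90-cell grid (well under a second with the compiled kernel); halving
$dr$ and $dz$ moves the central-probe endpoints by under 0.001 °C, far
inside the 0.1 °C convergence target the tests assert.  Probes are ideal
points: readings interpolate bilinearly between cell centres, except that a
probe lying exactly on a material-boundary face uses the conduction-weighted
face temperature (the consistent estimate where the gradient jumps), and
radii inside the first cell centre take the axis cell value by even
symmetry.  The endpoint is the series maximum, which equals the final value
while the source is on.

A pure-R single-step reference (`bioheat_step()`) performs the identical
update and is compared against the compiled kernel in the tests; it also
enforces the stability bound with an informative refusal.

## Trapped energy at the bone

The reverberation bookkeeping asks: of the energy leaving the transducer,
what fraction returns from the bone surface on first arrival instead of
entering the bone?  At incidence angle $\theta$ the tissue/bone interface is
treated as a fluid/solid half-space: Snell's law gives the longitudinal and
shear branch angles, $Z_i = \rho c_i / \cos\theta_i$, the solid's combined
normal impedance is $Z_{\mathrm{tot}} = Z_L \cos^2 2\theta_s + Z_S \sin^2
2\theta_s$, and the energy reflectance is $\left|(Z_{\mathrm{tot}} -
Z_f)/(Z_{\mathrm{tot}} + Z_f)\right|^2$, with transmitted energy
partitioned between the branches in proportion to their contributions to
$Z_{\mathrm{tot}}$ and each branch going dark past its critical angle.  The
trapped fraction multiplies this by the one-way tissue-path attenuation at
that obliquity ($30\,\mathrm{mm}/\cos\theta$ of tissue).  Both choices the
original description leaves open are exposed as flags rather than baked in:
`include_path_attenuation` and the transducer-face reflectance (which only
enters the alternative `"multibounce"` residence definition).

The half-space reading of the bone is the default deliberately: the
coherent 1 mm-plate reflectance at normal incidence (≈ 0.53) would push the
trapped fraction outside the documented 12–45 % reverberation band, while
the half-space value (≈ 0.26, giving ≈ 17–18 % after path loss across the
0–15° sweep) sits inside it.  The plate variant remains available via
`bone_model = "plate"`.

The bone shear speed is not characterised; the default 1462 m s⁻¹ (half the
longitudinal speed, typical of cortical-bone mimics) is flagged `assumed`
in the material record and only affects this module.  Likewise the water
constants (density 994, speed 1523, attenuation 0.0022 dB cm⁻¹ MHz⁻¹,
c_p 4178, k 0.62 near 36 °C) are literature defaults, overridable through
`material()` or the YAML config.  One recorded override: the bone density
is documented as “1700.59 g cm⁻³” in the characterisation, a physically
impossible unit for synthetic cortical bone; the registry reads it as
1700.59 kg m⁻³.

## The synthetic experiment

`simulate_measurements()` stands in for the laboratory endpoint data: each
thermocouple's 20 endpoint temperatures per arm are independent Gaussian
draws with the arm's reported mean and SD (`calorimeter_summaries()`),
deterministic for a fixed seed.  The Gaussian form matches the downstream
analysis (t tests after a normality screen); no cross-thermocouple
correlation is modelled because no covariance information exists — a real
calorimeter run would correlate probes through shared bath and transducer
drift, so passing tests certify the statistics pipeline, not the lab.
Under the generating parameters the probability that every with-bone sample
mean exceeds its without-bone counterpart is ≈ 0.93 in closed form
(dominated by the nearly-overlapping TP2 arms), and the tests check the
empirical proportion against exactly that number rather than a folklore
threshold.

## Inference

* **Pooled t** (`pooled_t_test()`, `pooled_t_from_summaries()`): pooled
  variance, $df = n_a + n_b - 2$, two-sided p, 95 % CI from the pooled
  standard error — the variant identified by a reported $t(38)$ at
  $n = 20 + 20$.  The summary-statistics path reproduces the reported TP2
  comparison ($t(38) = -1.52$, CI $(-0.85, 0.12)$) to within the rounding
  of the published means and SDs.
* **Mann–Whitney U** (`mann_whitney_u()`): U of the first sample from
  midranks; exact two-sided p from the null distribution for tie-free
  samples up to $n_x n_y \le 400$, complete enumeration of assignments when
  ties are present and $\binom{n}{n_x} \le 2\times10^5$, tie- and
  continuity-corrected normal approximation otherwise.
* **Normality screen** (`ks_normality()`): KS distance against the
  sample-fitted normal with the Lilliefors p value, since the parameters
  are estimated (the plain KS p is available but anti-conservative);
  zero-SD samples are flagged degenerate with distance 1.
* **Decision rule** (`compare_arms()`): the published analysis used
  “t, or U when appropriate” without stating the criterion; here it is
  operationalised as *U whenever either arm fails the Lilliefors screen at
  α = 0.05*, with no multiplicity correction (matching the original
  analysis).  The published U values themselves are not comparison targets:
  their convention is unstated and the raw data unavailable.
* **Sample size** (`required_sample_size()`): noncentral-t iteration via
  `power.t.test`; with α = 0.05, power 0.80, δ = σ = 0.5 this gives 17 per
  group (normal approximation 15.7 → 16).  The study that motivated these
  planning values enrolled 20 per group; the extra margin is consistent
  with rounding-up practice but not derivable from the stated inputs, so
  the package reports the calculation, not the 20.

## Known limitations

* The incoherent plane-wave energy model bounds what the thermal solver can
  reproduce at the bone.  The full-wave finite-element benchmark values
  shipped in `reference_endpoints()` reach 61.15 °C at the with-bone
  central distal probe; an energy-conserving layered model with the
  characterised longitudinal bone attenuation (13 % absorption per pass
  through the 1 mm disc) deposits roughly 1.4 kW m⁻² at that interface —
  an order of magnitude less than the ≈ 12.7 kW m⁻² (essentially the whole
  beam) that a +25 K interface rise in 120 s implies.  The package's
  with-bone TP5 lands in the low 40s °C, between the bench measurement
  (39.23 °C) and the full-wave benchmark; the without-bone probes and all
  qualitative patterns (bone-arm dominance, lateral symmetry, broader
  heated region) agree with the benchmark.  Closing the gap would need
  shear-wave absorption in the bone via full mode-conversion propagation,
  which is out of scope here.
* No diffraction or near-field structure, no nonlinear propagation, no
  cavitation, no perfusion, no transducer self-heating or thermocouple
  viscous-heating artifacts, no moving-transducer protocols.
* Pulsed modes are represented only by duty-cycle scaling of the source
  intensity.

## Reproducibility notes

Every stochastic element (only the synthetic measurements) takes an
explicit integer seed; simulations, sweeps and exports are deterministic
and byte-stable.  `run_study()` executes both arms, the sweep, the
generator and the comparison under one `run_config()` and writes every
artifact plus the verbatim config to an output directory.

```{r example, eval = FALSE}
st <- run_study(run_config(seed = 1L), outdir = "study_out")
st$report
```
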