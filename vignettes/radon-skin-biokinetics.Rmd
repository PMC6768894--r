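---
title: "Methods: the radon skin-uptake biokinetic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the radon skin-uptake biokinetic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radonskin)
```

## The model and its assumptions

`radonskin` simulates the transfer of radon from thermal bath water through
the skin into blood, organs and exhaled breath as a linear, time-varying
compartment system `dQ/dt = A(t) Q + b(t)`, with one activity `Q` (Bq) per
compartment. The compartments are the respiratory-tract (RT) air, the
non-pulmonary arterial and venous blood pools, two skin chains, and a table
of organ/tissue compartments (two fat pools, two bone pools, glandular and
adipose breast, kidneys, liver, red marrow and a lumped remainder).

Key physiological assumptions, inherited from the noble-gas circulation
models this structure follows:

* RT air and pulmonary blood equilibrate instantaneously via the blood–air
  partition coefficient `P_BA`; arterial and venous pools therefore
  represent the non-pulmonary blood.
* Each tissue exchanges with blood as a single well-mixed pool:
  uptake at `F_i/V_BA` from arterial blood, return at `F_i/(P_i V_i)` to
  venous blood.
* The arterial and venous blood balance equations are not independent
  inputs; they are closed by mass conservation from the printed transfer
  coefficients. This closure is verified structurally: with decay and
  environment couplings switched off, every column of `A` sums to zero and
  total activity is conserved (the property suite checks this to 1e-8
  relative; it achieves round-off level).
* Breathing is folded into a continuous exchange coefficient `λ_E`
  (default 2600 d⁻¹, sitting awake), scaled per subject by the ratio of the
  measured respiratory minute volume to the reference value (390 l h⁻¹
  female, 540 l h⁻¹ male). Discrete bag-sampling losses and dead-space
  re-breathing are not modelled; both remove or add only a few percent of
  the RT-air activity per breath.

### The skin sub-model

The skin is a two-layer chain: a dermal compartment (DS; low perfusion, low
fat; the stratum corneum is the rate-limiting diffusion barrier) feeding a
subcutaneous compartment (SS; adipose hypodermis, identified with the
second, slowly perfused fat pool of the circulation backbone; it holds the
main skin-to-blood pathway). Both layers are split into a water-exposed and
an air-exposed chain (default 90 %/10 %, head and shoulders staying above
water), with volumes and blood flows divided in proportion to surface area.
Whether the subcutaneous layer should be split at all is not observable from
exhalation data; we split both layers for structural symmetry, which also
keeps the air-exposed skin path present in every phase with no special-case
code. Radon uptake from room air into the non-exposed dermal chain during
bathing is retained even though it is negligible (~100 Bq m⁻³ against
~9×10⁵ Bq m⁻³ in water).

The exposed dermal chain takes up radon from water with flux
`K·A·C_W` and releases it at `K·A/(P_SW·V_DS)`; dry skin (the non-exposed
chain always, the exposed chain during rest) exchanges with room air through
`kappa_dry · K0` against the skin–air partition `P_SA`.

## Parameters, defaults, and why

All defaults ship in `inst/extdata/reference_female_synthetic.yaml` with a
provenance string per value; `load_parameters()` overlays user YAML/JSON on
these defaults and tracks overrides as `"user"`.

| parameter | default | unit | provenance |
|---|---|---|---|
| baseline permeability `K0` | 2.4e-7 | m s⁻¹ | paper |
| skin–water partition `P_SW` | 0.4 | – | paper |
| DS–blood / SS–blood partitions | 0.4 / 11.0 | – | paper |
| DS / SS volumes | 1.84 / 9.35 | l | paper |
| reference skin area | 1.66 | m² | paper |
| immersed fraction | 0.9 | – | paper |
| `k_DS` | 0.18 | h⁻¹ | paper |
| skin flow fractions (DS/SS) | 0.007 / 0.060 | of cardiac output | paper |
| dead space `V_D` | 0.110 | l | paper |
| `λ_E` reference | 2600 | d⁻¹ | paper |
| dry-skin multiplier `kappa_dry` | 4.0 | – | assumption |
| skin–air partition `P_SA` | 0.4 | – | assumption |

Two values deserve comment because no published number exists:

* **`kappa_dry`.** The source model's permeability refers to wet skin;
  diffusion through the air-filled crevices of dry skin is faster, and the
  resting-phase decline of measured exhalation curves requires an elevated
  value. We default to 4.0 — the same factor the temperature ramp reaches —
  which keeps the resting decline strictly exponential-like in the property
  suite; it is a configurable model choice, not a measured constant.
* **`P_SA`.** No skin–air partition value is published; we set it equal to
  the skin–water partition and flag it in the config schema. It only
  affects the small dry-skin exchange terms.

The circulation backbone (cardiac output 354 l h⁻¹, arterial/venous pool
volumes 1.0/2.4 l, `P_BA` 0.43, per-tissue flow fractions, partitions and
volumes) is a *synthetic reference configuration*: representative
adult-female values assembled from standard physiology and radon solubility
data, labelled `reference-config`, and freely overridable. Every package
test depends only on whatever configuration is loaded, never on hard-coded
copies. The printed skin-model values above are what the study contributes;
the backbone only needs to be physiologically reasonable for the structural
properties (conservation, partition equilibria, fat-buffered retention) to
be meaningful.

Female-adult values are used for all reference simulations; the male
respiratory references (V_RT 3.858 l, RMV 540 l h⁻¹) are selected by the
subject's gender flag.

### Units

Internally: time in hours, volumes in litres, activities in Bq, source
concentrations in Bq m⁻³. `K` is stored in m s⁻¹ and converted once at
matrix-build time: `K·A·C_W` × 3600 gives Bq h⁻¹ directly, and the
back-transfer coefficient picks up the additional 1000 l m⁻³. This keeps
the published mixed units intact at the interface while the ODE lives in
one coherent system.

## The modulation schedule

During immersion, warm water (37–40 °C) dilates skin vessels and opens
pores. Both the permeability and the skin blood flows are multiplied by a
ramp rising linearly from 1 to 4 over the first 10 minutes and holding at 4
afterwards. In saturation-type subjects the permeability multiplier (not
the blood flow) then declines linearly by a factor 2.5 between 12.5 and
20 minutes — swelling of the stratum corneum — and stays at the reduced
value afterwards; for 30-minute baths the endpoints stay at 12.5→20 min,
since the calibration protocol was a 20-minute bath. The
dermal–subcutaneous transfer coefficient follows the permeability
multiplier with about 20 % strength; we read "about 20 %" as the affine
form `m_k = 1 + 0.2 (m_K − 1)`, the simplest function that is 1 at baseline
and tracks the full schedule including swelling. Pre-heating in radon-free
warm water is represented as a flag that starts the ramp saturated, rather
than as an explicit radon-free bath phase — only the modulation state, not
the water's radon content, carries over.

A genuinely open point is whether the published permeability value, which
already folds in temperature and swelling effects, should be the ramp's
baseline or its plateau. We treat it as the baseline multiplied by the
ramp, matching the stated fitting procedure; users who prefer the other
reading can divide `K0` by the ramp factor.

## Numerical choices

* **Integration.** `deSolve::lsoda` (stiff-capable; the kidney compartment
  has a ~10 s time constant against multi-hour fat kinetics), relative
  tolerance 1e-8, absolute tolerance 1e-12 Bq. Each phase is integrated
  separately so source discontinuities at phase boundaries are never
  smoothed, and bath phases are further split at the modulation breakpoints
  (10, 12.5, 20 min), inside which every matrix entry is exactly affine in
  time — the solver sees smooth coefficients everywhere.
* **Oracle.** `matrix_exponential_solution()` propagates the affine system
  exactly over a frozen step via the augmented-matrix exponential
  (`Matrix::expm`); `oracle_trajectory()` chains midpoint-frozen steps
  (default 0.05 min) into an independent reference solution. The property
  suite requires agreement with the adaptive solver within 1e-5 relative on
  the standard 20+20 min scenario.
* **Degenerate inputs.** An immersed fraction of 1 removes the air-exposed
  chains entirely (no zero-volume compartments); zero-duration scenarios
  return the initial state; a singular steady-state system raises an error.
  Solver-level negative round-off (below 1e-6 Bq) is clamped to zero.
* **Fitting.** The one-parameter fit is a bounded golden-section search on
  `log k` over [0.05, 20] (tolerance 1e-4 on the log scale); the optional
  two-parameter fit is a Nelder–Mead simplex started from the
  one-parameter solution and never accepted unless it improves the
  objective. The objective is unweighted least squares on the linear
  concentration scale (measurement CVs are roughly constant at 5–15 %; a
  relative-error option exists). Skin blood-flow scaling is deliberately
  not fittable: exhalation curves confound permeability and flow, so the
  flow follows the modulation schedule only.

## The synthetic-data generator

`generate_exhalation_series()` emulates the measurement protocol: one bag
sample every 4 minutes starting 2 minutes into each phase (the published
protocol states only "approximately 4 min intervals"; the exact times are a
convention and fully configurable), multiplicative lognormal noise with
unit mean and CV 5–15 % (default 0.10) truncated at ±4 SD, and optional
dead-space dilution by `(V_T − V_D)/V_T` for raw "as-measured" series. An
additive-Gaussian noise option exists for sensitivity checks.
`generate_subject()` samples anthropometry uniformly within the per-gender
ranges of the shipped subject table and recomputes BSA (Mosteller) and RMV
so the profile invariants hold by construction.

What the generator does **not** emulate: counting statistics of the
scintillation measurement, bag handling and pressure corrections,
intra-session drifts of breathing patterns, or the radon depletion of the
bath water over a session (a few percent). Passing recovery tests therefore
show that the estimation machinery is self-consistent under the stated
noise model — not that real measured curves are free of systematic effects
the noise model omits.

## Problem sizes used by the tests

The shipped test-suite and acceptance script run at desk scale: the
standard 40-minute scenario on a 0.5–2 min output grid (16 compartments),
the 128.5 h inhalation-validation scenario on a 10-min grid, oracle
comparison at 0.05-min frozen steps, a 300-replicate noise-calibration
ensemble on a shortened 16-minute protocol, and a 50-replicate recovery
study at 10 % noise. These sizes were chosen so each property is checked
well inside its stated tolerance; all thresholds (conservation 1e-8, oracle
1e-5, recovery 1 % noise-free / 10 % median under noise) are met with wide
margins at these sizes.

## Known limitations

* Radon progeny are ignored entirely (no in-growth in compartments, no
  skin-deposition dosimetry), and no absorbed-dose quantities are computed.
* The circulation backbone is a labelled synthetic stand-in, not a verbatim
  transcription of the cited reference model; quantitative organ-level
  predictions should be read with that in mind, while the skin-uptake layer
  and all printed-table analyses are exact to their sources.
* Modulation endpoints are fixed calendar times within the bath; subjects
  whose temperature or swelling kinetics differ in timing (not just
  amplitude) are outside the default schedule, though every breakpoint is
  configurable.
* The identifiability caveat is structural: permeability and skin blood
  flow cannot be separated from exhalation data alone, and the package
  refuses to pretend otherwise.
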