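---
title: "Modelling and fitting stimulated dopamine FSCV transients"
author: "fscvfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and fitting stimulated dopamine FSCV transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fscvfit)
```

## The model and its assumptions

`fscvfit` simulates the dopamine transient evoked in the dorsal striatum by
burst stimulation of midbrain dopaminergic neurons, as it appears to a
carbon-fiber FSCV electrode, and fits that model back to recordings. Three
coupled ODE states are tracked (all concentrations in uM, time in s):

* **Striatal dopamine `[DA]_S`** — fed at rate `DAP * I * f * L` while the
  stimulus envelope is on, drained by Michaelis–Menten DAT reuptake
  `Vm * [DA]_S / ([DA]_S + Km)`. Release is a *continuous* rate over the
  burst, not a train of per-pulse deltas: with 50 Hz pulses and a reuptake
  time scale of hundreds of milliseconds, the per-pulse ripple is far below
  the acquisition resolution, and the continuous form is what the rate
  equation states.
* **Electrode dopamine `[DA]_E`** — the observable. The slow temporal
  response of carbon-fiber electrodes is modelled as first-order transfer
  into (`kS`) and away from (`kE`) the electrode, plus return of desorbed
  dopamine at rate `kGamma`.
* **Adsorbed dopamine `Gamma_DA`** — reversible binding to the carbon
  surface: adsorption `k1ads * [DA]_E`, desorption `k2ads * [DA]_E *
  Gamma_DA + k3ads * Gamma_DA`. The bilinear desorption term couples
  desorption to the solution concentration; it is implemented exactly in
  that form, without reinterpretation as a saturating isotherm.

Assumptions worth keeping in mind: the initial state is zero (FSCV traces
are background-subtracted, so a standing dopamine baseline is deliberately
out of scope); reuptake never reverses; the electrode operates in calibrated
concentration units, so no voltammogram synthesis, calibration curve or
background subtraction is modelled; and stimulation is strictly
non-overlapping bursts.

## Parameters, units, defaults

| parameter | units    | default | role |
|-----------|----------|---------|------|
| `DAP`     | uM/mA    | free    | dopamine released per pulse per unit current |
| `Vm`      | uM/s     | free    | maximal DAT reuptake velocity |
| `Km`      | uM       | 0.2     | DAT affinity constant |
| `L`       | –        | 1.0     | dead-space loss factor, in (0, 1] |
| `kS`      | 1/s      | 5       | striatum-to-electrode transfer |
| `kE`      | 1/s      | 5       | transfer away from the electrode |
| `kGamma`  | 1/s      | 1       | desorbed dopamine re-entering the signal |
| `k1ads`   | 1/s      | 0.1     | adsorption rate |
| `k2ads`   | 1/(uM s) | 0.05    | concentration-dependent desorption rate |
| `k3ads`   | 1/s      | 0.1     | first-order desorption rate |

`Vm` and `DAP` carry the biology and are free by default; the presets
`wt_params()` (`Vm` = 7.4 uM/s, `DAP` = 0.67 uM/mA) and `ko_params()`
(`Vm` = 2.0 uM/s, `DAP` = 0.31 uM/mA) hold the fitted values reported for
wild-type and auxilin-knockout mice.

The remaining defaults are declared implementation choices, not measured
values: `Km = 0.2` uM is the standard striatal DAT affinity scale; `L = 1`
because simulation and fitting share whatever value is chosen, so it cancels
from every self-consistent recovery analysis (any `L < 1` merely rescales
`DAP`); `kS = kE = 5` 1/s gives the ~0.1–0.2 s electrode lag typical of
carbon fibers while keeping unit pass-through gain (`kS/kE = 1`); the
adsorption rates are kept small so adsorption distorts the tail without
dominating it. `kGamma` is stated only as "= 1" in the source model; its
dimensional status is ambiguous, and it is implemented as a rate constant of
1 1/s (with value 1 the two readings are numerically identical). All
defaults are overridable through `kinetic_params()` or the config files, and
every fit records which values it used.

Units are fixed package-wide (s, uM, mA, Hz). Config readers reject unknown
keys — including unit-suffixed keys they do not recognise — rather than
converting silently.

## Stimulus envelope and integrator

The burst envelope is a sum of Heaviside windows; `stimulus_envelope()` uses
the closed convention `theta(0) = 1`, so both window endpoints count as
inside the burst. For a 30-pulse, 50 Hz burst the window is exactly 0.6 s.

Integration is fixed-step classical RK4 at `dt = 1e-3` s. The source term is
piecewise constant, so the only discontinuities are at burst boundaries;
those are required to fall on grid nodes, and within each step the source is
sampled at the step midpoint. Two consequences: the injected mass over a
burst is *exactly* `DAP * I * f * L * NP / f`, and the boundary convention
has no effect on the integral (it matters only for direct envelope queries).
A fixed-step deterministic scheme was chosen over an adaptive library solver
because fits must be bitwise reproducible and the scheme must be checkable
against an independent fine-step Euler oracle — the test suite holds the two
to below 1e-3 uM sup-norm disagreement on the observable. A diverging
integration (e.g. rate constants far above 1/dt) is reported as an error
naming the first non-finite time point rather than returned as garbage.

`sample_recording()` maps the simulation onto the acquisition grid by
nearest-node selection. The default acquisition rate is 10 Hz, a typical
FSCV scan-repetition rate (the source recordings do not state theirs), and
the default trace is 12 s with the burst at 2 s — long enough for the KO
transient to decay well past half-peak.

## Trace metrics

* **Baseline** is the mean of all pre-onset samples (traces are assumed
  background-subtracted, so this is typically ~0 plus noise).
* **Peak amplitude** is the maximum baseline-subtracted signal at or after
  onset, earliest sample winning ties.
* **Clearance half-time `t1/2`** is the time from the peak until the signal
  *first* falls to 50% of the peak above baseline, with linear interpolation
  between the two bracketing samples. First crossing, because noise can
  cause re-crossings and "time to clear half the dopamine" reads as the
  first attainment; interpolation, because at 10 Hz the grid-snap error
  (up to 0.1 s) would exceed the genotype effect of interest. A signal that
  never reaches half-peak is reported as an error (NA in `trace_metrics()`),
  never silently clipped. No smoothing is applied before the metric; a
  smoothed variant would be a caller-side preprocessing decision.
* **R-squared** is `1 - SS_res/SS_tot` about the observed mean.
* **`welch_t()`** wraps the unequal-variance t test for group comparisons of
  per-animal metrics.

`t1/2` is invariant under additive shifts and positive rescaling of the
whole trace, and the peak amplitude under additive shifts — both are tested
as properties.

## Fitting

`fit_trace()` minimises the unweighted residual sum of squares between a
recording and the model observable on the recording's grid, over the free
parameters only, inside box bounds (`Vm` in [0.01, 50] uM/s, `DAP` in
[0.001, 10] uM/mA by default), using Levenberg–Marquardt on the residual
vector (`minpack.lm::nls.lm`). The start is the supplied vector or the
geometric midpoint of the bounds; there are no randomised restarts, so a fit
is a pure function of its inputs. The problem is smooth and two-dimensional
by default, and single-start LM recovers noise-free truth to well below 1%
across the tested (Vm, DAP) grid. Residuals are unweighted because no noise
model is stated for averaged FSCV traces. Non-convergence is returned as a
diagnosed result (`converged = FALSE`), not an exception.

Only `Vm` and `DAP` are free by default, mirroring the claim that the
genotype contrast is explained by those two parameters; any other free set
must be requested explicitly, and `compare_genotypes()` refuses to compare
fits whose *fixed* parameters differ. Whether the original analysis also
adjusted nominally fixed parameters between genotypes is unstated; the
default assumes it did not. No uncertainty quantification is attempted —
the reported quantities are point fits.

## The synthetic-data generator

`generate_recording()` adds i.i.d. zero-mean Gaussian noise to the sampled
observable; `generate_cohort()` draws each animal's free parameters
log-normally with median `mean_params` and coefficient of variation
`between_animal_cv` (log-normal keeps rates positive; `sdlog =
sqrt(log(1 + cv^2))`, so the *median* equals the cohort parameter and the CV
is exact). Per-animal seeds are derived from the cohort seed by the fixed
mix `(seed * 69069 + index * 1234567) mod 2147483647`, so enlarging a cohort
never reshuffles existing animals. The default study conditions mirror the
source experiment: 4 WT and 5 KO animals, the published parameter medians,
10% between-animal CV, and measurement noise of a few percent of the WT
peak.

What the generator emulates: the rising-then-decaying uM-scale transient,
slow electrode distortion, additive measurement noise, and between-animal
parameter spread. What it does not: electrode drift, pH transients,
non-dopamine faradaic interferents, correlated noise, or model mismatch —
the synthetic truth *is* the fitted model. Passing recovery tests therefore
demonstrate that the pipeline is self-consistent and identifiable at
realistic noise, not that the model is correct for any particular real
recording.

## The experiment pipeline

`run_experiment()` ties the stages together: generate both cohorts (cohort
seeds `mix_seed(seed, 1)` and `mix_seed(seed, 2)`), average per genotype,
fit each average, and report the genotype comparison, per-animal metrics and
a Welch test on clearance half-times, optionally writing every artefact
(recordings, manifest, fits, comparison, metrics, log) to an output
directory. Reruns with the same config are byte-identical; timestamps are
confined to the log, which also records every seed, the config checksum and
the integrator settings, so no numeric used in a run is hidden. One
degenerate case is handled explicitly: a noise-free null experiment produces
identical half-times in both groups, where the Welch statistic is undefined;
the pipeline reports t = 0, p = 1 for that case instead of failing.

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script run on 12 s traces at `dt =
1e-3` (12,001 nodes), sampled to 121 points at 10 Hz; a fit takes a few tens
of model evaluations. Conservation and adsorption steady-state checks are
held to 0.1%; noise-free recovery to 1%; cohort-average recovery at 10% CV
to 5%; the RK4/Euler cross-check to 1e-3 uM. Concentrations are accepted
down to -1e-9 uM to absorb integrator round-off.

## Known limitations

* Single-recording fits only; hierarchical (per-animal joint) fitting is out
  of scope, matching the averaged-trace analysis it reproduces.
* `Km` and the electrode constants are not identifiable from a single
  transient alongside `Vm` and `DAP`; freeing them is allowed but the onus
  of identifiability is on the caller.
* The continuous-release approximation and zero baseline make the model
  inappropriate for tonic-firing or non-background-subtracted data.
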