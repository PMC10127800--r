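# fscvfit

Kinetic modelling and fitting of electrically evoked dopamine transients
measured by in vivo fast-scan cyclic voltammetry (FSCV).

## The problem

Burst stimulation of midbrain dopaminergic neurons evokes a transient rise of
extracellular dopamine in the dorsal striatum, recorded sub-second at a
carbon-fiber microelectrode. The shape of that transient carries two
physiological quantities: how much dopamine is released per stimulus pulse,
and how fast the dopamine transporter (DAT) clears it again. Genotypes with
impaired synaptic-vesicle recycling (e.g. auxilin/DNAJC6 knockouts, a model of
early-onset parkinsonism) show visibly wider transients; disentangling whether
that reflects reduced reuptake, reduced release, or both requires fitting a
kinetic model rather than eyeballing the trace.

`fscvfit` is for electrochemists and systems neuroscientists who want to
simulate such transients, fit them, and run fully seeded in-silico
genotype-contrast experiments.

## The model

Three coupled states on `t >= 0` (units: s, uM, mA, Hz; zero initial state):

    d[DA]_S/dt = DA_P * I * f * S(t) * L  -  Vm * [DA]_S / ([DA]_S + Km)
    S(t)       = sum_i theta(t - t_i) * theta(t_i + NP/f - t)
    d[DA]_E/dt = kS * [DA]_S - kE * [DA]_E + kGamma * Gamma_DA
    dGamma_DA/dt = k1ads * [DA]_E - k2ads * [DA]_E * Gamma_DA - k3ads * Gamma_DA

`[DA]_S` is striatal dopamine: released at rate `DA_P * I * f * L` while the
burst envelope `S(t)` is on (`NP` pulses at `f` Hz starting at `t_i`, current
`I`, dead-space loss factor `L`), and cleared by Michaelis–Menten DAT
reuptake with maximal velocity `Vm` and affinity `Km`. `[DA]_E` is the
dopamine the electrode actually reports, low-pass distorted by first-order
transfer (`kS`, `kE`) and by reversible adsorption to the carbon fiber
(`Gamma_DA`, rates `k1ads`, `k2ads`, `k3ads`, return rate `kGamma`).

The system is integrated with fixed-step classical RK4 (`dt = 1 ms`, grid
nodes exactly at burst boundaries), downsampled to the acquisition rate, and
fitted by bounded Levenberg–Marquardt least squares with a configurable free
mask (default: `Vm` and `DAP` free, everything else fixed).

## Worked example

An in-silico genotype contrast: generate WT and KO cohorts (4 and 5 animals,
10% between-animal CV on the free parameters, 0.05 uM measurement noise,
10 Hz acquisition), average each cohort, and refit the averages.

```r
library(fscvfit)

protocol <- stim_protocol()   # 30 pulses, 50 Hz, 0.4 mA, onset 2 s
cohorts <- list(
  WT = generate_cohort(cohort_spec("WT", wt_params(), between_animal_cv = 0.1,
                                   n_animals = 4, noise_sd = 0.05,
                                   seed = mix_seed(1, 1)), protocol),
  KO = generate_cohort(cohort_spec("KO", ko_params(), between_animal_cv = 0.1,
                                   n_animals = 5, noise_sd = 0.05,
                                   seed = mix_seed(1, 2)), protocol))
avg    <- lapply(cohorts, average_recordings)
fit_wt <- fit_trace(avg$WT, protocol, wt_params())
fit_ko <- fit_trace(avg$KO, protocol, ko_params())
compare_genotypes(fit_wt, fit_ko)
#> Genotype comparison (WT vs KO):
#>   Vm : 7.17 -> 1.98 uM/s   (72.3% reduction, ~72%)
#>   DAP: 0.685 -> 0.318 uM/mA  (53.5% reduction, ~54%)

th <- lapply(cohorts, function(x) sapply(x, clearance_half_time, protocol))
w <- welch_t(th$WT, th$KO)
cat(sprintf("t1/2: WT %.2f s vs KO %.2f s; Welch t = %.2f, df = %.1f, p = %.2g\n",
            w$mean_a, w$mean_b, w$t, w$df, w$p))
#> t1/2: WT 0.43 s vs KO 0.87 s; Welch t = -9.82, df = 6.9, p = 2.7e-05
```

The fitted `Vm` drops from 7.17 to 1.98 uM/s and `DAP` from 0.685 to
0.318 uM/mA — the cohorts were generated from medians (7.4, 0.67) and
(2.0, 0.31), so the refit recovers the generating physiology through the
between-animal variability and measurement noise; the clearance half-time
roughly doubles in the KO cohort, and the Welch test on per-animal half-times
rejects decisively. `run_experiment(default_experiment_config(seed = 1))`
runs this whole pipeline (plus per-animal metrics, JSON/CSV artefacts and a
provenance log) in one call, and a `fscv_cli()` dispatcher / `inst/cli`
script exposes `simulate`, `generate`, `metrics`, `fit`, `compare` and `run`
subcommands.

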