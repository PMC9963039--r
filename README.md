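# liftrisk

Simulated wearable-sensor assessment of low-back disorder (LBD) risk during
material handling.

## The problem

Low-back disorders are a leading occupational injury, driven by cumulative
micro-damage across repeated lifts. The Lifting Fatigue Failure Tool (LiFFT)
estimates a workday's LBD risk from two per-lift quantities — the number of
lifts and each lift's peak **load moment** (the moment the lifted object
creates about the L5/S1 joint). Wearable sensors could automate that
assessment, but a trunk IMU cannot observe how heavy an object is, or where
it is held relative to the spine. This package provides a seeded,
fully-synthetic simulation for quantifying the consequence: how accurately
can workday LBD risk be estimated from **trunk-motion signals alone**
(emulating a single trunk IMU) versus **trunk motion plus under-foot force
signals** (emulating an IMU plus pressure insoles)?

It is aimed at ergonomics and wearable-sensing researchers who want a
controllable test bed for sensor-set questions before investing in hardware
and calibration.

## The model

Per-lift damage follows an exponential fatigue-failure law and accumulates
additively over a workday; cumulative damage maps to risk through a
logistic model:

    d_i = exp(0.038 * M_load,i + 0.32) / 902416
    D   = sum_i d_i
    Y   = 1.72 + log10(D),    R = exp(Y) / (1 + exp(Y))

Because the machine-learning target is the total lumbar extension moment,
peak load moments are recovered by subtracting upper-body contributions:

    M_load = M_lumbar - [m_HAT (a + g) L + m_box a L] - I alpha

The pipeline: a planar lifting-biomechanics generator (ground-truth lumbar
moment, ground reaction forces, centre of pressure) → idealized wearable
channels (9 trunk channels; 6 under-foot channels) → gradient-boosted
lumbar-moment estimators with leave-one-participant-out cross-validation →
peak-moment lookup tables → Monte-Carlo workdays of 800–2000 lifts → RMSE,
±10-point agreement fractions, Fisher-pooled correlations, and a
lift-counter baseline. The methods vignette
(`vignettes/liftrisk-methods.Rmd`) documents every model assumption,
parameter and limitation.

## Worked example

A standalone LiFFT calculation — 2000 lifts at the nominal 75 Nm peak load
moment:

```r
library(liftrisk)
lbd_risk(cumulative_damage(rep(75, 2000))$D)
#> D = 0.05276, Y = 0.4423, LBD risk R = 60.9%
```

2000 such lifts accumulate a damage fraction of ~0.053, i.e. a logit of
0.44 and a 60.9% probability of being in a high-risk job.

The full simulation at its default study conditions (10 participants,
50 lifting tasks crossing 5–23 kg with 40–160 cm shelf heights, two
recorded lifts per task, 1000 simulated workdays per participant):

```r
res <- run_all(default_config(), seed = 1)
res$evaluation
#> LBD risk estimation accuracy over 10 participants x 1000 workdays
#>   RMSE  trunk: 7.0 +/- 2.8 %   trunk+force: 0.8 +/- 0.8 %   lift-counter: 2.8 %
#>   within +/-10 pts  trunk: 80.5 %   trunk+force: 100.0 %
#>   pooled r  trunk: 0.97   trunk+force: 1.00
#>   paired t(9) = 8.43, p = 1.5e-05, d = 3.02
#>   trunk risk vs lift count r = 0.80, vs bend angle r = -0.30
```

Reading this output: risk estimated from trunk motion alone is off by 7
percentage points of full-scale risk on a typical workday, while adding
under-foot force data cuts the error to under 1 point and keeps every
simulated day within the ±10-point agreement band; the paired comparison
across participants is decisive (t(9) = 8.4, pooled-SD Cohen's d = 3.0).
The trunk-only estimate correlates strongly with how many lifts were
performed (r = 0.80) — a trunk IMU acts largely as a lift counter — which
is the fundamental limitation the simulation exposes.

`run_all(cfg, out_dir = "run1")` additionally writes `manifest.csv`,
`profiles.csv`, `lookup.csv`, `workdays.csv` and `summary.json`, each
stamped with the configuration hash and seed. A thin command-line front end
with subcommands `generate`, `train`, `risk`, `simulate`, `evaluate`,
`run-all` and `validate` is installed at `inst/cli/liftrisk.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/liftrisk.R", package="liftrisk"))')" \
    run-all --seed 1 --out run1
```

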