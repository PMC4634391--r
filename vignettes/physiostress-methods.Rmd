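---
title: "physiostress: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{physiostress: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`physiostress` implements a complete stress-assessment pipeline for two
wearable physiological channels: a 250 Hz single-lead electrocardiogram (ECG)
and a 100 Hz thoracic electrical bioimpedance (TEB) stream. The pipeline has
five stages:

1. **Filterbank** — each channel is split into a slow ("continuous")
   component below 0.1 Hz, a respiration band, and a pulse-bearing band,
   using linear-phase FIR blocks and narrow-band interpolated-FIR (IFIR)
   stages.
2. **Rate estimation** — cycle detectors convert the band signals into eight
   derived signals on a common 50 Hz intermediate-frequency (IF) grid:
   `ECF`/`ZCF` (slow component), `ERT`/`ZRT` (respiration rate, breaths/min),
   `ERD`/`ZRD` (respiration depth) and `EPPM`/`ZPPM` (pulse rate, beats/min),
   for ECG and TEB respectively.
3. **Features** — 14 statistical/descriptive parameters per derived signal
   over sliding 60 s windows advancing by 10 s: 2 measurements × 4 signals ×
   14 parameters = 112 candidate features, each with a known
   operations-per-second price.
4. **Budget-constrained selection** — a genetic algorithm (GA) minimizes the
   cross-validated error of a least-squares linear classifier subject to the
   strict computational budget $N_{op} < N_{max}$, where $N_{op}$ counts the
   simple operations per second of the full processing chain a feature subset
   requires.
5. **Classification and evaluation** — a one-hidden-layer multilayer
   perceptron (10 tan-sigmoid units, linear outputs, argmax decision) or the
   linear classifier, evaluated by leave-one-subject-out (LOSO)
   cross-validation with per-class and unweighted-average error
   probabilities.

Because no recording database ships with the package, a seeded synthetic
generator produces multi-subject cohorts with known ground truth; every
stage is tested against that ground truth or against independent
brute-force oracles.

# The filterbank and the IFIR realization

The ECG chain uses an order-100 low-pass at 0.5 Hz (`LF`) as anti-aliasing
filter feeding two order-1150 IFIR stages with stretch factor $SF = 25$: a
0.1 Hz low-pass (`CF`, output `fe1`) and a 0.1–0.5 Hz band-pass (`RF`,
output `fe2`); a parallel order-100 low-pass at 30 Hz (`MF`) on the raw
input yields the pulse-bearing `fe3`. We read "low-pass filtered at 0.5 Hz
and then at 30 Hz" as an enumeration of parallel branches, not a cascade —
a 0.5 Hz low-pass followed by a 30 Hz low-pass would make the second block
vacuous.

An IFIR stage of order $N_2$ and stretch $SF$ is realized as a prototype
whose coefficients are spaced $SF$ samples apart, evaluated on the
$SF$-decimated grid; its spectral images at multiples of $f_s/SF$ (10 Hz for
both chains) fall deep in the stopband of the preceding anti-aliasing
low-pass. This realization costs $N_2 f_s / SF$ multiply-accumulates per
second — 11,500 ops/s for the ECG stages — and is the only reading under
which the chain can actually separate the 0.1 Hz split: the effective
prototype runs at 10 Hz, giving a transition width of roughly
$3.3 \cdot 10 / 1150 \approx 0.03$ Hz. (The alternative reading, a
46-nonzero-tap filter at the native rate, has a ~0.7 Hz transition and
cannot distinguish 0.1 Hz from 0.25 Hz at all.) The price is group delay:
$N_2 \cdot SF / 2$ native samples (57.5 s for the ECG chain), so each
recording loses one warm-up span at each end; feature windows are restricted
to the valid interior.

Filters are designed by Hamming-windowed sinc (`signal::fir1`). Any
linear-phase design meeting the band specifications would do; tests assert
response tolerances, never coefficients. Designs are exactly symmetric, so
group delay is exactly half the order and all branches are realigned by
integer shifts.

The TEB chain follows the same topology at 100 Hz with $N_2 = 400$,
$SF = 10$. The published description fixes only those orders; the band
edges are package choices: anti-aliasing low-pass at 4 Hz, respiration band
0.1–0.8 Hz (6–48 breaths/min) and pulse band 0.8–3 Hz (48–180 beats/min).
Two constraints drive them: the prototype rate is 10 Hz, so every passband
must stay below the 5 Hz prototype Nyquist with its image band clear of the
anti-aliasing stopband; and the estimators must cover the physiological
operating range, including exercise respiration above 30 breaths/min —
which the ECG-side 0.1–0.5 Hz respiration band (kept as published)
deliberately does not.

# Cycle detectors

**BPM block** (respiration, and the TEB pulse wave): treats the band signal
as sine-shaped and finds alternating maxima/minima with a hysteresis of 20%
of a running peak-to-peak estimate (an exponential moving average of recent
cycle amplitudes, which makes detection scale-invariant). Per cycle, rate
$= 60/\Delta t$ between successive maxima and depth $=$ max − min within
the cycle. A refractory interval (1 s for respiration; 0.3 s and 30%
hysteresis for the blunter, faster TEB pulse wave) suppresses double
counts. No detection thresholds are published; these values are
config-exposed defaults.

**PPM block** (ECG beats): five-sample differentiation
$d[n] = x[n] - x[n-5]$ of the wideband branch, thresholded at 0.5 × a
running 95th percentile of the positive differences over the trailing 5 s
(updated every second and held), refractory 250 ms (240 beats/min
ceiling). Only "thresholding of the five-sample differentiation" is
published; the adaptive threshold is the package's choice and makes
detection amplitude-invariant.

**Interpolation**: cycle events are held to the 50 Hz IF grid by
zero-order hold, left-closed (an event on a sample instant updates that
sample); samples before the first event take the first value. The rate
traces hold the instantaneous (per-cycle) rate, not a windowed average.

# Features and their costs

The 13 window statistics use standard definitions: sample standard
deviation; population-moment skewness and non-excess kurtosis (normal → 3;
the convention is not published, so it is fixed and documented here);
"trimmed mean of 25%" discards 12.5% of the sorted samples at each
extreme (25% total, the dominant toolbox convention, switchable via
`trim`); percentiles interpolate linearly between order statistics
(type 7), computed directly from the sorted vector. Geometric and harmonic
means require strictly positive windows and propagate `NA` otherwise; such
windows are excluded from training/testing when an affected feature is
selected. The 14th parameter, `baseline`, is a first-order IIR low-pass
$b[n] = (1-\alpha) b[n-1] + \alpha x[n]$ sampled at the window's last
sample; the default $\alpha = 1/(300 \cdot 50)$ gives a 300 s time
constant, matching the several-minute resting intervals the long-term mean
is meant to average over.

Windows are labelled by the majority class of their samples and dropped
when the majority share falls below 90% — a clean rule for windows
straddling class boundaries.

$N_{op}$ for a feature subset sums (i) every processing stage in the
subset's dependency closure exactly once (filter stages priced by the rules
order × $f_s$ for FIR and order × $f_s$/SF for IFIR; decimation and
detector blocks at their published constants), and (ii) per-parameter
costs, where the rank statistics of one signal share a single 27,580-ops/s
sort (the trimmed mean adds its 225-ops/s increment; median and percentiles
add nothing). The four filter costs are always computed from the rules,
never stored. The block constants' internal op-counting conventions are not
derivable from the published material and are adopted verbatim.

# Selection, classifiers, evaluation

The GA follows the published procedure: population 200, the best 20
survive, uniform set-crossover of two parents drawn (with replacement) from
the survivors, 10% per-individual mutation replacing one member feature
with a random non-member, 100 generations, 5 restarts, and the generation's
best individual carried over unaltered. Duplicated individuals are
perturbed by a single-feature swap; over-budget individuals are repaired by
random removal (random single-feature draws if emptied), so every evaluated
individual satisfies $N_{op} < N_{max}$ strictly. Unspecified details
resolved here: crossover inherits each feature of the parent union with
probability ½; mutation substitutes (never grows or shrinks) and is
per-individual; fitness folds are fixed across generations and cached.

Fitness is the $(k-1)$-fold by-subject cross-validated mean squared error
of a ridge-stabilized ($10^{-8}$ × mean Gram diagonal) least-squares linear
classifier on one-hot targets, with bias, on standardized features. The MSE
is the per-window squared error *summed over the $M$ outputs* (so pure
noise scores $(M-1)/M$, the one-hot target variance), averaged over folds.
The implementation precomputes per-fold Gram matrices once, making each
subset evaluation independent of the number of windows.

The MLP has one hidden layer of 10 tan-sigmoid units and linear outputs
trained on one-hot targets by quasi-Newton squared-error minimization
(`nnet`); with squared error and linear outputs this is the same objective
a Levenberg–Marquardt trainer would minimize, and acceptance is behavioral
(error rates), not trainer-identical. Early stopping holds out 10% of
*subjects* (at least one), checks validation error every 10 optimizer
iterations, stops after 6 non-improving checks (patience and check interval
are package choices; none are published) and keeps the best-validation
weights; 5 restarts from random weights compete by decision error over the
full design set. Features are standardized first — rate traces living near
70 beats/min would otherwise ill-condition training. Decisions are argmax
with ties to the lowest class index.

LOSO evaluation holds out one subject per fold, runs the GA and trains the
classifier on the remaining subjects only (no leakage; asserted by tests),
and pools confusion counts over folds. Per-class error is the off-diagonal
row share in percent; the average is the *unweighted* mean over classes.
Percentages are rounded only for display. The budget sweep
(`nmaxSweep()`) repeats the analysis over a grid of budgets — the
study-scale grid is 20,000–200,000 in steps of 20,000 with 100 repetitions —
and reports quartiles; both the repetition count and the GA depth are
exposed so the experiment can be run at desk scale.

# The synthetic generator

The generator emulates the class structure of the three tasks (activity:
neutral/emotional/mental/physical; emotion: neutral/sad/disgust; mental
load: low/high). Class-conditional means for heart rate, respiration rate,
the two respiration depths and the two slow levels are the published
per-class averages of the corresponding derived signals
(`classConditions()`). A single ground-truth physiology drives both
channels; published per-signal averages that disagree across channels
(e.g. the ECG- and TEB-derived respiration rates) are artifacts of the
original estimators that the generator does not emulate.

The ECG is a train of 80 ms raised-cosine pulses (amplitude 1) whose
inter-beat intervals follow the class heart rate with 2% log-normal
beat-to-beat jitter, riding on the slow level, a 0.05-amplitude drift at
0.02 Hz, and a respiration-coupled baseline wander of amplitude depth/2 —
a narrow positive pulse suffices because the beat detector thresholds a
differentiated signal and is not morphology-sensitive. The TEB is the
respiration oscillation (amplitude depth/2) plus a 0.05-amplitude
cardiac-frequency sinusoid, level and drift. Additive white Gaussian noise
defaults to 0.02 (ECG) and 0.005 (TEB). Subject identity is a confounder:
one log-normal factor per quantity (default 5% SD) is drawn once per
subject and applied to all of that subject's classes, creating the grouping
LOSO must respect. All randomness derives from explicit seeds;
identical seeds reproduce recordings bit for bit.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: realistic P-QRS-T morphology, motion and
electrode-contact artifacts, powerline interference, heart-rate-variability
spectra, within-class nonstationarity, and the true covariance between
physiological quantities. Published within-class variances are not
available, so class overlap is a generator parameter, not a calibrated one;
synthetic classification errors consequently say nothing about the error
rates attainable on real recordings, and the published headline error rates
are used in tests only to validate the metric arithmetic on their printed
confusion matrices.

# Numerical choices and degenerate inputs

* Decimation to the IF keeps every $(f_s/50)$-th sample, phase 0, length
  $\lfloor n \cdot 50 / f_s \rfloor$; inputs are already band-limited by
  construction.
* Detectors run on the warm-up-free span only; a detector that finds no
  cycles (e.g. constant input) yields an empty event set, the affected
  derived signals become `NA`, and downstream windows are excluded.
* Skewness/kurtosis of a zero-variance window are defined as 0; location
  statistics collapse to the constant.
* The linear classifier's ridge term makes duplicated features and
  rank-deficient windows well-posed; with `ridge = 0` it reproduces the
  pseudoinverse solution to 1e-8.
* GA dedupe retries are capped (20 per individual) so tiny budgets with few
  feasible sets terminate; repair errors out, naming the cheapest
  single-feature cost, when no single feature fits the budget.

# Problem sizes used by the test suite

The test and acceptance suites run the pipeline at desk scale: cohorts of
8 subjects × 4 classes × 150 s per class; rate-recovery grids on 240 s
single-class recordings; GA contract checks on planted-signal tables
(3 informative among 112 features, 8 subjects × 40 windows, 20 seeds,
population 200, 40 generations, 2 restarts); and LOSO analyses with
population 40, 15 generations, 2 restarts under an 80,000 ops/s budget.
These sizes are the package's defaults for its own validation experiments;
the full published experiment scale (40 subjects, 100 repetitions ×
10 budgets, 100 generations × 5 restarts) is reachable through the same
configuration objects.

# Known limitations

* The TEB band edges and all detector thresholds are package choices where
  the source material is silent; they are exposed in the configuration and
  documented above.
* The pulse band tops out at 180 beats/min (3 Hz) and bottoms at 48
  beats/min by design; severe bradycardia or tachycardia outside that range
  would be missed by the TEB pulse estimator.
* The ECG respiration estimate saturates above ~30 breaths/min because the
  published 0.1–0.5 Hz respiration band is kept as printed.
* The GA is a metaheuristic: no optimality guarantee, and with aggressive
  budgets its result depends on the seed; restarts mitigate but do not
  remove this.
* Cost modelling counts simple operations per second; it is not
  cycle-accurate for any real CPU and does not model energy.
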