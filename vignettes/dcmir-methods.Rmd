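---
title: "Modeling induced EEG responses: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling induced EEG responses: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`dcmir` infers directed, frequency-resolved coupling between cortical
sources from event-related changes in oscillatory power. The observed
quantity is the trial-averaged, baseline-corrected time-frequency power of
five motor sources (cM1, iM1, cPM, iPM, SMA) during motor preparation
(-1000 to 0 ms relative to EMG onset). The frequency axis (4-48 Hz at 1 Hz)
is reduced by SVD to M = 4 orthonormal spectral modes, and the stacked mode
power of all regions, g(t) (length J*M = 20), is modeled as a linear
dynamical system

tau * dg/dt = A g(t) + C u(t)

where A contains coupling rates between (and within) the regions' spectral
modes, C weights a gamma-shaped input u(t) entering the SMA modes, and tau
is a fixed scaling constant (1 s). A within-frequency ("linear") connection
is a diagonal M x M block of A; cross-frequency ("nonlinear") influence
fills the block. Back-projection through the loading matrix U turns an
estimated block A_ij into a frequency-by-frequency coupling map
U A_ij U^T, whose entry (f_target, f_source) is the influence of power at
f_source in the source region on power at f_target in the target region;
positive coupling is excitatory (same-direction power change), negative
inhibitory.

## Input

The extrinsic input is a gamma-density bump peaking 400 ms before EMG onset
with a standard deviation ("dispersion") of 400 ms, peak-normalized to 1.
Shape and scale are solved from the mode offset m and SD s via
(k-1)*scale = m, sqrt(k)*scale = s; on the default [-1000, 0] ms window
this gives shape 4 and scale 200 ms exactly. We interpret "dispersion" as
the SD of the bump; this is one of two common parameterizations and is the
only one that makes the stated peak/width pair well defined here.

## Model space

Twelve models in two families share full "nonlinear" extrinsic
connectivity options: family 1 (models 1-6) restricts intrinsic
(within-region) blocks to diagonals; family 2 (models 7-12) allows full
intrinsic blocks. In each family, five models drop one or two
premotor-origin connections (cPM->iPM, iPM->cPM, cPM->cM1, iPM->iM1, or
both PM->PM links) and the sixth is fully connected, so model 12 is the
fully connected nonlinear-intrinsic model. The exact membership of the
reduced models is not uniquely determined by the published description;
the list above is this package's fixed, configurable choice.

# Estimation

`fit_dcm()` is a variational-Laplace scheme: Gaussian priors on the free
parameters, Gauss-Newton updates of the posterior mode with a
finite-difference Jacobian, an EM update of a single observation-noise
precision under a broad Gamma hyperprior, and a free energy
(accuracy - complexity) that is recorded per accepted iteration and used
as the model evidence in group-level model selection.

Design choices that proved to matter, and why:

* **The initial state is estimated, not fixed.** The model is a
  deterministic ODE; forcing the trajectory through the noisy first
  observed sample pushes the resulting misfit into spurious couplings. The
  initial state is therefore a free parameter with prior centered on the
  first observed sample (`g0_var = 1`).
* **Tiered priors.** Extrinsic couplings get the shrinkage prior
  N(0, 1/16). Self-connections (the A diagonal) are known to be negative
  and of order one per second, so they get N(-0.5, 1); shrinking them
  toward zero with the extrinsic prior systematically slows the fitted
  decay and the optimizer compensates with structured spurious feedback
  couplings (we observed consistent negative couplings into the input
  region before adopting the tiered prior). Within-region cross-mode
  entries (nonlinear-intrinsic family only) default to the extrinsic
  variance.
* **A genuinely broad noise hyperprior.** With Gamma rate b0 = 1e-3 the
  noise precision saturates near N/(2 b0); on noise-free data that cap
  makes a low-parameter-norm alternative solution beat the truth. The
  default b0 = 1e-6 leaves the precision effectively unbounded, and exact
  data are then recovered exactly.
* **Hybrid finite differences.** Forward differences are used while the
  residual is large; once the RMS residual falls below ~100x the step the
  scheme switches to central differences, whose smaller truncation error
  is needed to resolve the flat valley around near-exact fits.
* **Monotone free energy.** A step that lowers the re-evaluated free
  energy is reverted and the step scale halved; the recorded trace is
  non-decreasing. Convergence at |dF| < 0.01 nats or 128 iterations.

Numerical integration uses the augmented-matrix exponential per time bin
with the input held constant within bins; this is exact for
piecewise-constant input, so refining the grid under the same input step
function changes nothing.

# Group inference

Random-effects Bayesian model selection estimates a Dirichlet posterior
over model frequencies from per-subject free energies (variational
updates, uniform Dirichlet(1) prior) and computes exceedance probabilities
by seeded Monte Carlo (default 1e6 draws). Family inference rescales the
prior so each family carries equal mass (1/family-size per model),
aggregates sampled frequencies per family, and then reruns model-level
selection inside the winning family. All results are invariant to
per-subject constants in the evidence and to model reordering.

A subtlety worth knowing: with 12 subjects and 12 models, a model favored
by every subject has a true exceedance of about 0.9987 under the
Dirichlet(1) prior - the "overwhelming evidence" limit of 0.999+ requires
more subjects (24 in our tests), a property of the posterior rather than
of the implementation.

Coupling maps are smoothed (FWHM 8 Hz on both frequency axes; spectrogram
contrasts 8 Hz x 96 ms) with truncated-renormalized Gaussian kernels, then
tested voxel-wise with two-tailed one-sample or paired t tests at
p < 0.005 uncorrected. Clusters are 4-connected components of the
suprathreshold mask, split by sign; tables report the peak voxel's
source -> target frequencies and band labels (theta 4-7, mu 8-12,
beta 13-35, gamma 36-48 Hz). Zero-variance voxels are flagged and their t
value capped rather than infinite.

# The synthetic study generator

`make_population()` / `simulate_study()` emulate a 12-subject,
~60-trial-per-subject study: per-subject coupling matrices built from a
planted band-to-band template ("HO": SMA->cM1, cPM->cM1, SMA->cPM,
iM1->cM1, all beta->beta positive; "HOL": a richer set with
cross-frequency and one negative link), mode trajectories simulated with
the gamma input into SMA, back-projected to 45 frequencies through a
smooth synthetic loading (one orthonormalized Gaussian bump per canonical
band), and iid Gaussian observation noise at 10% of the signal SD. Toy
rectified EMG traces carry onset differences drawn from a
truncated-normal (mean 75 ms, SD 50 ms, positive part), matching the
behavioral regime where essentially no trial violates the 500 ms
simultaneity rule.

Three generator properties are there deliberately, because without them
the inverse problem is degenerate rather than merely noisy:

* **Per-region heterogeneous decay** (intrinsic rate -1 +- 0.4 per subject
  and region). If all states decay at the same rate, free-decay signatures
  are indistinguishable and source attribution has an exact null space -
  we verified that a noise-free fit then reaches variance explained 1.0
  with a wrong A. The decay is a scalar per region, so intrinsic blocks
  stay diagonal under any orthonormal mode rotation and the generating
  process remains in the linear-intrinsic family even in the estimated
  mode basis. (An optional per-mode spread exists; note that it rotates
  into apparent cross-frequency intrinsic coupling under SVD and then
  favours the nonlinear-intrinsic family.)
* **Nonzero initial mode power** (SD 0.5). Baseline correction zeroes the
  mean power over the baseline window, not the instantaneous power at
  -1000 ms; regions with no incoming connections would otherwise be
  exactly silent and their outgoing couplings unidentifiable.
* **A zero-mean background network** (between-subject SD = 30% of the
  planted mean, applied to every extrinsic entry, rescaled if a draw is
  unstable). Real cohorts carry idiosyncratic couplings of comparable
  magnitude to the group-consistent ones; the background also propagates
  input-locked signal into every region - which is what makes outgoing
  couplings of regions like iM1 estimable at all - while averaging to
  zero in the group test.

## What passing tests do and do not show

The generator produces smooth, deterministic rank-4 spectrograms driven by
a single known input; real data add phase dynamics, non-Gaussian and
autocorrelated noise, volume-conduction residuals, head-model error and
trial-to-trial variability that are not emulated. Recovery results
therefore validate the estimation and inference chain, not the
physiological interpretability of real-data fits. Within the emulated
conditions, the weakest planted link (iM1->cM1, whose source region
receives no planted input-driven signal) sits near the p < 0.005
detection threshold: across probe seeds its group t ranged roughly
2.7-4.5, so single-study recovery of that link is borderline by design -
an honest reflection of the method's power for second-order sources given
one 1-s trial-average per subject. False-positive voxel rates on absent
connections stayed one to two orders of magnitude below the 1% bound in
every run we performed.

## Problem sizes used in the packaged experiments

The packaged tests and the acceptance script run: a 12-subject recovery
study (full linear-intrinsic model, 364 free parameters, 101 time bins),
forward-model oracle checks on twenty 20 x 20 systems, BMS calibration
cases with up to 24 synthetic subjects, a type-I-error simulation with
~100,000 null voxel tests, and a 3-subject two-model pipeline determinism
run. Small two-region, two-mode models are used for unit-level inversion
properties. These sizes were chosen to exercise every code path at full
model dimensionality while keeping a complete run in the minutes range.

# Known limitations

* Phase is ignored by construction; only power dynamics enter the model.
* tau and the input timing are fixed, not estimated; they are absorbed
  into the scale of A and C.
* The per-subject fit is heavily prior-regularized: with one trial-average
  per condition, many coupling directions are near-degenerate, and only
  group-consistent structure survives the one-sample t maps.
* Family identity is basis-dependent: cross-frequency structure in the
  estimated mode basis can reflect rotation of basis rather than "true"
  cross-frequency physiology.
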