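---
title: "Channel encoding models, transform equivalence, and Bayesian stimulus decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel encoding models, transform equivalence, and Bayesian stimulus decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iemtools)
```

## The model

`iemtools` studies the channel (forward) encoding model of trial-by-voxel
responses to an axial circular stimulus — orientation, with period 180°.
Writing `S` for the one-hot design (n trials × s orientations), `C` for the
basis evaluation matrix (s × k channels) and `W` for voxel weights (k × v),
the model is

$$B = SCW + \eta = RW + \eta,$$

with $\eta$ zero-mean Gaussian noise.  `iem()` estimates $\hat W$ by
ordinary least squares on a training set; `invert_iem()` applies the
pseudo-inverse $\hat R = B_V \hat W^\top (\hat W \hat W^\top)^{-1}$ to a
held-out validation set; `shift_average()` aligns each trial's
reconstruction to the presented orientation and averages, producing the
channel response function (CRF).

The package's central point is an identifiability result: for any
invertible $P$, the basis $C_2 = C_1 P$ yields a fit with
$\hat W_2 = P^{-1}\hat W_1$, identical predictions everywhere (including
orientations never trained on), identical variance explained, and
reconstructions $\hat R_2 = \hat R_1 P$.  The CRF therefore echoes the
assumed basis, not the underlying population tuning: the simulator only
ever contains unimodal neurons, yet a bimodal (or random) basis produces a
bimodal (or random-looking) CRF.  `check_weight_identity()`,
`check_reconstruction_identity()`, `check_leftout_prediction()`,
`check_variance_equality()` and `run_equivalence_suite()` execute these
identities as numerical checks.

## The synthetic data generator

`simulate_population()` emulates the standard voxel model: each of `v`
voxels pools `m` identical orientation-tuned units with evenly spaced
preferred orientations.  Tuning is a doubled-angle von Mises,
$a(\Delta) = \exp(\kappa(\cos(2\Delta \pi / 180) - 1))$, parameterized by
its half-width at half-height `h` through
$\kappa = \ln 2 / (1 - \cos(2h\pi/180))$ (`kappa_from_hwhh()`).  Pooling
weights are iid uniform(0, 1) draws normalized so each voxel's weights sum
to one — the simplest reading of "a random proportion of each neuron".
`simulate_dataset()` adds iid Gaussian noise per trial and voxel.

Defaults are the canonical study conditions: `v = 100` voxels, `m = 180`
units, `h = 40`°, 8 orientations × 27 repeats (n = 216), 8 channels with
exponent 7.  Unit count and weight distribution are this package's
choices where the convention leaves them open; `m = 180` gives dense
deterministic coverage, and unit peak response 1 fixes the response units.

What the generator does *not* emulate: correlated voxel noise,
hemodynamic temporal structure, heterogeneous tuning widths, or any
measurement nonlinearity.  Passing tests therefore demonstrate properties
of the model and estimators, not of real fMRI data — with the important
exception of the transform identities, which are exact algebra and hold
for any data whatsoever.

### Noise presets

Because each voxel pools many near-uniformly weighted units, the evoked
(across-orientation) signal per voxel is small (standard deviation about
0.01 in unit-response units).  `noise_presets()` provides `zero`,
`low_noise = 0.008` and `high_noise = 0.032`; the latter two were
calibrated once, by a seeded pilot sweep, to held-out encoding r² of about
0.7 and 0.1 — the "low noise (high r²)" and "high noise (low r²)" regimes.
They are conventions of this package, fixed after calibration and not
adjusted thereafter.

## The transforms

`bimodal_transform()` builds the circulant converter
$P = I + g\,\Pi^m$ ($\Pi$ the one-step cyclic channel shift).  Applied to
the unimodal basis it adds to each channel a secondary lobe `m` channel
steps away: with the defaults `k = 8, m = 3, g = 0.9` the lobes sit 67.5°
apart (the "about 67°" configuration).  Being circulant, its eigenvalues
are $1 + g e^{2\pi i m q / k}$ in closed form — minimum modulus 0.1,
condition number 19 — so invertibility is checkable analytically, and the
construction rejects singular parameter choices (e.g. `g = 1` here).
The exact transform used in the original demonstrations is not published;
the circulant construction is this package's choice precisely because it
is reproducible and analytically transparent.

`random_transform()` draws standard-normal k × k matrices from a seeded
stream and accepts the first with condition number below 1e3 (default).
The ceiling is a numerical hygiene choice: any invertible matrix works in
exact arithmetic, but reconstructions through an ill-conditioned transform
lose float precision; with cond(P) ≤ 1e3 all identities hold below the
1e-8 relative tolerance used throughout (roughly cond(P) × machine epsilon
× a safety margin).

One orientation subtlety: the aligned CRF is indexed by *channel-center
offset* from the presented orientation, so it samples the center channel's
profile mirror-imaged — a channel centered 67.5° below the stimulus
responds through its upper lobe.  The peak *separation* (67.5°) is
unaffected; tests compare the aligned curve against the profile evaluated
at negated offsets.

## The Bayesian decoder

`fit_noise_model()` models training residuals $Z = B_T - R\hat W$ as
Gaussian rows with covariance

$$\Omega = \hat W^\top \sigma_c^2 I_k \hat W + \mathrm{diag}(\tau^2),$$

iid channel noise propagated through the fitted weights plus independent
per-voxel noise.  A correlated voxel-noise term is deliberately omitted —
the simulator does not generate one.  Fitting maximizes the Gaussian
likelihood by BFGS with analytic gradients over
$(\log\tau^2, \log\sigma_c^2)$, initialized at the per-voxel residual
variances and $\sigma_c^2 = 10^{-3}\overline{\tau^2}$, with three jittered
restarts on non-convergence.  Non-positive-definite candidates are
rejected steps (infinite objective); an all-zero residual matrix is an
error, never a silent fit.

`posterior_grid()` evaluates, for each validation trial, the likelihood of
the observed voxel response under mean $c(\theta)\hat W$ and covariance
$\Omega$ on a uniform orientation grid, and normalizes with a log-sum-exp
shift under a uniform prior.  The default grid step in the experiment
drivers is 0.5° so that the default orientations (multiples of 22.5°) fall
exactly on grid points, making posterior alignment exact; `posterior_grid()`
itself defaults to 1°, and any step dividing 180 is accepted.  Posteriors
are discrete distributions over grid points (no bin-width density
scaling): only likelihood ratios survive normalization.

Because the decoder targets the stimulus rather than the model, its
posterior is unimodal and centered at the true orientation whether the
basis is unimodal, bimodal or random — the constructive counterpoint to
the CRF's basis-dependence.  Exact numerical invariance, however, holds
only for the predictive means: the fitted covariance family
($\sigma_c^2 \hat W^\top \hat W$ is basis-dependent for non-orthogonal
$P$) lets the estimated channel-noise variance differ slightly between
bases at finite n, so posterior maps under different bases agree closely
(order 1e-4 per entry at n = 216) but not to machine precision.  This is a
property of the noise model's parameterization, discussed further under
limitations.

## Numerical choices

* Least squares and model inversion use QR factorizations; the explicit
  normal-equations and pseudo-inverse formulas serve as test oracles
  (agreement at 1e-10 under the default conditions).
* Rank-deficient channel-response matrices (fewer independent basis
  evaluations than channels) are an error reporting the rank, not a
  silent pseudo-inverse; the same applies to rank-deficient weights at
  inversion.
* `shift_average()` requires every presented orientation to coincide with
  a channel center; off-center designs are rejected rather than
  interpolated, because the shift-and-average summary presumes matched
  centers.
* r² is pooled over voxels and trials about the grand mean by default;
  a per-voxel-mean variant is available via `pooled = FALSE`.  The
  equivalence of the two fits holds under either.
* `local_maxima()` uses strict circular neighbor comparison; a plateau
  counts once at its first index, and a constant curve has no maxima.
  Peak counts on CRFs are taken on the native k-point aligned grid, with
  no smoothing, to keep modality claims deterministic.  `fwhm()` alone
  interpolates linearly between grid points.
* Modes of *averaged posterior* curves are counted above a relative floor
  (1% of the peak, `mode_floor` in `summarize_posteriors()`): averaged
  probability curves carry exponentially small tail ripples (each trial's
  posterior tail decays at its own rate), which strict counting would
  report as maxima at heights like 1e-100.
* Equivalence discrepancies are relative Frobenius norms with an absolute
  fallback (1e-12) when the reference norm is numerically zero; the
  default tolerance 1e-8 follows from cond(P) ≤ 1e3 in double precision.

## Problem sizes

The bundled tests and demonstrations run the full default configuration
(100 voxels, 216 trials, 180 units) for the identity checks and the
Bayesian analyses; the noise-model recovery study uses n = 2160 trials;
replication studies of CRF modality use 100 seeded replicates per noise
level.  Unit tests of individual operations use smaller populations
(10–50 voxels), which is sufficient because the properties tested are
size-independent.

## Known limitations

* The equivalence results concern bases related by an *invertible*
  transform; comparing models with genuinely different spans (or different
  k) is out of scope.
* The Bayesian noise model assumes channel noise isotropic in the fitted
  basis.  Consequently basis-invariance of the posterior is exact in the
  means but only approximate in the fitted covariance at finite n (see
  above).  An alternative — defining channel noise in a fixed canonical
  basis — would make invariance exact but changes the model class.
* At high noise, the shift-averaged CRF over 216 trials retains a visibly
  attenuated secondary lobe and per-point sampling wiggles of the same
  order as the remaining structure; strict 8-point peak counting therefore
  rarely reports exactly one maximum, even when the curve "looks"
  unimodal.  Visual unimodality at low r² is a qualitative, not a strict
  combinatorial, phenomenon.
* Ridge or otherwise regularized weight estimation, stimulus-space
  read-outs by weighted receptive-field summation, and non-uniform priors
  are not implemented.
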