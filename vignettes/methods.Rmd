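---
title: "Effective connectivity from infant fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective connectivity from infant fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsDCM)
```

## What the package does

`fnirsDCM` estimates directed (effective) connectivity between cortical
regions from functional near-infrared spectroscopy (fNIRS) recordings by
dynamic causal modelling (DCM): a generative model links hidden neuronal
dynamics, through vascular (balloon) hemodynamics and a photon-transport
observation equation, to the optical-density signals measured at
scalp-level source-detector channels.  Bayesian inversion of this model
yields posterior distributions over the coupling parameters and a free
energy that approximates the log model evidence, supporting comparison of
alternative connectivity hypotheses.

The package targets the setting of an infant auditory study: a 3-region
network (inferior frontal gyrus IFG, superior temporal sulcus STS,
temporo-parietal junction TPJ) driven by two auditory conditions — vocal
(V) and non-vocal (NV) sounds — recorded with a 9-channel array (4 sources,
4 detectors, 2 cm separation, 770/850 nm, 10 Hz) in a block design of
12 + 12 blocks of 9 s with at least 13 s of rest over an 11.5-minute
session.  Because no public dataset exists for that recording, the package
carries a first-class synthetic-data generator that emulates the study
conditions and harnesses that quantify how well the pipeline recovers
known ground truth.

## The generative model

**Neuronal level.**  Region states `z` follow the bilinear deterministic
form

    dz/dt = (A + sum_j u_j B_j) z + C u

with intrinsic coupling `A` (Hz; self-connections on the diagonal),
condition-specific modulations `B_j`, and direct driving inputs `C`.  In
every model of the space, both auditory inputs drive STS, and the
intrinsic skeleton fixes bidirectional STS–TPJ and STS–IFG connections.

**Hemodynamic level.**  Each region runs a balloon model: vasodilatory
signal `s`, inflow `f`, venous volume `v` and deoxyhemoglobin `q`:

    ds/dt = z - kappa_s s - gamma (f - 1)
    df/dt = s
    tau dv/dt = f - v^(1/alpha)
    tau dq/dt = f (1 - (1 - E0)^(1/f)) / E0 - v^(1/alpha) q / v

Defaults (configurable via `hemodynamicParameters()`): kappa_s = 0.64 1/s,
gamma = 0.32 1/s, tau = 2 s, alpha = 0.32, E0 = 0.32 — the standard
published values for this model family.  Chromophore changes follow from
the balloon states via baseline concentrations HbT0 = 100 uM and
HbR0 = 40 uM: dHbT = HbT0 (v - 1), dQ = HbR0 (q - 1), dH = dHbT - dQ.
Only products of these baselines with the optical sensitivity are
identifiable; the observation scaling `k` (below) absorbs the rest, which
is why the baselines are fixed constants rather than free parameters.

**Optical observation.**  Per wavelength, optical-density changes are

    y(lambda) = epsH(lambda) WH(lambda) S(lambda) dHc
              + epsQ(lambda) WQ(lambda) S(lambda) dQc,   S = k S0

where `S0` is the channels x regions optical sensitivity computed by the
photon-transport module, `epsH`/`epsQ` are extinction coefficients,
`WH`/`WQ` are pial-vein correction factors (default 1: no correction),
and `k` is a free scaling with an informed log-normal prior,
log k ~ N(0, 1/16), accommodating unknown source strength and detection
efficiency.  A BOLD observation (`observeBold()`) provides the fMRI twin
for cross-modality experiments.

Integration is fixed-step 4th-order Runge–Kutta (compiled), with inputs
held on their own grid and linearly interpolated at stage times so the
integration step can be varied independently of the stimulus sampling.
The default step is 0.05 s for simulation and 0.1 s for model inversion;
step-halving changes outputs by less than 1e-4 relative on smooth inputs.
Non-positive hemodynamic states trigger sub-step retries; neuronal states
beyond |z| > 1e3 abort with an error naming the model.

## Photon transport and channel sensitivities

The continuous-wave diffusion approximation

    (div kappa grad + mua) phi = 0 in the volume,
    phi + 2 A kappa n . grad phi = q on the boundary

is discretised with linear tetrahedral finite elements on a layered slab
mesh standing in for the segmented infant head (scalp/skull +
extra-cerebral tissue, CSF, brain; scalp face at z = 0, depth along +z).
`kappa = 1/(3(mua + mus))` with `mus` read as the reduced scattering
coefficient — the standard diffusion-approximation convention.  The
boundary term uses A = 2.82 (tissue–air refractive mismatch, n ~ 1.4) by
default.  Tissue coefficients ship as replaceable literature defaults for
a neonatal head at 770/850 nm (`defaultOpticalCoefficients()`); they are
not measurements.

Sources are modelled as isotropic points buried one reduced scattering
length below the entry point, loaded onto the containing element by
barycentric weights.  A channel's sensitivity function (photon measurement
density function) is the absorption derivative of its log-measurement,
computed from products of the forward field of the source and the adjoint
field of the detector, normalised by the unperturbed measurement; node
entries are symmetrised so the row is exactly invariant under
source-detector exchange.  Adjoint fields are reused across channels, so a
4 + 4 optode array costs 8 solves per wavelength rather than 18.

Numerical choices worth knowing:

* The mesh builder accepts an explicit tensor grid (`grid =`), used to
  refine the region under a source.  The analytic oracle (semi-infinite
  extrapolated-boundary solution, `analyticSemiInfiniteFluence()`) agrees
  with the solver to better than 10% in the interior zone (>= 5 mm from
  the source, >= 10 mm from walls) on a ~12k-node graded slab; agreement
  improves with resolution.
* P1 finite elements do not guarantee positivity; on coarse meshes the far
  field can undershoot zero by a tiny fraction of the peak.  Interior
  positivity holds at the fixture resolutions used in the tests.
* Sparse systems are solved by a cached Cholesky factorisation; the
  package never builds meshes large enough to require iterative solvers.

## Preprocessing

* Intensities convert to optical density (`-ln(I/I0)`) and to chromophore
  changes via the modified Beer-Lambert law with DPF = 5.13 at both
  wavelengths and bundled extinction coefficients from a standard
  hemoglobin compilation (configurable).
* Temporal filters: 5th-order Butterworth high-pass at 0.008 Hz and
  band-stops over 0.06-0.16 Hz (Mayer waves) and 0.8-1.8 Hz (cardiac),
  all applied forward-backward (zero phase; effective order doubled).
  Stages are realised as cascaded biquads, and each band-stop as the
  parallel sum of a low-pass and a high-pass: at these very low
  normalised cutoffs a direct transfer-function band-stop design is
  numerically unstable (poles round outside the unit circle), while the
  biquad form is exactly linear to machine precision.  The channel mean
  is removed before high-pass filtering (DC is in the stopband; leaving
  it excites edge transients longer than the session).
* Motion artifacts are detected on the HbO series as moving-SD excursions
  above 3 uM in a 1 s centred window (truncated at the edges), and
  corrected by fitting a cubic smoothing spline to each flagged segment,
  subtracting it, and re-leveling the segment to the preceding clean mean.
  Samples outside flagged segments are never touched.  A complementary
  amplitude-excursion detector (deviation > 2 uM from a 10 s running
  median) catches slow, large residuals — e.g. the decaying tail of a
  spike — whose local variance stays under the moving-SD threshold;
  evoked channel-level hemoglobin changes are an order of magnitude
  smaller, so the criterion is conservative with respect to real signal.
* Trial averaging extracts per-condition epochs over a [-2, +22] s
  peristimulus window (9 s block + rest), baseline-shifts each epoch to
  its pre-onset mean, and averages; epochs overlapping flagged artifact
  samples can be excluded, which is how residual motion energy is kept
  out of the averages.

## Model inversion

`variationalLaplace()` implements fixed-form Gaussian variational Bayes:
Gauss–Newton ascent on the free energy F = accuracy - complexity, with
central finite-difference Jacobians (relative step 1e-4),
Levenberg-style damping, and group-wise noise log-precision
hyperparameters (one per wavelength; hyperprior N(4, 1)).  Convergence is
declared when the accepted improvement falls below 0.01 nats, with a
64-iteration cap; runs start at the prior mean (no random initialisation).
Design points that mattered in practice:

* Candidate steps are scored against the current Jacobian (one model
  evaluation each) and several Gauss–Newton moves reuse one Jacobian; the
  exact F is re-verified at the next expansion point, and only F-increasing
  iterations are recorded, so the reported trace is non-decreasing by
  construction.
* The estimated log-precision may rise by at most 2 nats per iteration.
  Without this annealing the hyperparameters jump to their fixed point
  immediately, the likelihood surface becomes extremely sharp while the
  parameters are still at the prior mean, and the optimiser crawls along
  curved ridges.  The fixed point itself is unchanged.
* On conjugate linear-Gaussian problems the engine reproduces the
  closed-form posterior to 1e-6 and the closed-form evidence to 1e-3 nats
  (the Laplace free energy is exact there).

Priors follow established DCM conventions, since the study prints none:
off-diagonal A entries N(0, n/64); self-connections parameterised as
log-scalings of -0.5 1/s with N(0, 1/256); B and C entries N(0, 1);
transit-time and stiffness log-scalings per region N(0, 1/256); and the
fNIRS scaling log k ~ N(0, 1/16).

**Fitting trial-averaged sessions.**  `dcmFitSession()` predicts the full
session from the design's stimulus functions and passes data and
prediction through the *identical* linear pipeline: (i) optional
projection out of narrowband physiological confounds (sine/cosine pairs at
the Mayer and cardiac frequencies, coefficients estimated per channel from
artifact-free samples only); (ii) the exact trial-averaging operator
(`epochAverageOperator()`, a sparse matrix encoding epoch extraction,
baseline subtraction, artifact exclusion and averaging); and (iii) a
whitening transform.  The whitening matters: under white measurement
noise, per-epoch baseline subtraction correlates the averaged samples
(every sample of an epoch average shares its baseline estimate), and
ignoring this makes the posterior roughly 25% too confident — enough to
break credible-interval calibration.  Whitening by the eigendecomposition
of E E' (dropping the exactly-null directions the baseline subtraction
creates) restores the iid noise model, after which credible intervals
are well calibrated in simulation.  Confound projection inside the fit
plays the role of the Mayer/cardiac band-stop filters with exact
data/model consistency; a zero-phase filter applied to 24 s epochs cannot
be mirrored on model predictions without edge-transient mismatch, which
we found biases coupling estimates badly.

## The 13-model space and comparison statistics

All models share the STS-driven skeleton; they differ only in which
inter-regional connection is modulated: model 1 none; models 2-5 the V
modulation on STS->TPJ, TPJ->STS, STS->IFG, IFG->STS in that order;
models 6-9 the NV modulation on the same ordered connections (model 8 =
NV on STS->IFG); models 10-13 both modulations on the same connection.
This enumeration is a reconstruction: the source study fixes the shared
structure, the count of thirteen, the parameter census (91 intrinsic, 26
input, 8 + 8 modulatory across the space) and model 8's identity, and the
chosen ordering satisfies all of these constraints.

Fixed-effects Bayesian model selection exponentiates free energies into
posterior model probabilities (single-subject setting; random-effects BMS
is out of scope).  Bayesian model averaging takes mixture moments across
models, with parameters absent from a model entering as point mass at
zero.  Cross-method agreement uses Pearson correlation, robust regression
(IRLS with Tukey's bisquare, tuning 4.685, MAD scale — `MASS::rlm` under
the hood, with F and R^2 computed on the final weighted fit), and seeded
case-resampling bootstrap intervals for the robust slope.

## The synthetic-data generator

`simulateExperiment()` emulates the study recording: a seeded block
design (12 + 12 x 9 s, rest >= 13 s, 690 s at 10 Hz), the model-8 ground
truth (inter-regional couplings 0.2-0.3 Hz, self-connections -0.5 Hz,
drives 0.3, NV modulation 0.4 — values chosen for stability and
identifiability; the study prints none), the optics observation through
the slab-head fixture sensitivities, and a BOLD twin.  Noise comprises
white noise scaled to SNR 5 (clean-signal SD over white SD on the best
channel), Mayer-band (0.1 Hz) and cardiac-band (1.2 Hz) sinusoids at 0.5
and 0.3 of the best channel's clean SD with random per-channel phases,
and motion spikes: step-plus-1 s-exponential-decay transients at Poisson
times (0.5/min), 5-15 uM equivalent, converted to optical density through
the Beer-Lambert pathlength so they dwarf the brain signal, as real
motion artifacts do.  The clean series, every noise component, and their
exact sum are all stored, and the clean series depends only on the design
seed.

What the generator does *not* emulate: superficial/systemic hemodynamics
with task-locked components, optode-coupling drift, spatially
heterogeneous noise, real infant head geometry (the slab permits an
analytic optics oracle; curvature effects are absent), or fMRI artifacts.
Passing recovery tests therefore demonstrate internal consistency of the
pipeline under the stated conditions, not performance on real data.

`recoveryExperiment()` runs the full loop — simulate, preprocess (artifact
detection and spline correction; band-limited physiological noise is
handled by the confound projection inside the fit), trial-average, fit all
13 models, select and average — and scores model recovery (how often the
generating model wins BMS), parameter recovery (coverage of the nonzero
couplings by 90% credible intervals), and, optionally, cross-modality
agreement against fits of the same models to the BOLD twin.

## Problem sizes and reproducibility

The shipped experiments use: a ~12k-node graded slab for the optics
oracle; a 5 mm slab fixture (~2k nodes) for channel-region sensitivities;
20 simulated sessions for the recovery harness (each: one 690 s
simulation, 13 variational-Laplace inversions of ~17 parameters against
8640 averaged-domain data points); and 3 of those sessions additionally
fitted in the BOLD twin for cross-modality statistics.  The acceptance
script reports a 12-session harness.  All randomness is seed-derived;
identical seeds reproduce results bit for bit.

## Known limitations

* Trial-averaged fitting with the exact averaging operator removes the
  epoching approximation, but model error from preprocessing distortions
  inside kept epochs is not represented in the noise model.
* The credible-interval calibration statement is specific to the
  generator's noise families; strongly autocorrelated (1/f) noise would
  require an explicit temporal covariance model, which is out of scope.
* The 13-model enumeration beyond its published constraints, the optode
  coordinates of the probe fixture, and all tissue/extinction constants
  are documented reconstructions or literature defaults, not study
  values.
* Fixed-effects BMS only; no hierarchical inversion, no Bayesian model
  reduction, no time-/frequency-domain photon transport.
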