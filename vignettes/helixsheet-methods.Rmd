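---
title: "Methods: the in-silico tilted light-sheet 3D localization microscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the in-silico tilted light-sheet 3D localization microscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(helixsheet)
```

# What this package models

`helixsheet` is a complete in-silico single-molecule localization
microscope. The instrument it emulates images blinking far-red dye
molecules on 3D structures in whole mammalian cells with a high-NA oil
objective, excites them with a thin illumination sheet tilted ~10 degrees
downward so the sheet can reach the coverslip without dipping any optics
into the chamber, and encodes each emitter's axial position in the *shape*
of its image rather than the position of the sheet. Two engineered point
spread functions (PSFs) carry that axial information:

* a **double-helix PSF (DH-PSF)** for the molecules — two lobes whose
  connecting line rotates with defocus over a ~2 um working range; the
  midpoint of the lobes gives x and y, the angle gives z;
* **tetrapod PSFs** with 6-10 um range for fiducial beads, which can
  therefore be tracked from any height in the cell while the focal plane
  steps through the sample.

The sample is sectioned into overlapping 1-um-spaced axial slices; a bead
at the coverslip is imaged on every twentieth frame, feeding a live axial
feedback loop during acquisition and a post-hoc lateral/axial drift
correction; the per-slice localization tables are then stitched into one
3D reconstruction.

All data the analysis consumes is produced by the package's own simulator,
which is a first-class, tested component — not a fixture. Every
calibration (angle-to-z, tetrapod templates, retrieved pupils) is
generated self-consistently from the shipped masks, which makes round-trip
accuracy a meaningful, closed test of the analysis chain.

# Optical model

## Image formation

Scalar Fourier optics on a discretized pupil: the emitted field is a
unit-amplitude disc (aperture radius = NA cutoff) times the mask phase
times a high-NA defocus phase
$\phi_z(\rho) = k n z \sqrt{1 - (\rho\,\mathrm{NA}/n)^2}$ with immersion
index $n = 1.518$; the camera image is the squared modulus of its Fourier
transform. Emitters are treated as isotropic (dipole-averaged); vectorial
effects and index-mismatch aberrations are out of scope, and this is a
stated fidelity limit, not an approximation we correct for elsewhere.

Two renderers share this model. `psf_at()` is a padded FFT on the grid's
natural pixel, used for calibration stacks and energy bookkeeping (by
Parseval's theorem total energy is defocus-independent, so unit-sum
normalization is exact; a guard errors when more than 5% of the energy
leaves the central half-field). `render_emitter()` is a direct matrix DFT
evaluated at arbitrary camera pixel positions with sub-pixel emitter
offsets — the workhorse for the simulator, the Fisher-information bound,
and the maximum-likelihood refinement.

Pixels are point-sampled at their centers rather than integrated over
their area. One measurable consequence: with 160 nm pixels the Fisher
information oscillates a few tens of percent with the emitter's sub-pixel
phase, so `crlb()` takes the emitter's sub-pixel position and comparisons
against the bound are made position-matched.

## The pupil grid

Default 256 x 256 samples with a 64-sample aperture radius (grid side 2x
the aperture diameter, the minimum that avoids FFT aliasing).
Simulation-heavy work uses a 128/32 grid; renders are ~4x cheaper and the
PSF physics is unchanged. The tests and the shipped end-to-end analysis
state which grid they use.

## Masks

* **Clear aperture** — zero phase; its focal image reproduces the Airy
  first-minimum radius $0.61\lambda/\mathrm{NA}$ to within the radial
  binning of the test (<5%), which anchors the whole Fourier machinery.
* **Double helix** — the commercial mask used on the physical instrument
  is proprietary, so the package ships its own design and calibrates
  against it. We first tried the textbook Gauss–Laguerre
  mode-superposition with a phase-only projection; on this pupil it
  produced a multi-peaked ring rather than two clean lobes, and we
  replaced it with an annular-zone construction: five equal-area Fresnel
  zones carrying azimuthal charges 0, 2, 4, 6, 8. Even charges make the
  image inversion-symmetric (hence exactly two lobes), and the defocus
  phase advancing roughly linearly across the zones rotates the pair.
  Measured behavior: strictly monotone rotation over at least ±1.2 um,
  ~100 degrees per 2 um, lobe separation ~900 nm.
* **DH, lobe-energy-optimized** — the zone design leaves ~60% of the
  energy in a halo, which a double-Gaussian estimator cannot use (its
  precision then sits 2-4x above the Cramér–Rao bound).
  `optimize_dh_mask()` runs iterative Fourier projections onto
  two-Gaussian-lobe targets placed at the seed design's own angle and
  separation at 13 defocus planes (60 iterations), raising the lobe
  energy fraction to ~0.65 while preserving the rotation law. This is the
  recommended single-molecule mask and the one the pipeline tests use.
* **Tetrapod** — the published designs come from information-theoretic
  optimization of Zernike coefficients; re-running that optimization is
  out of scope, so the package ships a fixed smooth recipe (primary plus
  secondary astigmatism, $4 Z_2^2 - 1 Z_4^2$ waves at 6 um range, scaled
  linearly to 10 um) validated by properties rather than by matching any
  external mask: the footprint grows with |z|, no two templates are
  alike, and the correlation z-estimate is strictly increasing across the
  range. The phase is smooth (deformable-mirror-realizable), which the
  tests check via a bounded finite-difference gradient.

# Illumination

The sheet is an elliptical Gaussian beam focused in one dimension:
thickness (waist radius) 2.1 um and width 19 um at 1/e², confocal
parameter 73 um, tilt 10 degrees — the measured parameters of the real
sheet. Waist and confocal parameter are mutually inconsistent with an
ideal Gaussian beam at 647 nm; we deliberately treat them as two
independent measured quantities (aberrated-sheet phenomenology) rather
than deriving one from the other. The thickness follows the hyperbolic
law $w(s) = w_0\sqrt{1+(2s/b)^2}$ along propagation with the $w_0/w(s)$
amplitude factor, so beam power is conserved (verified to <2%). Epi
illumination is modeled as z-uniform across the cell — the real epi
profile is a wide Gaussian, and the comparison between modes is
background-dominated, so the flat-epi simplification is acceptable and
stated.

Out-of-focus background integrates labeled density x illumination
intensity over the volume by deterministic quadrature, assuming the
defocused PSF redistributes photons across the field without loss
(geometric-optics blur); the field-mean background per pixel is then
independent of the blur kernel, which is why the quadrature can stay
one-dimensional in z with lateral averaging for the tilt. On a uniformly
labeled 10 um slab this gives an epi/sheet background ratio of ~3.7,
inside the 3-7x band the sheet is expected to deliver.

# The synthetic microscope

`simulate_stream()` is the fixture factory for everything downstream.
Study conditions, chosen once:

* **Camera** (EM-CCD): 50 ms exposure, calibrated EM gain 186, offset 100
  counts, conversion 10 e/count, read noise 10 e RMS, QE 0.9, 300 dark
  frames for offset calibration. EM amplification uses the standard gamma
  approximation (excess-noise factor sqrt(2)).
* **Photon budget**: 3000 expected photons per frame for a molecule at
  the sheet peak (6e4 photons/s on-state x 50 ms). Per-molecule yields
  are not published for this dye in this buffer; 3000/frame is a typical
  figure for the dye class, and all precision targets are expressed
  relative to the Cramér–Rao bound rather than absolutely.
* **Blinking**: three states (on/off/bleached), rates in 1/s with
  per-frame probabilities $1-e^{-k\Delta t}$. Defaults k_off = 10,
  k_on = 0.05, k_bleach = 0.2, initial dark fraction 0.9; the dense-shell
  end-to-end run uses k_on = 0.003 and initial dark 0.9995 so that the
  ~4600-emitter phantom keeps ~1-2 active emitters per frame — the
  sparsity a large-footprint PSF needs, achieved in the real experiment
  by initially shelving most fluorophores in a dark state.
* **Schedule**: fiducial frame every 20th frame (1-based: frames 20,
  40, ...), reactivation every 100th frame after frame 10,000, fiducial
  role winning ties; both periods are configuration.
* **Drift**: per-axis random walk, default 0.5-1 nm/frame steps —
  hundreds of nm over a long acquisition, consistent with the drift the
  instrument is built to correct.
* **Two channels**: the molecule channel (far-red, 670 nm) and the
  fiducial channel (red, 605 nm) are separate logical channels; each mask
  is rendered at its own design wavelength. (An early version rendered
  both at 670 nm; the resulting 10% defocus-phase error displaced the
  tetrapod z-estimate by ~150 nm and is exactly the class of bug the
  self-consistency tests exist to catch.)
* **Feedback**: on each fiducial frame the bead's apparent defocus is
  measured (by the real tracking code via `make_feedback_tracker()`, or
  by ground truth for unit tests) and the focal plane corrected by
  `measured - setpoint` with one frame of latency. Corrections are
  expressed in a slice-independent gauge so commanded focal steps between
  slices are not "corrected" away; the tracker's z search seed moves with
  every commanded focal change for the same reason.

The ground-truth log records every rendered emitter's drifted position,
defocus, and expected photons; re-rendering from the log reproduces the
pre-noise frame bit-for-bit, and the expected photon budget matches the
per-emitter sum to <0.5%.

# Double-helix localization

Detection runs a matched filter of two displaced Gaussians over eight
trial orientations; local maxima above a robust (median + k·MAD)
threshold become ROIs. Fitting is the field's standard double-Gaussian
estimator: least squares of two isotropic Gaussians plus constant
background, parameterized directly in (midpoint, angle, separation,
amplitudes, shared width, background). Unweighted residuals are the
default (robust at low counts); Poisson weighting is a flag.

Calibration fits every plane of a bead z-stack, unwraps the angles
(mod 180), references z = 0 to 0 degrees, and keeps the largest strictly
monotone window (≥ 2.4 um for the shipped masks at our sampling). Two
design choices deviate from common defaults and are worth recording:

* **Spline, not polynomial, inversion.** The zone-design angle curve has
  ~0.2 degree ripple; a 5th-order polynomial fit leaves residuals worth
  4-5 nm of systematic z bias, which is large against a ~2.5 nm bias
  budget (0.2x the empirical precision). Inversion therefore goes through
  a monotone (Hyman) cubic spline of the calibration table; the
  polynomial is still fitted and stored for reporting.
* **Full-model MLE refinement.** Measured against the position-matched
  CRLB, the bare double-Gaussian estimator plateaus at 1.2-1.6x the bound
  — structural information loss (the halo and the lobe-shape detail carry
  real Fisher information). `refine_localization()` maximizes the Poisson
  likelihood of the actual diffraction model over (x, y, z, photons,
  background), seeded by the double-Gaussian fit, implemented as least
  squares on Poisson deviance residuals; with it the chain is unbiased
  (<1.5 nm) and sits at 0.9-1.05x the bound. In a real instrument the
  model would come from a phase-retrieved pupil; here simulator and
  estimator share the shipped mask by construction.

Quality filtering drops fits by residual (default 3; the EM-noise floor
of the normalized residual is ~1.4), lobe asymmetry (2.5:1), separation
deviation from calibration (20%), photon minimum (500), and calibration
z range, each drop tagged with its reason.

# Tetrapod fiducial tracking

Template matching against a fine (100 nm) z grid of renders: normalized
cross-correlation per template, parabolic sub-step interpolation in z,
parabolic sub-pixel peak in xy, followed by the same full-model MLE
refinement, which removes the interpolation biases (up to ~50 nm in xy,
~14 nm in z at range edges) entirely. Round trips are then exact to <1 nm
noiselessly, and Monte-Carlo precision at 1e6 photons is nm-scale with
σ_xy < σ_z near focus — the regime the real instrument reports for
fiducial detection. Dropouts (correlation below 0.35) hold the previous
position and are interpolated in the track.

`retrieve_pupil()` recovers the pupil phase from a measured bead z-stack
by alternating projections (replace model magnitudes with measured ones
plane by plane, unwind defocus, average, re-impose the unit-amplitude
aperture), with a mild complex-domain Gaussian smoothing between
iterations standing in for low-order modal regularization — smooth,
DM-realizable phases are the design space, and smoothing the complex
field avoids phase-unwrapping pathologies that a direct Zernike fit of a
wrapped multi-wave phase would hit. Retrieval is judged in the image
domain (piston/tip/tilt are gauge freedom; residual tilt is removed by
centering the focal image): noiseless self-consistency <2% normalized
RMS, <5% at 1e5 photons/plane.

# Drift correction and stitching

Fiducial tracks are interpolated linearly to all frames (drift is slow
against the 20-frame interleave), multiple beads combine by
inverse-variance weights from each track's detrended scatter, and the
axial trace adds back the commanded focal position so that intentional
slice steps survive correction. Closed-loop feedback against a linear
drift leaves a sawtooth residual bounded by (interleave period x drift
rate) — checked as arithmetic, and end-to-end in the lamina run.

Stitching cross-correlates adjacent slices' localization histograms in
the overlap (the 2 um DH range against 1 um steps guarantees overlap),
with a parabolic sub-bin peak, 10 nm bins, chained from the bottom slice.
The default 1D z histogram fails informatively on one important phantom:
a spherical shell's z marginal is *uniform*, so there is nothing to
align and the correlation peak is spurious. The `method = "xyz"` option
bins laterally as well and correlates over z lags only, anchoring the
axial alignment with the lateral structure; that is what the shell
pipeline uses, and it recovers injected offsets to a few nm.

# Rendering and measurement

Histogram and Gaussian-splat renderings in any axis pair (or 3D), with
mass conserved up to boundary clipping. `linescan_fwhm()` averages across
a scan width, fits Gaussian + constant, and returns 2.3548σ; the
convolution identity FWHM² ≈ thickness² + (2.3548σ_loc)² is verified
both on constructed shells and in the end-to-end run, where the rim
width is taken from the radial-distance histogram of all localizations
(a pole line scan would rest on ~15 points at desk scale) and σ_loc is
the robust (MAD) core of the truth-matched radial errors — the Gaussian
core fit and the robust σ describe the same population, with the heavy
tail absorbed by the fit's constant term. `measure_sbr()` reports
(peak − annulus background)/annulus background with the annulus at 2-3x
the PSF footprint radius.

# Problem sizes

The shipped analyses and tests run at desk scale, chosen once: pupil
grids of 128 samples for simulation-heavy paths; localization round
trips on a 3 x 3 x 5 position grid with 25 repeats per position; the
end-to-end lamina run uses a 1.2 um radius shell (center 2 um above the
coverslip, thickness 100 nm, 250 labels/um², ~4600 emitters), two slices
at 1.5 and 2.5 um with 900 frames each, one coverslip bead, and yields
~1400 accepted localizations. A full-cell acquisition differs only in
field, slice count, and frame count.

# What passing tests do and do not show

The simulator shares its forward model with the estimators, so the suite
demonstrates internal correctness — unbiasedness, bound-limited
precision, drift/stitch recovery — under the stated noise model. It does
not demonstrate robustness to the mismatches real data carry: index
mismatch and depth aberrations, dipole orientation effects, non-uniform
and structured background, fluorophore photophysics beyond three states,
chromatic offsets between channels, or a PSF that differs from its own
calibration. Those are the stated non-goals of the model, and the
quantities the package reports from real-scale claims (lamina widths of
order 100-130 nm, tens-of-nm molecular precision) enter only through the
measurement operators, never as asserted constants.
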