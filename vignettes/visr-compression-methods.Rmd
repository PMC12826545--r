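---
title: "Methods: simulating and analysing VisR measurements under surface compression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing VisR measurements under surface compression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visrcomp)
```

## Overview

Viscoelastic Response (VisR) ultrasound applies two consecutive acoustic
radiation force impulse (ARFI) excitations at a focal depth, tracks the
micrometre-scale axial displacement of the tissue through slow time, and
fits the displacement to a one-dimensional mass–spring–damper (MSD) model.
Because the applied force amplitude is unknown in vivo, the fitted spring
and damper constants are *relative*: relative elasticity (RE) and relative
viscosity (RV), per unit force. Peak displacement (PD) — the maximum
tracked displacement — is a model-free compliance surrogate. Rotating the
probe about its axis changes the alignment between the push geometry and
the tissue's axis of symmetry (AoS); in transversely isotropic (TI) tissue
such as mammary tissue the metrics therefore vary with a 180° period, and
the degree of anisotropy (DoA) is estimated from an ellipse fitted to the
per-angle values.

`visrcomp` implements this measurement chain end to end on synthetic
tissue, for studying how practitioner-applied surface compression
(pre-loading) perturbs PD, RE, RV and DoA. No clinical RF data is
distributed or required: a seeded generator produces cohorts whose
statistical structure mirrors the emulated protocol — 40 beam lines over a
2-cm field of view at a 20-mm focus, acquisitions at 0/2/5 mm compression
× 0/30/60/90° imaging angle, two pushes (300 cycles at 4.21 MHz) separated
by 8 tracking pulses with 43 more after, at an 11.5-kHz PRF.

## The mass–spring–damper model

Displacement obeys

$$ m_0\,\ddot x + \mathrm{RV}\,\dot x + \mathrm{RE}\,x = f(t), $$

with $f(t)$ equal to the (unit) force amplitude during each push window
(duration $300/4.21\,\mathrm{MHz}\approx 71\ \mu s$) and zero otherwise,
and $x(0)=\dot x(0)=0$. `msd_response()` evaluates the exact piecewise
closed form of this linear ODE (no numeric integrator); the test suite
checks it against an independent fourth-order Runge–Kutta integration at
$\Delta t = 10^{-4}$ ms to better than 0.1%.

**Units and the nominal mass.** Only ratios to the applied force are
identifiable, so the model is expressed per unit force: RE in 1/µm, RV in
ms/µm, and the relative mass fixed at the nominal constant
`visr_mass()` = $10^{-3}$. The constant is deliberately small: soft-tissue
ARFI response is inertia-negligible (Voigt-like), and in this regime a
unit push produces micrometre-scale displacement (PD ≈ push duration / RV)
with millisecond recovery (time constant RV/RE), matching the scales the
tracking stage must resolve. The choice also makes the per-unit-force
semantics exact: scaling the displacement curve by a factor rescales the
fitted (RE, RV) by its inverse. The same constant is used by the generator
and the fitter; it is a unit convention, not an estimate, and none of the
downstream analyses (ratios, percent changes, DoA) depend on it.

## Synthetic tissue and RF speckle

A `tissue_phantom()` is a uniform random field of point scatterers with
standard-normal amplitudes, ≥ 10 per resolution cell (fully developed
speckle), carrying per-layer mechanical ground truth: longitudinal and
transverse RE/RV, the AoS orientation (drawn uniformly in [0, 180), since
the in-vivo alignment is unknown a priori), and a per-mm compression
stiffening rate. The angular modulus law is the polar ellipse

$$ r(\theta) = \frac{ab}{\sqrt{b^2\cos^2\Delta + a^2\sin^2\Delta}},
\qquad \Delta = \theta - \mathrm{AoS}, $$

which is more accurate than a sinusoid at high anisotropy. Surface
compression by $d$ mm is modelled as uniform axial strain $d/20$ relative
to the focal depth (so 0/2/5 mm ≈ 0/10/25% strain; scatterers shift toward
the transducer by exactly strain × depth) together with geometric modulus
stiffening $(1+s)^d$. The sign of $s$ is not constrained: poroelastic
stiffening is expected, but in-vivo responses go both ways, so the
generator exposes it as a distribution rather than asserting a regime.

RF synthesis superposes a Gaussian-enveloped cosine pulse at the tracking
frequency (6.15 MHz, 2 cycles, envelope FWHM equal to the pulse duration)
at each scatterer's instantaneous round-trip delay, with a Gaussian
lateral beam profile (σ = 0.3 mm), sampled at 40 MHz with c = 1540 m/s,
plus seeded white noise at a configured SNR (default 20 dB). Scatterer
motion follows the MSD response of the scatterer's layer at that
acquisition's angle-dependent moduli. Deliberately *not* modelled:
diffraction of the physical aperture, elevational beam structure, depth-
dependent force profiles, nonlinear or 3-D mechanics, and physiologic
motion. Passing tests therefore demonstrate correctness of the estimation
chain on speckle with realistic statistics — not robustness to beam-shape
or motion artefacts of clinical data.

## Displacement tracking

`ncc_track()` estimates axial displacement per kernel, slow-time event and
line by zero-normalized cross-correlation against the mean of the two
reference events, with a 376-µm kernel, an 80-µm search region, spline
upsampling of the correlation by a factor of 4 and a final parabolic
vertex refinement. Kernels overlap 75% (axial pitch ≈ 94–96 µm, one
kernel-rounding away from nominal). Estimates with peak correlation below
0.8 are flagged invalid; both thresholds are configurable.

Two numerical choices matter here:

* **Reference re-zeroing.** Peak interpolation on the asymmetric speckle
  correlation function carries a per-kernel bias of a few tenths of a
  micron even on noise-free data. The motionless reference events measure
  exactly that bias, so each pixel's curve is re-zeroed on its own
  reference-event estimates. This cuts the noise-free pixel-to-pixel
  spread of fitted RE on a homogeneous phantom to under 10% and leaves
  displacement still defined relative to the reference mean.
* **Noise floor.** At 20 dB SNR the per-estimate jitter is ≈ 0.8–0.9 µm
  RMS, which is at the information-theoretic (Cramér–Rao) limit for a
  376-µm kernel at 6.15 MHz: the bound for these settings is ≈ 0.5 µm
  with a noise-free reference, before speckle and windowing losses.
  Per-estimate RMS error on known rigid shifts stays below 1 µm; the
  sub-0.5-µm "static floor" applies to the ensemble-averaged displacement
  of a motionless pixel, not to single estimates.

## Per-pixel fitting and parametric maps

`fit_msd()` solves the bounded nonlinear least-squares problem in
log-parameter space with a 3 × 3 multi-start grid (the error surface can
be multimodal for noisy curves), using all events from the first push
onward so both push responses constrain the fit. `visr_image()` maps a
whole displacement field; its default engine evaluates every pixel
against shared banks of closed-form model curves on a hierarchical
log-spaced grid (coarse 26 × 22, then an 11 × 11 refinement around the
coarse minimum, then a quadratic vertex interpolation), which agrees with
the iterative fitter to within a few percent at a small fraction of the
cost; `engine = "optim"` runs the full optimizer per pixel. Pixels with
fewer than 10 valid post-push events, or flat curves, are masked invalid.

## Regions of interest

Quantitative analysis uses pixels within 3 mm axially of the focal depth
and 3 mm laterally of the image centre (`focal_roi()`; the symmetric
axial reading is the default, with an `above_only` option). Because
compression moves tissue through a depth-fixed ROI, `matched_roi()`
implements the feature-matched alternative: `bulk_shift()` estimates the
axial displacement of image features between compression levels from the
mean per-column correlation of envelope images, the ROI is translated to
follow the tissue, then cropped back to within 3 mm of the focus so
forcing conditions stay comparable. Both policies are reduced to
per-acquisition scalars by `roi_reduce()` (medians of valid pixels, with
a 25% minimum-validity flag) and reported side by side; medians rather
than means are used throughout for robustness, which also fixes an
ambiguity in how per-angle values enter the ellipse fits.

## Anisotropy

`fit_ellipse()` fits the polar ellipse to the four per-angle ROI medians
by least squares with a multi-start over orientation (15° steps),
enforcing $a \ge b$ by axis swap + 90° rotation. With 4 points and 3
parameters the fit is near-interpolating; $R^2$ is still reported, and a
degenerate circle ($SS_{tot}=0$) reports $R^2$ as undefined rather
than 1. The four protocol angles span a half-period at Nyquist sampling,
so the ellipse is fully determined; other angle sets are accepted but
flagged out-of-protocol. PD-derived orientation is phase-inverted
relative to RE (compliance vs stiffness), which the tests check as a
cohort-median alignment of the PD major axis with the RE minor axis.

## Cohort statistics

The statistics layer mirrors the emulated analysis: percent change
between the 0–2, 2–5 and 0–5 mm levels (a force-normalized, multiplicative
metric), baseline normalization by the 0-mm value, angle-averaged and
extreme-angle ("minimum/maximum angle", chosen from the 0-mm per-angle
values, ties to the smallest angle) summaries, Kruskal–Wallis tests of
the ROI pixel distributions across compression levels within each
patient, Wilcoxon rank-sum tests (exact enumeration for groups of ≤ 10
without ties) for dense vs non-dense contrasts, and a Bonferroni-adjusted
threshold of $0.05/(12 \times 20) \approx 2.08\times10^{-4}$, reading the
12 as 3 metrics × 4 angles per patient. The rank tests delegate to the
standard tie-corrected implementations in base R behind this interface.

## The synthetic cohort as study conditions

`make_cohort()` draws, per subject: ground-truth DoA uniform in
[1.5, 3.5] (shared by RE and RV, consistent with stiffness and viscosity
varying in phase; mammary-tissue anisotropy in this class of measurement
is mostly in the 2–4 range), transverse RV uniform in [0.006, 0.010]
ms/µm (peak displacements of roughly 2–12 µm across angles and
compressions), recovery time constant uniform in [0.4, 1.0] ms, AoS
uniform in [0, 180), and stiffening per mm uniform in [0.04, 0.08] for
the dense group vs [0.01, 0.04] for the non-dense group — dense tissue
stiffens more under compression, and the implied 0→5 mm modulus changes
(≈ 5–47%) bracket the percent-change scale of the emulated setting. One
master seed drives everything; per-subject and per-acquisition streams
are derived with a fixed multiplicative scheme, so any acquisition can be
regenerated in isolation and full reruns are bit-identical at the scalar
level. RF ensembles are realized lazily (one acquisition at a time)
because the 240-ensemble cohort would occupy gigabytes if materialized.

Problem sizes used in the shipped validation: the protocol-scale study is
20 subjects × 12 acquisitions at full 40-line geometry; unit tests
exercise the same chain on reduced lateral extents (10–12 lines) where
protocol scale is not the property under test.

## Known limitations

* The MSD reconstruction is self-consistent (generator and fitter share
  one model) but not guaranteed identical to any particular clinical
  implementation's parameterization or windowing.
* The PD ellipse is an approximation: PD is a nonlinear functional of the
  angular moduli, so PD-derived DoA is mildly biased relative to the
  modulus ratio even noise-free.
* Bulk-shift estimation assumes axial-only feature motion and degrades
  (flagged via its correlation attribute) at high strain, where speckle
  decorrelates.
* Invalid-estimate handling, the reference-frame choice and the ROI
  scalarization are exposed as configuration; their fidelity to any
  specific clinical processing chain is unknown.
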