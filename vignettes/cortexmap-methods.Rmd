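---
title: "Measuring myosin penetration into the actin cortex: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring myosin penetration into the actin cortex: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexmap)
```

# The scientific problem

The actomyosin cortex is a thin (~150-300 nm) actin network under the
plasma membrane of animal cells; nonmuscle myosin II minifilaments pull
on it and set the cell's surface tension. Whether myosin motors reach
through the whole thickness of the actin layer, or only engage its inner
(cytoplasmic) face, changes how much tension a given amount of myosin
can produce. cortexmap implements the quantitative machinery needed to
answer that question from four kinds of measurements:

1. **Two-colour SMLM (dSTORM)** of the equatorial cortex: per-molecule
   localization tables are drift- and chromatically corrected, rendered
   as density maps, and the straightened cortex yields per-bin FWHMs,
   peak-to-peak distances and the signed *cytoplasmic overhang*.
2. **Two-colour SIM** of myosin minifilaments: bipolar ~300 nm dumbbells
   (two head spots flanking a tail spot) are detected and their
   projected lengths converted to orientation angles and a
   relative-tension factor.
3. **Confocal linescans** across the cortex: a step-convolution model
   yields the actin cortex thickness `h_actin` and the myosin
   penetration depth `h_myo`; their difference is the myosin-free
   cortex length.
4. **AFM parallel-plate compression**: the relaxed force plateau plus
   the cell geometry gives the cortical tension, and drug-addition
   transients are quantified as normalized mean/max force ratios.

Every input has a seed-deterministic synthetic generator with recorded
ground truth, so the full pipeline is testable end to end without any
microscope data.

# Conventions

Coordinates are continuous nanometres with the origin at the corner of
pixel (1, 1); matrix rows index y and columns x, and pixel centres sit
at `(j - 0.5) * pixel_size`. The transverse axis across the cortex is
signed, **positive toward the cytoplasm**. FWHM intervals are closed;
`hi` denotes the cytoplasmic edge.

# SMLM post-processing

## Rendering

Each localization contributes a unit-mass isotropic Gaussian whose SD is
its own localization uncertainty (drawn from a truncated normal with
mean 20 nm, SD 10 nm in the synthetic scenes, matching typical dSTORM
performance). Gaussians are truncated at 4 sigma (relative mass error
< 1e-4) and the map is multiplied by 100, a constant that protects
against digitization artifacts and cancels from all downstream
measurements. The default rendering pixel is 10 nm so that the 200 nm
analysis bins along the cortex span 20 pixels.

## Drift correction

Two estimators are provided. `track_fiducials()`/`drift_from_beads()`
follow always-on fiducial beads; each bead is anchored on its mean
position over the first smoothing window (rather than the raw first
frame) so the zero reference is not contaminated by single-frame
jitter, and bead tracks are averaged (equal weights by default,
inverse-variance optionally) and smoothed with a 50-frame moving
average.

`drift_rcc()` implements drift estimation from the sample itself: the
acquisition is cut into consecutive 2000-frame windows, each window's
localizations (optionally restricted to a cortical region of interest)
are histogrammed with 20 nm sub-pixels, successive histograms are
cross-correlated, and the correlation peak is refined with a 3-point
parabolic fit. Cumulative shifts sit at window midpoints and a natural
cubic spline interpolates to every frame. Histograms are smoothed with
a 2-bin Gaussian before correlation; this widens the correlation peak
enough for the parabolic refinement to be stable on sparse histograms.
An all-pairs least-squares mode (`pairs = "all"`) adds redundancy and
reduces the random walk of accumulated successive shifts. Drift is
defined only up to a constant reference offset (the first window is the
reference); accuracy statements therefore refer to the offset-free
trajectory. Under the synthetic study conditions (60,000 cortical
localizations over 20,000 frames) linear drift is recovered to ~3-6 nm
RMS and a 50 nm-amplitude sinusoid to well within 15 nm RMS; the
residual for oscillatory drift is dominated by the spline's boundary
extrapolation beyond the outermost window midpoints.

## Chromatic registration

An affine transform (scaling, rotation, shear, translation) is fitted by
least squares on matched bead positions (mutual nearest neighbours
within 300 nm); three non-collinear pairs are the minimum. The fit is
exactly invariant to bead relabelling, and noiseless beads recover a
known transform to numerical precision.

# Cortex straightening and the overhang statistic

The cortex is detected on the actin channel: each seed point of a coarse
polyline is moved along its local normal to the transverse intensity
maximum (parabolic sub-pixel refinement; points diverging beyond the
search half-width or sitting over holes are dropped), and a cubic
smoothing spline is fitted through the survivors, parameterised by arc
length. The inward normal points toward the cytoplasm — by default
toward the centroid of the refined points, appropriate for closed,
convex cell outlines; an explicit side flag covers open contours.

Straightening samples every channel along the spline normals at the
rendering pitch by bilinear interpolation; for a circular cell of
radius R the residual curvature-induced width error over a half-width w
is below `w^2 / (8 R)` (about 12 nm for w = 500 nm, R = 2.5 um, and
entirely common to both channels, so it cancels from the overhang).
Profiles are averaged in 200 nm bins along the cortex; bins containing
rows whose normals left the image are excluded and an incomplete
trailing bin is dropped.

Per bin and channel, the background is the mean of the two per-side
medians of the outer 20% of samples; the peak is the
background-subtracted maximum with parabolic refinement; and the FWHM
interval is bounded by the innermost half-maximum crossings bracketing
the peak, located by linear interpolation. Profiles without an interior
peak or truncated before a crossing are rejected with reason codes.

With the actin interval `[a_lo, a_hi]` and target interval
`[t_lo, t_hi]` on the signed axis, the **cytoplasmic overhang** is

    100 * (t_hi - a_hi) / (t_hi - t_lo)  percent.

It is positive when the target protrudes beyond the actin layer into
the cytoplasm and negative when the target's cytoplasmic edge is
retracted toward the membrane (as for the membrane linker moesin). This
single-edge signed form is the minimal definition consistent with a
non-overlap percentage that can take negative values; the symmetric
two-sided non-overlap is available (`nonoverlap_interval()`) but off by
default. Per-cell values average the accepted bins (mean by default,
median optionally; at least 3 accepted bins are required).

Out-of-plane curvature can only inflate the measured FWHM; the worst
case for a spherical cell of radius R imaged with a slab of thickness t
is `2 (R - sqrt(R^2 - (t/2)^2))` — about 2 nm for R = 5 um, t = 200 nm —
and `curvature_broadening_bound()` evaluates it.

## What the synthetic scenes do and do not emulate

`gen_smlm_cortex()` draws molecules on annular bands (uniform angle,
Gaussian radial profile of stated FWHM), adds localization error equal
to each molecule's uncertainty, injects cumulative drift, applies the
chromatic affine to one channel, and places always-on fiducial beads.
Each molecule appears in exactly one random frame: multi-frame blinking
statistics are not modelled because no downstream analysis uses them.
The scenes are 2D; microvilli, label-density variation along the
cortex, and 3D cortex structure are not emulated, so passing tests
demonstrate the correctness of the measurement chain, not robustness to
those real-data features (the pipeline's rejection codes and manual
ROI support are the tools for them). Under the default study
conditions (20,000 localizations per channel, 2.5 um cell radius,
20 +/- 10 nm uncertainty), recovered overhang tracks truth with slope
1.0 +/- 0.03 and per-condition bias of ~1 percentage point; the
rendering convolution widens both FWHMs (in quadrature with
2.355 * uncertainty), which slightly compresses the overhang scale —
an effect within the stated slope tolerance.

# Minifilament detection and the angle/tension chain

Processing follows the standard spot-detection recipe: large-radius
Gaussian background homogenization (default 500 px; the signed residual
is kept because zero-clipping would destroy the background noise
statistics that the later threshold is estimated from),
Richardson-Lucy deconvolution with a Gaussian PSF (default 20
iterations; the iteration is stopped early if the estimate norm
diverges; a signed input is shifted up by its minimum, which survives
as a flat plateau), thresholding at the background level plus 3 SD of a
user-chosen cell-free region, and an erosion-style cleanup that removes
pixels with fewer than two above-threshold 8-neighbours. A strict 3x3
box erosion was rejected: after 20 RL iterations real spot cores are
~2 px wide and a box erosion deletes them along with the noise; the
neighbour rule removes exactly the isolated white-noise pixels the
erosion is meant for. Peaks are strict 8-neighbour maxima refined to
the intensity centroid of the surrounding 5x5-pixel region; refined
duplicates within one pixel are merged.

All pairs of head peaks separated by 200-400 nm are candidates and a
candidate is validated if a tail peak lies within 50 nm of its
midpoint; a head may serve several candidates (all-pairs rule, matching
the detection definition), with an optional greedy conflict resolution
off by default. Analysis is restricted to the image interior by one
maximum pairing distance.

Assuming the true minifilament length is constant, the angle to the
membrane plane is `acos(L_proj / L_ref)` with `L_ref = 317` nm by
default (the stress-fiber value; 330 nm from electron microscopy is the
documented alternative), and the equal-contribution cosine model turns
an angle change into a relative tension change
`100 (cos(theta_after) / cos(theta_before) - 1)` percent — equal to the
percent change in projected length at fixed reference. The default
angle aggregation applies the arccosine to the per-cell mean ratio.

The synthetic scenes use a uniform out-of-plane angle on
`[0, theta_max]` (default 30 degrees): the cortex constrains
minifilament orientation, and no empirical distribution is available,
so the choice is exposed as a parameter rather than asserted. The
background field's correlation scale defaults to ~12 um, i.e. larger
than the homogenization radius — the high-pass homogenization step can
only remove background varying at scales above its radius, which is
also true of the real out-of-focus background it targets. Under the
default conditions (25 filaments per 10 x 10 um field, SIM-like 60 nm
PSF sigma, photon and read noise) detection precision and recall are
~0.99 and the mean projected-length error ~2 nm.

# Confocal quantification

Background is removed with a grayscale top-hat: an opening with a flat
disc of radius 50 px (the cortex is ~8 px wide) estimates the
background surface, implemented with EBImage morphology on intensities
normalized to [0, 1]. Two independent segmentation routes run on every
image: (i) threshold at the mean + SD of a user-chosen empty region,
with a 3x3 binary opening to remove noise speckle before components are
labelled, and (ii) Sobel gradient magnitude above mean + 3 SD, filled,
cleaned and split by a watershed on the distance map. Candidates from
both routes are grouped by centroid proximity (20 px default) and the
candidate whose outline carries the highest total intensity wins, its
provenance recorded. Objects clipped by the field of view are
discarded. Per cell, the cortical intensity is the mean over an 8 px
band centred on the outline, and unspecific staining is corrected by
subtracting the mean of secondary-antibody-only controls (negative
corrected values are allowed and flagged).

## Step-convolution linescan fits

The fluorophore density across the cell edge is piecewise constant —
`i_out` outside, `i_cort` over `[X_m, X_m + h_actin]`, `i_in` inside —
and the observed linescan is this profile convolved with a Gaussian PSF
(`sigma_psf` is a calibration input, default 170 nm). The erf-based
closed form is shared verbatim between the generator and the fitter, so
a zero-noise synthetic scan is reproduced exactly. The fit frees `X_m`,
`h_actin`, `i_cort`, `i_in` (with `i_out` taken from the extracellular
tail median), multistarts the thickness over 50-400 nm in steps of
50 nm, and keeps the best residual. Two numerical guardrails avoid the
degenerate thin-slab corner of the likelihood valley: slabs below 20 nm
are excluded (optically meaningless at this PSF) and the cortical
density is capped at 20x the observed background-subtracted peak. When
`sigma_psf` is below half the sampling step the convolution model is
degenerate and the plateau width is read directly from the half-level
crossings.

A single linescan determines `h` only weakly when `h` is comparable to
`sigma_psf` (the slab width trades against its density); profiled
residual analysis puts the single-scan SD at ~40-80 nm for 5% noise at
h = 150-250 nm, shrinking as h grows. Estimates are close to unbiased —
the Monte-Carlo bias pooled across the 100-350 nm grid is below 5 nm —
but per-scan scatter of this size is intrinsic, which is why practical
thickness estimates average many linescans.

Myosin is a slab of width `h_myo` whose cytoplasmic edge is pinned at
the fitted `X_m + h_actin`, extending toward the membrane; its width
and levels are fitted the same way, a fitted `h_myo` exceeding
`h_actin` is clipped with a warning (full penetration), and the
**myosin-free cortex length** is `h_actin - h_myo`.

# AFM cortical tension

After the compression peak the force relaxes (20-30 s) to a plateau;
`extract_plateau()` averages the force from the end of the relaxation
window to drug addition or the curve end and reports the residual
slope (plateaus with slope above 0.02 nN/s are flagged
non-stationary). For a cell compressed between parallel plates, the
contact area follows from the equatorial cross-section and the
compressed height as `A_c = A_mid - (pi/4) h_cell^2` with
`r_c = sqrt(A_c / pi)` — the relation is applied as an area balance;
the alternative literal reading of the printed relation as a perimeter
is dimensionally inconsistent and not used — and the force balance at
the contact line gives

    T = F (r_mid^2 / r_c^2 - 1) / (2 pi r_mid),

in nN/um = mN/m. The ~8 degree cantilever tilt is neglected. Cell
height is the difference of cantilever z positions on the cell and on
the glass.

Drug transients are analysed on the Savitzky-Golay-smoothed curve
(window 21 samples, order 3; the filter reproduces polynomials up to
its order exactly): the baseline is the mean force over the 20 s before
drug addition and the outputs are mean(post)/baseline and
max(post)/baseline over the 300 s after it. A transient rise with
subsequent decay gives max ratio > 1 and mean ratio < 1 (the low-dose
signature); an immediate monotone drop gives max ratio ~ 1 and mean
ratio < 1 (high dose).

# Group statistics

Distributions are tested for normality with the D'Agostino-Pearson
omnibus K2 test (implemented from the standard 1990 transformed
skewness/kurtosis formulas and verified against an independent
implementation; it requires n >= 8, so smaller groups force the
nonparametric branch). If both groups pass at alpha = 0.05, a
two-tailed Welch's t-test is used; otherwise the two-tailed
Mann-Whitney U test, exact for small tie-free samples and
tie-corrected otherwise. Boxplot summaries report type-7 quartiles,
the median, and min-max whiskers.

# Problem sizes used in the tests

The test-suite scenes are desk-scale choices: 20,000 localizations per
SMLM channel on a 2.5 um-radius cell (drift scenes use 60,000 over
20,000 frames), 25 minifilaments per 256 x 256 SIM field, 128 px
confocal fields, 20 nm linescan sampling over 5 um, and 10 Hz force
curves. They are large enough that the estimators' statistical errors
sit well inside the stated tolerances, while a full check of the
pipeline runs in minutes.

# Known limitations

- The SMLM scenes are 2D and blink-free; drift estimation quality on
  real data with sparse cortical signal depends on the chosen ROI.
- The FWHM innermost-crossing rule is slightly biased narrow on noisy
  per-bin profiles; the bias is common-mode between channels and
  largely cancels in the overhang.
- Single-linescan thickness estimates carry tens of nanometres of
  scatter near `h ~ sigma_psf`; average many linescans.
- The minifilament angle model assumes a rigid, constant-length
  dumbbell and equal tension contribution per minifilament.
- Segmentation is tuned for rounded (ring-like) cells; spread cells
  with complex outlines may need the manual ROI entry points.
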