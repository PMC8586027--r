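# cortexmap

Quantitative analysis of actomyosin cortex architecture and tension.

The actin cortex of animal cells is a thin (~150-300 nm) network under
the plasma membrane; bipolar myosin II minifilaments (~300 nm dumbbells)
pull on it and set cortical tension. Whether myosin penetrates the whole
actin layer or engages only its cytoplasmic face determines how
efficiently it can generate tension. cortexmap implements the complete
measurement chain used to address this question, for people analysing
super-resolution, confocal and AFM data of the cell cortex:

- **SMLM post-processing** — drift correction by fiducial tracking or
  redundant cross-correlation of 2000-frame windows (20 nm sub-pixels,
  spline interpolation), chromatic affine registration from multicolour
  beads, and Gaussian density-map rendering (per-molecule sigma = its
  localization uncertainty, map x100).
- **Cortex profiling** — spline-based cortex straightening, 200 nm bins,
  per-bin FWHM and peak-to-peak distance, and the signed **cytoplasmic
  overhang**: with the actin FWHM interval `[a_lo, a_hi]` and target
  interval `[t_lo, t_hi]` on an axis pointing into the cytoplasm,
  `overhang = 100 (t_hi - a_hi) / (t_hi - t_lo)` %.
- **Minifilament geometry** — two-channel SIM spot detection
  (homogenize, Richardson-Lucy, 3-sigma threshold, 8-neighbour maxima,
  5x5 centroids), all-pairs head pairing at 200-400 nm validated by a
  tail peak within 50 nm of the midpoint, then
  `theta = acos(L_proj / L_ref)` and the cosine tension model
  `dT/T = cos(theta_2)/cos(theta_1) - 1`.
- **Confocal quantification** — rolling-ball background subtraction,
  dual (threshold + edge/watershed) segmentation with
  highest-contour-intensity selection, 8 px cortical band intensities,
  and step-convolution linescan fits for the cortex thickness
  `h_actin`, the myosin penetration `h_myo`, and the myosin-free cortex
  length `h_actin - h_myo`.
- **AFM tension** — plateau extraction after the compression peak,
  `A_c = A_mid - (pi/4) h_cell^2`, `r_c = sqrt(A_c/pi)`, and
  `T = F (r_mid^2/r_c^2 - 1) / (2 pi r_mid)` (nN/um = mN/m), plus
  Savitzky-Golay-smoothed drug-response ratios.
- **Statistics** — D'Agostino-Pearson-gated choice between Welch's
  t-test and the Mann-Whitney U test, and boxplot summaries.

Every input has a seed-deterministic synthetic generator
(`gen_smlm_cortex()`, `gen_sim_minifilaments()`, `gen_linescan()`,
`gen_force_curve()`, `gen_confocal_cells()`) with recorded ground
truth, so the whole pipeline can be exercised and validated without any
microscope data. Real data enter as ThunderSTORM-dialect localization
CSVs, TIFF images (pixel size in a JSON sidecar) and force-curve CSVs.

## Worked example

Simulate a two-colour dSTORM scene of an equatorial cortex whose myosin
band is 40 nm deeper and slightly wider than the actin band, then
recover the overhang:

```r
library(cortexmap)

scene <- cortex_scene(target_band = list(offset_nm = 140, fwhm_nm = 220,
                                         n = 20000))
sim <- gen_smlm_cortex(scene, seed = 1)
sim$truth$true_overhang_pct
#> [1] 22.72727

ext <- c(0, 8000, 0, 8000)
actin_img <- render_localizations(sim$actin, 10, extent = ext)
myo_img   <- render_localizations(sim$target, 10, extent = ext)
result <- measure_cortex_overhang(actin_img, myo_img,
                                  circle_seed(c(4000, 4000), 2500, 72))
glance(result)
#> # A tibble: 1 x 6
#>   n_bins n_rejected actin_fwhm_nm target_fwhm_nm peak_to_peak_nm overhang_pct
#> 1     77          0          195.           208.            36.0         28.8
```

All 77 bins along the cortex were accepted; the myosin peak sits 36 nm
deeper than actin (truth: 40 nm) and 28.8% of the myosin FWHM protrudes
beyond the actin layer (truth: 22.7%; single-cell estimates scatter by
a few percentage points, and averaging cells — as the per-cell test
suite does over 20 seeds — recovers the truth with |bias| < 3 points).

The minifilament angle/tension chain from mean projected lengths:

```r
angle_from_projection(295, 317)   # interphase
#> [1] 21.47156
angle_from_projection(305, 317)   # mitosis
#> [1] 15.81533
tension_change_from_angles(21.47156, 15.81533)
#> [1] 3.389831
```

A flattening from ~21.5 to ~15.8 degrees raises tension by only ~3.4%
under the equal-contribution cosine model — too small to explain a
mitotic tension increase on its own.

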