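---
title: "Modelling and compensating positioning errors of a motorized microscope stage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and compensating positioning errors of a motorized microscope stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagecal)
```

## The problem

Vision-guided micromanipulation (microinjection, nucleus transfer,
microdissection) positions cells by converting a pixel offset measured in
the microscope image into a motion command for a motorized X-Y stage.
Three systematic error sources corrupt that conversion:

1. **Radial lens distortion.** The microscope's optical train is not an
   ideal pinhole; straight rulings image as slightly bowed curves.  We
   model a single second-order radial term: an observed point $(u, v)$
   relates to its theoretical (undistorted) projection by
   $\tilde u = u + k\,(u - u_0)\,r^2$, $\tilde v = v + k\,(v - v_0)\,r^2$
   with $r^2 = (u-u_0)^2 + (v-v_0)^2$ about the principal point
   $(u_0, v_0)$ and distortion factor $k$ (px$^{-2}$).
2. **Camera mounting deflection.** The camera is screwed onto the
   microscope port; image axes are rotated by a small angle $\theta$
   relative to the stage axes.  At high magnification even a fraction of
   a degree displaces a long move by micrometres.
3. **Mechanical displacement error.** Lead-screw stages travel a slightly
   different distance than commanded, by a relative factor that depends
   on axis *and* direction (backlash-like asymmetry):
   $\Delta_{x+}, \Delta_{x-}, \Delta_{y+}, \Delta_{y-}$.

The package calibrates all three from images of a square calibration grid
and assembles them into a compensation model; the combined error
transform is
$T = M'\,\begin{pmatrix}1 & \varepsilon_y & \Delta_x\\ \varepsilon_x & 1 &
\Delta_y\\ 0 & 0 & 1\end{pmatrix}\,[R \mid \hat t]$,
where $M'$ is the ratio of actual to nominal magnification and
$\varepsilon_x = -\varepsilon_y = \sin\theta$ is the first-order rotation
convention we adopt (the deflection factors are not tied to $\theta$ by
any constraint in the model itself, so both are exposed separately and a
non-orthogonality term can be injected in tests).

## Calibration chain

`calibrate_stage()` runs the stages in order and returns a classed fit
object:

1. **Centerline extraction** (`extract_center_lines`).  Dark grid lines
   are scanned perpendicular to each family; every scanline contributes an
   intensity-weighted centroid with subpixel precision.  Samples are
   grouped into lines by de-sloped 1-D clustering (the family's dominant
   drift per scanline is estimated from nearest-neighbour matches and
   removed), and samples contaminated by crossings of the perpendicular
   family are rejected against a per-line cubic, which absorbs the smooth
   distortion bow but not crossing artefacts.
2. **Plumb-line distortion fit** (`fit_distortion`).  Straight world
   lines must be straight after correction, so we minimize
   $\sum_i \sum_j (\hat u_{ij} \cos\alpha_i + \hat v_{ij} \sin\alpha_i +
   \varphi_i)^2$ over $(k, u_0, v_0)$ and the per-line Hessian-form
   parameters $(\alpha_i, \varphi_i)$, by Levenberg–Marquardt
   (`minpack.lm`) with an analytic Jacobian.  The normal vector
   $(\cos\alpha_i, \sin\alpha_i)$ is unit by construction, which removes
   the trivial all-zero solution that the raw objective admits.  Lines
   are initialized by total-least-squares fits, $(u_0, v_0)$ at the
   raster centre, $k$ at zero.
3. **Homography and decomposition** (`estimate_homography`,
   `decompose_imaging`).  Corrected line parameters and their pairwise
   intersections, paired with the known 50 µm grid pitch, feed a DLT with
   both point constraints $p \times H P = 0$ and line constraints
   $L \times H^\top l = 0$ (world-to-image direction throughout), solved
   by SVD after similarity normalization.  With zero skew and the
   principal point taken from the distortion fit, the focal scales
   follow from the row norms of the centred homography; a single plane
   cannot identify them without the metric grid pitch, which is why the
   target's pitch is a required input.  Decomposition recovers
   $[r_1\, r_2\, t] = \lambda A^{-1} H$, magnifications $M_u = f_x L_u$,
   $M_v = f_y L_v$, $M = (M_u + M_v)/2$, $M' = M / M_{nominal}$, and the
   distortion-compensation offsets as the translation components of
   $[R \mid \hat t]$.
4. **Deflection by stitching** (`deflection_from_series`).  Frames taken
   across half-frame stage steps are registered pairwise;
   $\theta = \arctan(dy/dx)$ for X-series (transposed for Y-series), and
   per-pair angles are averaged arithmetically.
5. **Mechanical errors** (`axis_error_from_series`).  After rotating the
   measured offsets back by $\theta$, the mean per-step deviation from
   the nominal step gives the relative error of each direction; the
   direction-dependent quadrant coefficient $\mu(\beta)$ selects the
   $(\Delta_x, \Delta_y)$ pair by the motion quadrant (half-open
   quadrants; 90° belongs to the second).

## Registration backends and lattice ambiguity

The stitching hardware reference uses SIFT features with RANSAC
consensus.  Grid images make generic feature matching fragile — every
corner looks alike — so the package's primary backend matches grid-corner
features (centerline intersections) with a mode-of-differences consensus
vote and mean-of-inlier refinement, which plays the same robust-consensus
role.  A windowed FFT cross-correlation backend serves as fallback and
cross-check; in automatic mode the two must agree within half a grid
period or an ambiguity error is raised.

A strictly periodic lattice determines a translation only modulo its
pitch, and a deflection of 6° over a 600 px step moves the transverse
offset by more than half a pitch.  Real scale plates are not strictly
periodic: they carry major graduations.  The simulator therefore renders
every fifth line twice as thick (`grid_spec(major_every = 5)`), and the
corner backend disambiguates its candidate translations (which differ by
whole lattice vectors) by image correlation, aligning the scoring window
through the local distorted shift when intrinsics are available and by a
small local search otherwise.

## The compensation model

`compensate_move()` supports two readings of the printed compensation
formula:

* **coherent** (default): the desired displacement, expressed in image
  axes under the nominal pixel scale, is rotated by $-\theta$ into stage
  axes, divided per-axis by the direction-selected gains
  $1 + \Delta$, and divided by $M'$.  This is the unique reading under
  which a perfect model yields exactly zero residual, and it reduces to
  the identity when nothing was measured.  Distortion enters by locally
  undistorting the pixel measurements (the offsets act once per absolute
  position, not per unit step).
* **paper_literal**: evaluates the printed single-coefficient form
  $X_1 = X_0 + M'\delta_x\,\mu\,s\cos\theta$,
  $Y_1 = Y_0 + M'\delta_y\,\mu\,s\sin\theta$ verbatim (with the scalar
  quadrant coefficient $\mu$ and $|\cos|, |\sin|$ magnitudes), retained
  for auditability.  Note its structural quirks: displacement is
  proportional to the distortion offsets (zero offsets would freeze the
  stage), and an error-free stage at $\beta = 45°$ gets gain $\sqrt 2$.
  These are the reasons the coherent mode exists and is the default.

## What the simulator emulates — and what it does not

`ground_truth()` + `render_grid_image()` draw a square grid (20 × 20
squares of 50 µm by default, imaged at 1200 × 900 px) through the exact
inverse imaging chain: observed pixel → closed-form undistortion →
rotation by $-\theta$ → metric scale → anti-aliased (trapezoidal) line
coverage.  Defaults place the system at a 20× objective with 20 µm
sensor pixels (≈ 1 px/µm, so a 600 µm step is half a 1200 px frame),
$k = 5\times10^{-8}$ px$^{-2}$, $\theta = -5.58°$, actual magnification
19.843, and per-axis relative errors $-5.2/-5.8/-5.7/-5.2$ px per 600 px
step — the measured study conditions.  Intensities are 200 (background)
over 50 (lines) with optional Gaussian noise, clipped to 8 bits; a seed
fixes every raster byte-for-byte.  `n_squares = Inf` renders the
unbounded periodic ruling of a long scale so displacement series can
travel several millimetres.

Not emulated: the microscope PSF and defocus, illumination gradients,
shot noise, stage vibration, thermal drift, and within-run variation of
the screw errors (each direction's $\Delta$ is a constant).  Passing the
closed-loop tests therefore demonstrates the *estimators and the model
algebra* are correct and self-consistent at realistic signal levels — not
that a physical stage will reach the same residuals.

## Numerical choices

* Distortion inversion: damped Newton on the radial magnitude,
  tolerance $10^{-12}$ px², at most 50 iterations, guarded by the
  monotone-radius condition $|3kr^2| < 1$.
* Line parameters: $\alpha \in (-\pi/2, \pi/2]$, Hessian normal form.
* DLT conditioning: failure if the second-smallest singular value falls
  below $10^{-10}$ of the largest (degenerate geometry), or if the
  smallest-to-second-smallest ratio exceeds 0.1 (no well-defined null
  space).
* Decomposition sign: $\lambda$ is flipped so the third translation
  component is non-negative.
* Registration: inlier threshold 1 px, fallback below 8 inliers,
  subpixel by parabolic interpolation of the correlation peak; series
  registration searches around the commanded offset (the prior that
  resolves lattice aliases beyond the major-graduation super-period).
* Quadrant boundaries are half-open, $[0°, 90°)$ first.

## Worked example

```{r example, eval = FALSE}
truth <- ground_truth(intr = intrinsic_params(1, 1, 599.5, 449.5, 5e-8),
                      theta_deg = -5.58, M_true = 19.843, M_nominal = 20,
                      axis = axis_errors(-5.2/600, -5.8/600, -5.7/600, -5.2/600))
grid_img <- render_grid_image(truth, grid_spec(), c(0, 0))
ser <- function(a, d) simulate_series(truth, grid_spec(n_squares = Inf),
                                      displacement_plan(a, d, 8L, 600))
cal <- calibrate_stage(grid_img, ser("x", 1L), ser("y", 1L),
                       ser("x", -1L), ser("y", -1L))
summary(cal)
predict(cal, rbind(c(100, 0)))        # compensated command for 100 um in +X
single_shot_trial(cal$model, truth, seed = 1)
```

The test suite runs this loop at the defaults above; the problem sizes
used there (one grid image, four 9-frame series, 50 single-shot trials,
and 20 replicates of the five cumulative path classes at 600 µm steps)
were chosen so the whole study re-runs comfortably on a laptop while
keeping every estimate's Monte-Carlo error well below the tolerances
being checked.

## Known limitations

* A single fronto-parallel plane cannot identify $f_x, f_y$ without the
  metric grid pitch, and out-of-plane tilt is not modelled
  ($P = (X, Y, 0)^\top$ throughout).
* Only the second-order radial term is modelled; tangential and
  higher-order radial distortion are out of scope.
* The standalone `deflection`/`mech` command-line subcommands operate
  without a distortion calibration and a calibrated pixel scale, so
  their magnitudes carry the corresponding biases; exact values come
  from the full pipeline (`calibrate` subcommand or
  `calibrate_stage()`), which threads the fitted intrinsics into the
  registration.
* The mechanical model is a per-direction constant relative error;
  lead-screw periodic error spectra and load-dependent hysteresis are
  not modelled.
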