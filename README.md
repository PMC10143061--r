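# stagecal

Positioning-error calibration and compensation for camera-guided
motorized microscope stages.

Vision-guided micromanipulation converts a pixel offset clicked in the
microscope image into a stage motion command. Three systematic errors
corrupt that conversion and accumulate over a session: radial lens
distortion of the microscope optics, the mounting deflection angle
between camera and stage axes, and signed per-axis mechanical
displacement errors of the stage screws. stagecal calibrates all three
from images of a square calibration grid and corrects motion commands
with the combined model. It is aimed at builders of micromanipulation
and automated-microscopy rigs who need micrometre-level closed-loop
positioning from commodity stages.

## The model

An observed image point relates to its theoretical projection through a
second-order radial distortion about the principal point,

    u~ = u + k (u - u0) r²,   v~ = v + k (v - v0) r²,
    r² = (u - u0)² + (v - v0)²,

and the theoretical projection follows the planar imaging model
λ p̃ = H P̃ = A [R₁₂ | t] P̃ with zero-skew intrinsics A. The distortion
parameters (k, u0, v0) are estimated by a plumb-line criterion — images
of straight grid lines must be straight after correction — minimized by
Levenberg–Marquardt over all per-line tilt/intercept parameters jointly.
The homography H is estimated by a DLT over both point and line
correspondences with the known 50 µm grid pitch and decomposed into the
magnification ratio M′ = M / M_nominal, pose, and distortion
compensation offsets. The camera mounting angle is θ = arctan(dy/dx)
from stitching offsets of half-overlap frames across stage steps, and
per-axis relative displacement errors Δx±, Δy± are the mean per-step
deviations of stitched travel from the commanded step. A motion command
is then compensated by inverting the combined error transform

    T = M′ [1 εy Δx; εx 1 Δy; 0 0 1] [R | t̂],

with the (Δx, Δy) pair selected by the motion direction's quadrant.

A synthetic grid-image simulator (`ground_truth()`,
`render_grid_image()`, `simulate_series()`) renders the whole imaging
chain with known parameters, so every estimator has a ground-truth
recovery test and the compensation can be evaluated closed-loop.

## Worked example

Calibrate a synthetic system whose ground truth mirrors the study
conditions (20× objective at actual magnification 19.843, k = 5e-8
px⁻², θ = −5.58°, screw errors of −5.2/−5.8/−5.7/−5.2 px per 600 px
step):

```r
library(stagecal)

truth <- ground_truth(intr = intrinsic_params(1, 1, 599.5, 449.5, 5e-8),
                      theta_deg = -5.58, M_true = 19.843, M_nominal = 20,
                      axis = axis_errors(-5.2/600, -5.8/600,
                                         -5.7/600, -5.2/600))
grid_img <- render_grid_image(truth, grid_spec(), c(0, 0))
ser <- function(a, d) simulate_series(truth, grid_spec(n_squares = Inf),
                                      displacement_plan(a, d, 8L, 600))
cal <- calibrate_stage(grid_img, ser("x", 1L), ser("y", 1L),
                       ser("x", -1L), ser("y", -1L))
cal
#> Stage calibration
#>   k = 4.999e-08 px^-2, (u0, v0) = (599.54, 449.51) px
#>   M = 19.8435 (nominal 20), M' = 0.99218
#>   theta = -5.5799 deg over 16 stitched pairs
#>   Delta = -0.00870 / -0.00970 / -0.00953 / -0.00869 (+X/-X/+Y/-Y)
```

Every generating parameter is recovered: k within 0.02%, the mounting
angle within 0.0001°, magnification within 2 × 10⁻⁶ relative, and the
four screw errors within a few parts in 10⁴. Compensated commands then
pre-distort the requested displacement so the true stage lands on
target:

```r
predict(cal, rbind(c(100, 0), c(-250, 120)))
#>          cmd_x     cmd_y
#> [1,]  101.1911  9.894236   # rotated +5.58 deg, divided by (1+Delta), M'
#> [2,] -265.1085 96.795338
single_shot_trial(cal$model, truth, seed = 1)
#> Trial residual: (0.00139, -0.0005145) um, norm 0.001482 um (compensated)
```

Uncompensated, the same trials miss by ~31 µm (median); compensated,
the median residual is 0.0014 µm — the remaining error is estimator
noise, not model structure.

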