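---
title: "Boundary coding from spherical optic flow: the model behind bvcflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary coding from spherical optic flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bvcflow)
```

Boundary vector cells (BVCs) in the subiculum and entorhinal cortex fire
when a boundary — a wall, or the edge of a platform — lies at the cell's
preferred distance and allocentric direction from the animal. `bvcflow`
implements a full visual pathway that could support such firing using
nothing but optic flow: a simulated rat forages in a parametric arena, the
analytical flow field on its spherical retina is matched against flow
templates for ground and wall surfaces, and the resulting wall
distance/direction estimates drive a classical BVC activation model whose
occupancy-normalized rate maps can be compared with recordings.

This vignette explains the model stage by stage, states every numerical
choice and its rationale, and describes what the synthetic data do and do
not emulate.

## Coordinate conventions and the spherical camera

The world frame is left-handed: `x` to the right, `y` up, `z` forward at
head direction 0; arenas are centered on the origin with the ground in
`y = 0`. The allocentric head direction `phi` rotates about the vertical,
so the heading vector in the plan view is `(sin phi, cos phi)`.

The eye is modeled as a spherical camera at height `h = 3.5` cm. A viewing
direction is parameterized by azimuth `theta`, measured from the optical
axis in the `xz`-plane (positive to the right), and elevation `varphi`,
measured from the azimuth-rotated forward axis (positive up). The field of
view spans 240 degrees horizontally and 120 degrees vertically — the wide,
almost panoramic field of a rat — sampled on a cell-centered regular grid,
80 x 40 nodes by default and 400 x 200 for drop-off detection, where the
detector needs elevation resolution.

## Flow for curvilinear self-motion

Self-motion is restricted to curvilinear motion: translation `v_z` along
the optical axis plus yaw `omega_y` about the vertical. For a static point
at distance `D` in direction `(theta, varphi)` the angular velocities are

    dtheta/dt  = (v_z / D) * sin(theta) / cos(varphi) - omega_y
    dvarphi/dt = (v_z / D) * sin(varphi) * cos(theta)

(derived from the rigid-motion kinematics of the spherical projection; the
package evaluates the general vector form, which reduces to these at zero
tilt). Two structural facts drive everything downstream:

* the rotational component affects only the azimuth rate and is independent
  of depth;
* the translational component scales with `1/D`.

With non-zero tilt `gamma` the rat still translates parallel to the ground,
so `analytic_flow()` expresses the motion in the tilted camera frame before
evaluating the flow.

Measurement noise is emulated by `add_flow_noise()`: independent zero-mean
Gaussian perturbations of both components at every node, with standard
deviation `sigma_n` in deg/sec.

## Scene model: planes in Hessian normal form

Ground and walls are planes described by a unit normal and a distance along
it. The ground at zero tilt has depth `D = h / sin(-varphi)`; a vertical
wall at allocentric direction `alpha` and perpendicular distance `d` has

    D(theta, varphi) = d / (cos(varphi) * cos(alpha - phi - theta))

Wall normals are built by three rotations applied in a fixed order — wall
direction `alpha` about the vertical, tilt about the heading-perpendicular
horizontal axis, head direction `phi` about the vertical — so the tilt axis
depends on `phi` and the order matters whenever `gamma != 0`
(`wall_normal()` exposes exactly this construction). Curved walls are
approximated locally by planes: the circular wall is meshed as 128 facets,
and each facet is explained by the tangent-plane hypothesis of the matching
grid.

## The template model

Matching proceeds in the four stages of `estimate_boundaries()`:

**1. Wall–ground segmentation.** Because yaw moves features purely in
azimuth, the elevation flow component is rotation-invariant and
depth-dependent — multiplying the flow equation by `(0, 1)` eliminates the
unknown rotation. Each node is assigned to the family (ground plane over
linear-velocity samples, or wall planes over direction x log-distance
samples at the mean sample velocity) whose best template explains its
elevation flow, with ties going to ground. One design decision matters
here: the wall family is strictly richer than the ground family, so if its
search grid is sampled densely it can fit *noise* at almost every node and
segmentation collapses. The segmentation stage therefore searches a
deliberately coarse wall grid (30-degree directions, 8 log-spaced
distances; `seg_alpha_step`, `seg_n_dist`). Noise-free segmentation with
these defaults is ~94% correct and majority-correct (~86%) under strong
noise; with a fine search grid it is exact on noise-free flow but fragile
under noise. Isolated accidental collisions — wall points whose flow is
exactly consistent with the ground plane at an on-grid velocity — are
possible at special poses and are unresolvable within this constraint.

**2. Linear velocity.** The same rotation-invariant constraint, accumulated
over the segmented ground nodes for each velocity sample (0–60 cm/sec in
1 cm/sec steps), followed by the 1D read-out.

**3. Rotational velocity.** A Gaussian of the Euclidean distance between
the two-component input flow and ground templates built at the estimated
linear velocity, over yaw samples (±1000 deg/sec in 5 deg/sec steps; the
yaw-rate distribution of foraging rats has a standard deviation near
350 deg/sec, so the grid must reach far into the tails).

**4. Wall distance and direction.** A Perrone-style tuning in polar flow
coordinates: the product of a Gaussian in the difference of *log* speeds
(width `sigma_logspeed = 0.13`) and a Gaussian in the difference of flow
directions (width 30 degrees, minus a baseline offset of 0.1), accumulated
over the segmented wall nodes for every direction (5-degree steps) x
log-distance (64 samples, 2–250 cm) hypothesis. Two details are essential:

* *Derotation.* The estimated rotational field is subtracted from the input
  and the templates contain translation only. Keeping rotation inside both
  makes all templates nearly identical whenever `|omega|` is large (every
  speed approaches `|omega|`), flattening the match surface; derotation is
  also what makes log-speed the natural metric, since translational speeds
  span decades as `1/D`.
* *Log speed.* Comparing log speeds weights a given relative depth error
  equally at all distances and emphasizes near surfaces; the package keeps
  the plain speed-difference variant (`log_speed = FALSE`) for the
  ablation, which is reliably worse on large arenas.

**Read-out.** 1D curves are read out as the match-weighted mean of the
arguments inside a window of two percent of the grid centered on the
maximum (even window sizes are widened by one cell so the window stays
centered; windows are clipped at the grid edge). The 2D surface returns
*all* cells within 70% of the maximum, each weighted by its relative match
value — several walls therefore yield several estimate clusters.

## Drop-off detection

Platform edges produce no wall flow; they appear as a discontinuity of
flow speed along elevation. `detect_dropoff()` applies a one-dimensional
center-surround filter (one center cell against two cells on each side)
along the elevation axis of each azimuth column of the speed image and
takes the elevation of the maximum response; responses below 10% of the
global maximum are invalid, which is what suppresses detections of distant
edges. Valid elevations are converted to ground distances through the known
eye height and tilt (`dropoff_distance()`), and enter the BVC stage exactly
like wall estimates, weighted by their normalized filter response. The
filter runs on raw speed (not log speed): the edge contrast is a
near-to-zero transition which the logarithm would compress.

## The BVC stage

A BVC tuned to distance `D_i` and direction `Phi_i` accumulates, over all
read-out estimates `(alpha_k, d_j, w_kj)`,

    sum_kj exp(-(d_j - D_i)^2 / (2 sigma_rad(D_i)^2))
         * exp(-wrap(alpha_k - Phi_i)^2 / (2 sigma_ang^2)) * w_kj

with `sigma_rad(D) = 12.2 * (D / 183 + 1)` cm and `sigma_ang = 0.2` rad —
the standard constants of the BVC model family this stage adopts. The sum
is not divided by the number of estimates, so two half-weight estimates
equal one full one. Ground-truth positions are used only to bin activations
into occupancy-normalized rate maps (2 cm bins), mirroring how experimental
rate maps are registered by tracking the animal; the `gt_boundary_estimates()`
input mode (true ray-cast distances along all sampled directions, weight 1)
reproduces the classical, non-visual BVC model for comparison.

## The trajectory generator

Locomotion is simulated at 50 Hz. Each 20 ms step draws a linear speed from
a Rayleigh distribution and a yaw rate from a normal distribution; the
defaults are the fits to recorded foraging data (circular environments:
`b = 16.99` cm/sec, yaw `N(-2.48, 350.58)` deg/sec; square environments:
`b = 13.25`, `N(0.62, 337.93)`). A deterministic avoidance rule turns the
heading parallel to any boundary closer than 2 cm that the rat is heading
into (the tangent with the smaller turn wins); residual escapes are clamped
to a 0.5 cm clearance. Realized speeds (displacement per step) are recorded,
so wall interactions slightly deflate the fitted Rayleigh scale relative to
the drawn one — the same deflation seen when fitting the generated sessions
(about 16.4 and 13.2 cm/sec in the default boxes). Avoidance turns are
modeled as discrete heading resets rather than yaw velocity, keeping the
recorded yaw-rate distribution normal.

What the generator does *not* emulate: speed autocorrelation, thigmotaxis
beyond the turn rule, rearing, head-scanning, or pitch/roll of the head. A
passing test battery therefore shows that the *visual pipeline* is sound
under realistic velocity statistics, not that the locomotion model is
behaviorally complete.

The interior-wall arena places a two-sided wall of half the box side
through the center (endpoints `(0, ±15.5)` cm by default, configurable);
the trajectory then starts in the middle of the western half, since the
arena center lies on the wall itself.

## Numerical choices and performance

* Depths below 0.5 cm are clamped before entering `1/D` terms
  (`min_depth`); rays are cut off at 1000 cm (`max_depth`).
* Ray casting uses closed-form plan-view segment intersection (exact for
  the polygonal meshes); a Möller–Trumbore triangle-mesh caster is kept as
  the cross-checked reference implementation.
* The trajectory-scale matcher (`method = "binned"`) exploits that a wall
  template depends on the node only through `P = cos(el) *
  cos(alpha - phi - theta) / d` and that the distance grid is log-uniform:
  the tuning is evaluated once per node on a dense log-`P` grid (2x the
  distance-grid resolution) and window-added into the match surface with
  integer shifts. The approximation quantizes depth by under 2%, small
  against the 7.7% distance grid; the exact matcher (`method = "exact"`)
  is the default for single poses and the two agree to read-out accuracy.
* Tie-breaks: first maximum wins in every argmax; segmentation ties go to
  ground.
* Default problem sizes: 20-minute sessions (60,000 samples at 50 Hz) with
  every 10th frame evaluated by the template model; rate maps at 2 cm bins
  and error maps at 5 cm bins for stable per-bin means. All are
  configuration fields, and full-rate runs are a config change.

## Worked example poses

The package's worked example for wall read-out places the rat in the 79 cm
circular box at `(20, 3.5, 3)` cm with head direction 23 degrees and
self-motion `v_z = 19` cm/sec, `omega_y = 25` deg/sec: the 2D match surface
peaks at 80 degrees allocentric direction and 18.5 cm distance (the nearest
wall lies 19.3 cm away along 81.5 degrees). The noise-robustness example
uses the square box at `(20, 3.5, 15)`, same heading and self-motion, with
`sigma_n = 5` deg/sec — self-motion is recovered at the grid (19 cm/sec,
~25 deg/sec) and the mean absolute distance error averages ~0.7 cm over
noise seeds.

## Known limitations

* Only visible boundaries drive the model; transparent walls and darkness
  are out of reach of a flow-based mechanism by construction.
* Self-motion is curvilinear; pitch/roll and off-axis translation are not
  modeled.
* Distance estimates for curved walls carry an intrinsic error: the matcher
  estimates tangent-plane (perpendicular) distances while errors are scored
  along the viewing direction; on the 79 cm circle this contributes most of
  the residual error under strong noise.
* The elevation-flow segmentation constraint is locally ambiguous wherever
  `sin(varphi) * cos(theta)` is small (near the horizon and near ±90
  degrees azimuth); segmentation there relies on the discreteness of the
  template families.
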