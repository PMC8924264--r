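---
title: "A two-rule model of diameter-dependent tendril coiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-rule model of diameter-dependent tendril coiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendrilcoil)
```

## The scientific problem

Tendril-bearing climbers must grip supports whose diameter they cannot
sense directly. Experiments with *Cayratia japonica* tendrils offered
cylindrical supports of 10-35 mm show a striking decision-tree structure in
the coiling response: within the first five minutes the tendril either coils
in place around its initial contact point (*continuous coiling*, thin
supports) or lets the contact migrate toward its tip (*moving contact
point*, thick supports); moving contacts then either run off the tip and
detach (*tip contact*) or, after a secondary contact near the tendril base,
curl into a clip that may grip the support (*clip-shape coiling*); and final
coiling success falls with support diameter and rises with tendril length.

`tendrilcoil` implements the hypothesis that two local behavioural rules
generate this whole pattern without any direct diameter sensing:

1. **Coiling starts around the contact point.** A touch stimulus makes the
   tendril lay down intrinsic curvature in a window around the contact.
2. **Minimum coiling angle.** Once coiling has started, the tendril always
   expresses at least a fixed bend `theta_min` (about 25 degrees) over the
   stimulated region.

The package has two halves: a quasi-static planar simulator of these rules,
and the measurement pipeline used to test them on marker-tracking data
(bending-angle series, rapid-coiling/stop-stage segmentation, stop-stage
coil diameter by 3D circle fitting), plus generators for the synthetic
tracks and coiling-success tables everything is tested on, and a logistic
GLM for the success analysis.

## The simulator

The tendril is an inextensible chain of nodes `ds = 1` mm apart; each
interior joint carries an intrinsic bend in degrees toward the touched side.
The support is the circular cross-section of the rod, tangent to the
straight tendril at the contact fraction (default: the middle, as in the
experiments, with the rod perpendicular to the tendril).

The liftoff decision is the geometric heart of the model. Expressing
`theta_min` over a contact window of arc length `w = contact_window`
demands local curvature `theta_min_rad / w`. The contact holds if and only
if the support surface curves at least that sharply:

$$\frac{2}{\phi} \ \ge\ \frac{\theta_{\min}^{rad}}{w}
  \quad\Longleftrightarrow\quad
  \phi \ \le\ \phi^\ast = \frac{2w}{\theta_{\min}^{rad}},$$

so the step-1 bifurcation diameter is an explicit function of the two rule
parameters. With the defaults (`theta_min = 25` degrees, `contact_window =
3` mm) this gives `bifurcation_diameter(model_params())` =
`r round(bifurcation_diameter(model_params()), 2)` mm, inside the 10-15 mm
band where the behavioural switch is observed. (The source experiments state
the bifurcation "in cm"; given the 10-35 mm support range we read that as a
typo for mm.)

* **Continuous coiling** (`phi <= phi*`): the contact window curls to
  `theta_min` in place and coiling then spreads along the tendril in both
  directions at the free-coil curvature `2 / free_coil_diameter`. Because
  the free coil (18 mm default) is wider than any maintained support
  (below 13.75 mm), the growing coil encircles the rod without ever
  penetrating it; the wrap is closed - coiling success - when the total
  intrinsic turn reaches `detach_wrap_threshold` (360 degrees).
* **Moving contact point** (`phi > phi*`): bend that would drive the
  tendril into the rod is truncated at surface tangency, so the tendril
  conforms to the surface and the stimulated front slides tip-ward along
  the rod; every time `theta_min` of new bend accumulates the old contact
  lifts off and a new contact is logged closer to the tip - the model's
  re-stimulation cycle. The conformal wrap uses the inscribed-chord turn
  `2 asin(ds / phi)` per joint, so wrapped nodes sit exactly on the
  surface. A front that runs off the tip without a secondary contact is a
  tip contact and detaches. If the conformed arc itself comes full circle
  (tip-side arc at least `pi * phi`) the wrap closes and the trial
  succeeds - this is what makes success increase with length and decrease
  with diameter even without a clip.
* **Root-side coiling and the clip.** Once the moving phase begins,
  coiling also propagates root-ward at the free-coil curvature; a
  "reaction" rotation of the root-side chain about the contact (the rod
  pushing back) keeps it off the support, and root-ward curling that no
  rotation can reconcile with the rod is truncated (the rod blocks it).
  Circumnutation is modelled as a seeded Gaussian sway of amplitude
  `jitter_sd` (mm) of the root-side segment; when the sway exceeds the
  current clearance between the root quarter (`root_contact_fraction` of
  arc length) and the rod surface for `secondary_persistence` consecutive
  steps, a secondary root contact is logged and the trial becomes
  clip-shape coiling. The clip closes (success) when the primary conformed
  arc plus the root-side coil laid down after the secondary contact reach
  the wrap threshold - but the root-side coil, which curls at the
  free-coil diameter, can only count when the rod actually fits inside it
  (`phi <= free_coil_diameter`). A clip that exhausts its coiling capacity
  or stays jammed longer than `detach_persistence` lets go.

With `jitter_sd = 0` every trial is fully deterministic and no clip can
form, which makes the deterministic branches (bifurcation, tip contact,
wrap-closure success) exactly testable; with jitter on, the tip-contact
versus clip-shape split is driven by circumnutation, while diameter and
length decide the clip's fate. This division of labour is deliberate: the
source experiments likewise found that diameter and length left much of the
second-step variance unexplained and attributed the remainder to the
rotatory movement of the plant.

### Parameters and calibration

| parameter | default | units | meaning |
|---|---|---|---|
| `theta_min` | 25 | deg | minimum coiling angle (measured plateau) |
| `free_coil_diameter` | 18 | mm | intrinsic coil diameter (measured 16.1-20.4) |
| `contact_window` | 3 | mm | arc over which `theta_min` is expressed |
| `coiling_rate` | 6 | deg/min | curvature uptake speed |
| `contact_tol` | 0.2 | mm | touch distance |
| `detach_wrap_threshold` | 360 | deg | wrap angle defining success |
| `max_time` | 180 | min | observation window (3 h) |
| `dt` | 0.5 | min | time step |
| `ds` | 1 | mm | node spacing |
| `jitter_sd` | 0 | mm | circumnutation sway amplitude |

`theta_min` and `free_coil_diameter` are taken directly from the
measurements the model is built on (the 25-degree coiling-angle plateau and
the 16.1-20.4 mm stop-stage coil diameters). `contact_window` is the one
genuinely free geometric parameter; 3 mm places the bifurcation at 13.75 mm,
inside the observed band, and is of the order of the contact patch a 1-2 mm
thick tendril makes on a rod. `coiling_rate = 6` deg/min completes the
25-degree rapid stage in about 4.2 min, consistent with an initial response
scored within 5 min and a rapid stage spanning a handful of 1-min frames.
For jittered runs we use `jitter_sd = 15` mm in tests, a typical
centimetre-scale circumnutation amplitude for vine shoots. None of these
defaults is fitted to data beyond these published anchor values.

### Numerical choices

Placement anchors the chain at the initial tangency with the two chords at
the contact straddling the tangent symmetrically; with the inscribed-chord
conforming turn this keeps wrapped nodes on the surface to machine
precision, which is why the non-penetration invariant can be asserted at
`1e-6` mm. The root-side reaction rotation is found by a deterministic
1-degree scan (away from the coiling side first) refined by 60 bisection
steps. Segment lengths are exact by construction (positions are rebuilt
from intrinsic bends every frame), so inextensibility holds to rounding
error. The only randomness is the circumnutation draw; trials are
bit-for-bit reproducible given `seed`.

## The measurement pipeline

`bending_series()` computes, per frame and interior marker, the interior
angle at the marker between its neighbours (180 degrees = locally
straight). `segment_stages()` finds the stop stage as the first frame from
which the per-frame angle change stays below `stop_eps` (default 1
degree/frame) for at least `persistence` (default 3) consecutive
transitions; these thresholds are design choices, since the stages are
described only qualitatively. `stop_stage_diameter()` fits a circle to the
coiled markers at the midpoint frame of the stop window: a total
least-squares plane (SVD), projection, a Pratt algebraic circle fit, and
one Gauss-Newton refinement pass on geometric distance. Which markers form
the coil is ambiguous in general, so the subset is an explicit argument;
the default auto-detection keeps the contiguous run of markers bent by more
than half the strongest bend (at least 5 degrees), plus the tip-ward end
marker, which rides on the coil.

The coiling angle at the contact marker is defined as 180 degrees minus the
bending angle there: zero for a straight tendril, rising to the plateau as
it coils. The source figures define the coiling angle only pictorially;
this complement-at-the-contact-marker definition is our choice, made
because it starts at zero and rises to the reported 25-degree plateau.

## The synthetic-data generators

No raw marker coordinates or trial tables are deposited with the
experiments, so the generators emulate the protocols:

* `gen_free_coil_track()` - the time-lapse protocol: 12 frames at 1-min
  intervals, markers every 5 mm, bend accruing at the contact marker along
  a linear ramp that reaches exactly `theta_min` after one third of the
  frames and holds. The ramp shape is a stand-in (only "rapid then stop"
  is described); holding the plateau exactly makes the generator/estimator
  round trip sharp.
* `gen_wrap_track()` - the 3D-tracking protocol: the tendril region from
  the contact marker to the tip winds onto a circle whose curvature rises
  along a saturating exponential (at least 80 percent of the final value by
  one third of the frames, held exactly from half the frames on), with
  markers at exact 5 mm arc intervals on the current circle. Presets
  `fig5_thin` (89 mm tendril, 1 mm rod, 20.4 mm stop diameter) and
  `fig6_thick` (69 mm tendril, 40 mm rod, 16.1 mm stop diameter) encode
  the two published tracking runs.
* `gen_success_dataset()` - Bernoulli coiling-success tables over the
  experimental nine-diameter grid (10-35 mm), lengths uniform on 60-160 mm,
  with logistic coefficients (`beta0 = 0`, `beta_diameter = -0.25` per mm,
  `beta_length = 0.05` per mm) chosen so failures concentrate at the
  large-diameter, short-length corner; 87 trials by default, the
  experimental sample size. The published per-coefficient estimates are in
  supplementary material that is not reproduced here, so these are
  generator settings, not fitted values.

What passing round-trip tests show is that the pipeline recovers the
generating kinematics exactly or within stated noise tolerances; they do
not show that real tendrils follow those kinematics. Real tracking data add
marker mis-identification, non-planar coils, and heteroscedastic
triangulation error that the isotropic Gaussian noise model does not
emulate.

## The GLM

`fit_logistic()` fits success ~ diameter + length by iteratively reweighted
least squares, converging when the largest coefficient change falls below
`1e-8` (at most 100 iterations), with Wald standard errors and z tests.
Complete or quasi-complete separation is detected (diverging coefficients
with saturating fitted probabilities) and reported as a flag instead of
fabricated finite estimates. The main-effects-only design matches the
stated analysis; an interaction is available behind a flag. Tests check the
fit against a brute-force likelihood maximization and against `stats::glm`,
and verify 95 percent Wald coverage of the generating coefficients in
seeded replicates.

## Problem sizes used in the test suite

The shipped tests run the simulator on tendrils of 60-160 mm at 1 mm node
spacing (up to 360 half-minute steps), a 9-diameter by 6-length
deterministic sweep, 20-seed jittered replicates for the clip-majority
checks, and 100-replicate GLM calibrations at n = 500. These sizes keep the
whole suite under a few minutes while leaving every assertion
statistically comfortable.

## Known limitations

* The simulation is planar; multi-wrap coils self-overlap in the plane and
  are only disambiguated by an optional out-of-plane pitch on export.
* The model is kinematic: no elasticity, gravity, or contact friction, so
  detachment times are rule timings, not mechanics.
* The short arm of the tendril is not modelled (its role is an open
  question in the source experiments).
* Clip formation is stochastic by construction; the model does not predict
  which individual moving-contact trial will clip, only the diameter- and
  length-dependence of the clip's fate.
* The GLM assumes independent trials; repeated measures on the same plant
  would need a random effect, which is out of scope.
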