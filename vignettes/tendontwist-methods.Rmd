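---
title: "Modelling fascicle twist in the Achilles tendon: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fascicle twist in the Achilles tendon: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science inside `tendontwist`: the constitutive
model and its assumptions, how fascicle twist is embedded as a continuum
field, how the inverse calibration and the in-silico experiments work, what
the synthetic-data generator does and does not emulate, and the numerical
choices we made where the design was genuinely open. Units are mm, N and
MPa throughout (so stresses are MPa and energies mJ/mm^3).

## The material model

Tendon is modelled as a transversely isotropic hyperelastic composite: a
compliant ground-substance matrix reinforced by one family of collagen
fibers. The strain energy splits additively,

$$W = F_1(\bar I_1) + F_2(\bar\lambda) + \tfrac{\kappa}{2}(\ln J)^2,$$

with a neo-Hookean matrix $F_1 = \tfrac{c_1}{2}(\bar I_1 - 3)$ and a fiber
term whose stress is the classic three-branch uncrimping law

$$\lambda\frac{\partial F_2}{\partial\lambda} =
\begin{cases}
0 & \lambda \le 1 \quad\text{(crimped toe region)}\\
c_3\left(e^{c_4(\lambda-1)}-1\right) & 1 \le \lambda \le \lambda^\ast\\
c_5\lambda + c_6 & \lambda \ge \lambda^\ast .
\end{cases}$$

The offset $c_6 = c_3(e^{c_4(\lambda^\ast-1)}-1) - c_5\lambda^\ast$ is not a
free parameter: it is fully determined by continuity at the uncrimping
stretch $\lambda^\ast$, and `material_params()` refuses an inconsistent
value. The five coefficients with physical content are $c_1$ (matrix
modulus), $c_3$ (exponential scale), $c_4$ (uncrimping rate), $c_5$
(straightened-collagen modulus) and $\lambda^\ast$.

Parameter interpretation and typical magnitudes (from cadaveric Achilles
fits): $c_1 \sim 10\text{--}160$ MPa, $c_3 \sim 2\text{--}37$ MPa,
$c_4 \sim 3\text{--}155$, $c_5 \sim 1000$ MPa. The optimizer bounds
($c_1\in[1,300]$, $c_3\in[0.1,60]$, $c_4\in[1,200]$) span those observed
ranges with headroom.

Design choices that the source material left open:

* **Near-incompressibility.** Tendon is mostly water; no volumetric law is
  standard in this literature. We use a multiplicative isochoric/volumetric
  split with $U(J) = \tfrac{\kappa}{2}(\ln J)^2$ and $\kappa = 1000\,c_1$
  by default. At that stiffness the single-element uniaxial response matches
  the fully incompressible closed form $c_1(\lambda^2 - 1/\lambda) +
  \lambda F_2'(\lambda)$ to well under 1%, which is what makes that closed
  form usable as an independent oracle for the solver.
* **$\lambda^\ast$** is fixed at 1.03 (configurable) and is never fitted:
  the model is calibrated as a five-coefficient family with $c_6$ slaved to
  continuity. 1.03 sits in the 2--4% toe-to-linear transition range typical
  of energy-storing human tendon.
* **Fiber stretch is isochoric** ($\bar\lambda$, computed from
  $J^{-1/3}F$), for consistency of the split; at tendon strains the
  difference from the total stretch is negligible but the split keeps the
  volumetric penalty from leaking into the fiber stress.
* **$F_2$ integration constants** are chosen so $F_2(1)=0$ and $F_2$ is
  $C^1$ at $\lambda^\ast$. The exponential branch integrates to an
  exponential-integral (Ei) term; the energy is only needed for the
  stress-consistency checks, so the Ei evaluation lives on the R side
  (`pracma`) while the solver works with stresses in closed form.

## Geometry and meshing

The free tendon is described by a `cross_section_profile`: elliptical
sections (semi-axes, centroid offsets) at stations along the axis.
Convention: x = medial(+), y = anterior(+), z = distal (0 mm) to proximal.
The default geometry is a 60 mm free tendon with stations at 0/20/40/60 mm
(the latter three mirroring typical 2/4/6 cm ultrasound planes), mid CSA
near 70 mm^2, medio-lateral aspect ratio 2.8, a slightly waisted
mid-portion, and a gentle medial/anterior bow of the centroid line. The bow
matters: under axial load through offset section centroids it produces the
medial stress concentration that makes the compartment comparison
non-trivial.

`build_tendon_mesh()` lofts the sections into trilinear hexahedra. The
cross-section is discretized by mapping a structured grid on the square
smoothly onto the ellipse (the "elliptical" square-to-disk map), which
avoids the polar-mesh center singularity; the section boundary is an
inscribed polygon, so the meshed area is within 2% of $\pi a b$ at the 6x6
default in-plane resolution. Volumetric locking near incompressibility is
handled by mean dilatation: the volumetric pressure of each element is
evaluated from its average dilatation rather than pointwise.

Compartments (medial/lateral) split elements by the sign of the element
centroid's x-offset from the section centroid. Sub-tendons are angular
sectors around the section centroid, anticlockwise from the medial axis,
assigned greedily by accumulated cell area, so achieved fractions are
within one element of the targets and the partition is identical in every
axial layer.

**Sub-tendon areas vs. sub-tendon forces.** The triceps-surae force split
follows the muscles' PCSA ratio 6:2:1 (soleus : medial gastrocnemius :
lateral gastrocnemius). Cadaveric morphometry, however, puts the soleus
sub-tendon at only about half of the tendon cross-section. The default
`label_subtendons()` targets are the 6:2:1 fractions; the study drivers
deliberately label with anatomical fractions (0.52/0.35/0.13,
`study_config()$area_fractions`) while splitting force 6:2:1. This
force-to-area mismatch is what makes the loading genuinely differential: if
each sub-tendon's area share equalled its force share, the applied traction
would be uniform by construction and there would be nothing for fascicle
twist to redistribute.

`ffd_scale_csa()` implements the free-form mid-section morph used by the
sensitivity study: in-plane coordinates scale about the section centroid by
$s^{w(z)/2}$ with $w=\sin^2(\pi \tilde z)$, so the mid-section area scales
exactly by $s$ while the end sections are untouched.

## Continuum fascicle twist

Twist is distributed linearly along the axis: a material point at axial
fraction $t$ is rotated about the centroidal long axis by $t\,\theta$,
giving helical fascicle paths whose normalized tangents
$\propto c'(z) + \psi'(z)\,\hat z \times p$ form the analytic twisted
fiber field (`analytic_twist_directions()`). Anticlockwise (viewed from
proximal) corresponds to the right limb.

The continuum embedding mirrors a field-fitting workflow: a uniform data
cloud (4^3 points per element by default) records straight and twisted
directions; the minimal rotation taking straight to twisted at each point
is decomposed into Z-Y-Z Euler angles; and the three angle components are
fitted as trilinear nodal fields by sparse least squares
(`fit_euler_field()`), then interpolated to Gauss points and applied to the
straight directions (`evaluate_fiber_at_gauss()`).

One representation detail is load-bearing: the Euler angles are stored in a
*local cylindrical frame* (circumferential, radial, axial about the
centroid line), not the global frame. For a helical rotation the global
decomposition has an azimuth that wraps by $2\pi$ around the section --
un-interpolatable as a nodal field -- whereas in the local frame the same
rotation is a pure $R_y(\beta)$ with $\beta = \arctan(r\psi')$: smooth in
radius, constant in azimuth, zero on the axis. Near-gimbal rotations
($\beta \approx 0$) resolve the redundant third angle to zero for
determinism. The round-trip accuracy (generate -> fit -> evaluate vs. the
analytic helix) is well under 0.1 degrees RMS at default cloud density, far
inside the 2-degree acceptance bound; the pipeline uses the fitted route by
default (`fiber = "fitted"`), with the analytic field available both as the
oracle and as a cheaper stand-in where the two are interchangeable.

## The static solver

`solve_static()` is a standard total-Lagrangian Newton-Raphson scheme:
incremental load stepping with automatic bisection on failure, a
backtracking line search on the force residual, and honest convergence
reporting (an unconverged state is returned flagged, never silently
accepted). The element tangent is assembled by central finite differences
on the element's 24 dofs -- affordable at desk scale because the
reference-configuration quantities are precomputed per element and each
perturbed residual costs only the constitutive update. Relative
force-residual tolerance is 1e-8 (1e-6 inside calibration objectives, where
marker positions are converged far beyond the optimizer's needs), with at
most 50 iterations per step.

Sub-tendon interfaces are node-to-node constraints on conforming,
geometrically coincident surfaces, enforced with Lagrange multipliers:
`bonded` ties all three components, `frictionless_sliding` ties only the
interface-normal component (small-sliding assumption, sufficient for the
millimetre-scale tangential slips seen here). The bonded two-body model
reproduces the monolithic solution to solver tolerance, which is the
equivalence oracle used in the acceptance suite.

Markers are convected with the interpolated displacement field after a
Newton inversion of the trilinear map locates them in their elements.
Transverse rotation is measured exactly as in vivo studies define it: the
in-plane principal axis of the deformed proximal-most section relative to
the distal-most one (second moments of the section nodes), referenced to
the undeformed state; sections with principal-axis aspect ratio below 1.05
fall back to the mean azimuthal node rotation because a near-circular
section has no meaningful principal axis.

## Synthetic data and calibration

`population_model()` replaces the cadaver cohort. Positive quantities (CSA,
$c_1$, $c_3$, $c_4$, $c_5$) draw log-normally, moment-matched so sd = 0
collapses to the mean; twist draws normally (mean 37°, sd 14°, matching the
reported cadaveric range of roughly 11-65°) and clamps to [0°, 90°].
Defaults: CSA 70 ± 12 mm^2; $c_5$ 1200 ± 250 MPa (tendon Young's modulus
of order 1 GPa); $c_1$ 50 ± 20, $c_3$ 12 ± 5, $c_4$ 45 ± 15, consistent
with the spread of published cadaveric fits.

`simulate_experiment()` emulates the bench test: distal face clamped (the
potted calcaneus), total axial force over the proximal face by tributary
area, a ramp from zero to a peak nominal stress of 80 MPa (i.e. peak force
scaled to the specimen's mid CSA, as bench protocols load specimens
relative to their size) in 10 levels -- the upper levels must reach the
post-$\lambda^\ast$ linear regime or the terminal-gradient estimate of
$c_5$ is impossible, mirroring why bench protocols load close to failure
-- six equidistant posterior-surface markers, and i.i.d. Gaussian marker
noise (default 0.1 mm, the order of published marker-fit residuals).
What the generator does *not* emulate: viscoelastic conditioning and
hysteresis of the cyclic test (the model is hyperelastic; only the loading
envelope is meaningful), ultrasound segmentation error in the geometry,
marker dropout, and grip-slip artifacts. Green tests therefore demonstrate
internal consistency of the pipeline on its own model class, not fidelity
to any individual cadaver.

Calibration follows the bench procedure: $c_5$ comes first, from the
least-squares gradient of the terminal 30% of the Cauchy stress-stretch
curve (`estimate_c5()`; the optional `c1` argument subtracts the linearized
matrix contribution $c_1(2\lambda + \lambda^{-2})$ -- with the default
`c1 = 0` it is the raw experimental gradient, which on bowed geometry
carries a tens-of-percent bias from chord-based strain and bow
straightening; this bias is inherited by the study pipeline exactly as it
would be on a bench). Then (`optimize_material()`) minimizes the RMS
marker error over $(c_1, c_3, c_4)$ with $c_5, \lambda^\ast$ fixed --
a bounded simplex: Nelder-Mead on a tanh-log transform of the box, seeded
multistart (5 starts by default), $c_6$ recomputed from continuity inside
every objective evaluation, ties between equal-objective starts broken
toward the smallest $c_4$. The $(c_3, c_4)$ pair is strongly correlated (a
ridge: both shape the exponential knee), so the simplex needs on the order
of 150-200 iterations to localize the minimum; with a noiseless record the
recovery of all three parameters is then essentially exact, and the
acceptance bound of 5% is comfortable. Successive objective evaluations
warm-start each load level from the previous parameter set's solution,
which roughly halves the cost of a calibration.

## In-silico experiments

**Rupture** (`run_rupture()`): monotone load staircase in 100 N steps,
force split 6:2:1 over the sub-tendon proximal node sets (per-node weights
by tributary area). After each step the longest run of consecutive
over-threshold (100 MPa von Mises) Gauss points along any *axial Gauss
column* -- points sharing one in-plane position across the axially stacked
elements -- is evaluated; rupture is declared at the first load with a run
of 15 or more. The criterion's physical span depends on axial resolution
and is recorded per mesh (`run_length_mm`); at the cohort resolution of 8
axial layers (16 axial points) 15 points span most of the free tendon, so
the criterion behaves as a near-through-length failure condition rather
than the ~3 mm local one it represents on a research-scale mesh -- an
explicit desk-scale compromise, and the main reason rupture loads move in
whole 100 N quanta with only weak twist sensitivity (see Limitations).

**Sliding** (`run_sliding_study()`): the two-body soleus/gastrocnemius
model under displacement-controlled stretch, four cases (straight/twisted
x bonded/sliding), failure measured with the same run-length criterion,
and nodal von Mises patterns compared (squared Pearson correlation) against
the monolithic embedded-twist model at the largest stretch all cases
reached (10% when nothing fails earlier).

**Sensitivity** (`run_sensitivity()`): one-at-a-time ±1 population sigma on
mid-section CSA (free-form morph), $c_5$, and twist angle; 6 runs per
subject plus baseline; factors ranked by mean |% rupture-load change|.
Because the morph leaves the end sections untouched while the run-length
criterion spans nearly the whole length, CSA shrinkage is
rupture-neutral at this scale while CSA growth raises the rupture load --
the reported CSA sensitivity is therefore conservative.

**Statistics**: classical equal-variance one-way ANOVA
(`anova_oneway()`, via `stats::oneway.test`), with the all-identical
degenerate case reported as F = 0, p = 1 and flagged.

The full factorial driver (`run_full_study()`) chains everything: per
subject, one simulated experiment at the subject's own twist; then per
angle (0/15/30/45/60°), calibration against that same record and rupture
with the *fitted* parameters -- so, exactly as in the original 50-model
design, angle dependence can enter both through mechanics and through the
per-angle re-calibration. Every stage is seeded; identical config and seed
give byte-identical CSVs.

## Problem sizes and tolerances

The default scales were chosen so the whole pipeline runs on a laptop core:
calibration meshes 2x2x4 elements (the marker observables are essentially
one-dimensional, so in-plane resolution buys little identifiability),
rupture meshes 4x4x8 (the minimum that resolves the three sub-tendon
sectors, the compartment split, and 16-point axial Gauss columns),
six-layer 4x4 meshes for the field-fitting checks, and cohorts of 5-10
subjects. The end-to-end verification runs (`scripts/acceptance.R` and the
acceptance test file) use slightly leaner variants of the same scales --
4x3x8 cohort rupture meshes, 3x3x8 sensitivity meshes with 400 N staircase
increments, 2% strain steps in the sliding study, and single-start
calibrations of about 80 simplex iterations plus a polish restart -- which
keep the recovery error well below one percent while the full
reference-protocol values (100 N rupture increments, 100 MPa threshold, 15
Gauss points, 6:2:1 split) stay untouched. Mesh-refinement behavior (volume
convergence, tip-displacement Cauchy sequences within 2%) is covered by the
test suite.

## Known limitations

* Hyperelastic only: no viscoelasticity, damage, plasticity or
  poroelasticity; cyclic-test history effects are not represented.
* The 15-point run-length criterion is resolution-dependent in physical
  span; at desk-scale meshes it acts near-globally, which compresses
  between-condition rupture differences into 100 N quanta and makes
  twist-direction comparisons marginal (ties are common). Research-scale
  use should raise the axial resolution until `run_length_mm` approaches
  the few-millimetre scale the criterion is meant to represent.
* Small-sliding node-to-node interfaces: no large-sliding contact search,
  no friction.
* The synthetic geometry is a smooth idealization (lofted ellipses with a
  gentle bow); real subject-specific irregularity, which drives much of the
  between-subject spread in the original cadaveric study, is outside the
  generator's model class.
* The $c_5$ terminal-gradient estimate is biased on bowed geometry (by
  design, since it reproduces the bench procedure); the inverse-crime
  recovery checks use straight calibration-style configurations where the
  estimate is clean.
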