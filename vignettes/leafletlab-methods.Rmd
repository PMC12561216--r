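---
title: "Models and methods behind leafletlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind leafletlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`leafletlab` compares closed and semi-closed transcatheter heart-valve
leaflet designs along the whole evaluation chain: parametric geometry,
crimp-plus-pressure structural simulation with Pinwheeling Index
extraction, and ISO-5840-style hydrodynamic metrics computed from
pulse-duplicator pressure/flow waveforms. This vignette documents the
models, the tunable parameters, and the numerical choices, including the
places where the design was genuinely open and the package had to commit
to one interpretation.

## 1. Parametric leaflet geometry

A trileaflet valve design is described by the valve radius
$R_\mathrm{valve}$ (15 mm for the packaged 30 mm designs), the valve
height $H$, the commissure height/sagitta $h$, the commissure span $s$,
the opening degree and the free-edge shape. The opening degree

$$OD = \frac{\Delta L}{R_\mathrm{valve}} \times 100\,\%$$

is the relative retraction of the free edge from the valve axis in the
unloaded state; $OD = 0$ is a fully closed design whose leaflets meet at
the centerline, and with a linear free edge $OD$ cannot exceed 50 %,
where the three edges form the inscribed equilateral triangle. The span
is the side of that triangle, $s = \sqrt3\,R_\mathrm{valve}$ (the
stated equilateral-triangle construction; a literal span of
$3R_\mathrm{valve}$ would exceed the chord geometrically possible on the
circle). The sagitta defaults to 10 % of the valve diameter (3 mm at
30 mm). The free-edge frontal profiles are parabolas,
$y = -4h/s^2\,x^2 + h$ (concave) and $y = 4h/s^2\,x^2 - h$ (convex),
with the linear edge on the $x$-axis.

The seven packaged designs combine these parameters as G0 (0 %, linear)
through G6 (50 %, linear), with convex/concave/linear variants in
between (`valve_designs()`).

Two aspects of the 3D realization are not fixed by the parameter set and
were decided here:

* **Attachment scallop.** A cosine-blended scallop on the cylinder of
  radius $R_\mathrm{valve}$, from the commissure tops at height $H$ down
  to the belly nadir at height 0 (nadir height configurable). $H$
  defaults to $0.7\,D_\mathrm{valve}$; the comparison results are
  insensitive to $H$ because the Pinwheeling Index is measured in top
  view.
* **Interior surface.** A ruled loft between the attachment curve and
  the free-edge curve; the free edge's top view is the two-segment trace
  from commissure through the innermost point at distance $\Delta L$ to
  the other commissure (a single chord at $OD = 50\,\%$). This is the
  simplest surface honoring both boundary curves and is the only surface
  generator in this version.

The default mesh is 24 circumferential by 16 radial intervals per
leaflet; the structural runs in this package use 16 by 10 (about 1200
nodes for the valve), at which the free-edge polyline length is
converged well below the tolerances used anywhere downstream, and one
crimp-plus-pressure solve takes tens of seconds on one core. The
commissure columns of the ruled grid collapse to a point and are meshed
as triangle fans.

## 2. Structural model: crimp and diastolic pressure

The deployment experiment prescribes a uniform radial displacement of
every attachment vertex ($r \mapsto r(1 - c/100)$ for an oversizing of
$c\,\%$, angle and height unchanged), followed by a diastolic
transvalvular pressure of 20 mmHg on the arterial face. Crimp is ramped
in increments (default 4) with the structure relaxed to equilibrium
after each, then pressure likewise; ramping mirrors implant-then-load
physics and avoids snap-through artifacts.

The leaflets are modeled as constant-strain-triangle membranes
(total-Lagrangian, plane stress) with an isotropic nonlinear response:
the stress-strain curve is tabulated and the solver uses its secant
modulus at the element's current largest principal stretch. The packaged
material is a deliberate placeholder with the character of crosslinked
pericardium: bilinear with a 1 MPa toe up to 10 % strain and a 10 MPa
collagen-locked tangent beyond, Poisson ratio 0.49, density
1410 kg/m³, thickness 200 µm. Every structural number in this package
depends on this curve and it is replaceable via `material_model()`.

**Bending.** A pure membrane turned out to be qualitatively wrong for
the closed design: with zero bending energy, the excess free-edge
material of G0 is absorbed by vertical element-scale folds inside each
leaflet sector and the rotational wheeling pattern never nucleates. The
package therefore adds discrete hinge bending (restoring each interior
edge's rest dihedral angle) with stiffness
$k_b = b \cdot E_1 t^3 / (12(1-\nu^2))$. The default multiplier $b = 5$
is chosen by a mesh-consistency argument: it makes the shortest wrinkle
wavelength the default mesh can represent (about two elements)
marginally stable, so sub-element wrinkling that the mesh cannot resolve
is not replaced by spurious element-scale folds. With bending active the
membrane carries compression in full (`compression_retention = 1`);
a tension-field variant (compressive principal stresses scaled toward
zero) is available for bending-free runs, but mixing strong stress
clamping with bending forces is numerically unstable and is not the
default.

**Contact.** Node-to-triangle penalty contact acts between distinct
leaflets with gap equal to the shell thickness (midsurfaces of touching
shells are one thickness apart) and penalty stiffness
$10\,E_1 t$ per mm. Candidate pairs are rebuilt every 25 iterations by
centroid culling; each pair remembers which side of the triangle the
node was on so a node pushed through the surface is driven back.
Self-contact within a leaflet is off.

**Equilibrium search.** Dynamic relaxation: explicit pseudo-time
stepping with kinetic damping (velocities are zeroed whenever the total
kinetic energy passes a peak), fictitious nodal masses from a stiffness
bound using the curve's largest tangent modulus plus hinge and contact
contributions, and a per-step displacement cap of 10 % of the smallest
adjacent rest edge that bounds transients where the geometric stiffness
exceeds the small-strain mass estimate. Convergence is declared when the
RMS residual force on free nodes falls below $10^{-4}$ times the applied
load norm (the larger of boundary reactions and pressure loads, with an
absolute floor so unloaded states converge on round-off). When kinetic
damping stalls on contact chatter near equilibrium — common for the
wheeled closed design — up to three polishing rounds run with light
viscous damping and a frozen contact-pair set, which makes the force
field continuous and lets the residual reach the tolerance.

**Symmetry breaking.** The wheeled equilibrium is rotationally bistable
and unreachable from a perfectly symmetric state. Before pressurization
the free-edge vertices receive a seeded perturbation of 0.1 % of the
valve radius: a coherent tangential component whose sign (the wheel
direction) is drawn from the seed, plus Gaussian noise at one third of
that amplitude. The seed is recorded in the returned state; the
resulting Pinwheeling Index varies by only a few tenths of a percentage
point across seeds.

**Pressure orientation and variants.** Pressure acts on the downstream
(arterial) face as a uniform follower load (along current normals),
pushing the leaflets toward closure. Two alternatives are available:
`"axial"` (projected-area traction, the net transvalvular load only) and
`"shielded"` (follower pressure restricted to the wetted surface, with
triangles beyond a closed coaptation seal detected by flood fill
carrying no load). The follower default matches the usual static FE
treatment.

**Scale.** The Pinwheeling Index is scale-invariant, and the structural
runs use a proportional downscale factor of 0.5 applied to all lengths
including the shell thickness; the solver is exactly scale-equivariant,
which the test suite checks by comparing full- and half-scale solves.

## 3. Pinwheeling Index

$$PI = \frac{L_\mathrm{actual} - L_\mathrm{ideal}}{L_\mathrm{actual}}
\times 100\,[\%]$$

Both lengths are measured on the top-view (axial) projection, because
pinwheeling is defined and observed in top view and video-derived
in vitro values are necessarily 2D; the 3D arc lengths are reported
alongside. Two interpretation choices are logged here:

* $L_\mathrm{ideal}$ is the designed (unwheeled) free-edge top-view
  length scaled to the deployed radius,
  $L_\mathrm{ideal}(r) = L_\mathrm{design}\, r / R_\mathrm{valve}$ —
  after crimping, the ideal unwheeled edge spans the reduced lumen. The
  designed top-view length is $2\sqrt{(R/2-\Delta L)^2 + 3R^2/4}$ per
  leaflet ($2R$ for the closed design, $\sqrt3 R$ at $OD=50\,\%$).
* The index is evaluated per free edge; the package reports the three
  per-leaflet values and uses their mean for comparisons.

`generate_wheeled_edge()` builds planar traces of exactly known arc
length (a seeded transverse perturbation scaled by root finding), so the
whole measurement chain can be validated against closed-form PI values.

## 4. Hydrodynamic metrics

Cycles are segmented into windows of exactly one nominal period,
phase-aligned to the forward-flow upstroke (first sustained crossing of
5 % of peak flow, padded back by 1 % of the period so the positive
differential pressure period is not clipped at the window boundary).
The positive differential pressure period (PDP) is the longest
contiguous interval with ventricular above arterial pressure, with
sub-sample crossings by linear interpolation. Then, per cycle:

* TPG: trapezoidal time-average of the gradient over the PDP;
* $q_{v,\mathrm{RMS}}$: RMS forward flow over the PDP;
* $EOA = q_{v,\mathrm{RMS}} / (51.6 \sqrt{TPG/\rho})$ with the fluid
  density standardized to 1.005 g/cm³;
* volumes by trapezoidal integration: forward volume over the
  forward-flow phase, closing volume from the end of forward flow to the
  valve-closure instant, leakage over the remainder;
  $RF = (\text{closing} + \text{leakage})/\text{forward} \times 100$;
* cardiac output (net forward volume times cycle rate), whole-cycle MAP,
  and the systolic fraction as total positive-flow time over the period.

The valve-closure instant is not defined by the source standard's
summary; the package uses the first time after peak backflow at which
the flow has returned to within 1 % of the peak backflow magnitude of
zero, sustained for five samples, with a stall-detection fallback for
waveforms that settle on a nonzero leak plateau. Group statistics use
sample SD ($n-1$); `one_way_anova()` wraps the classical fixed-effects
F test and `variance_f_test()` the two-sided variance-ratio test with F
reported as larger over smaller variance.

## 5. Synthetic pulse-duplicator waveforms

No deposited recordings exist, so the generator emulates right-heart
normotensive conditions: cardiac output 5.0 L/min, heart rate 70 bpm,
35 % systolic time span, MAP 20 mmHg, arterial end-diastolic pressure
12 mmHg (ISO range 8-15) and ventricular peaks capped at 35 mmHg (ISO
18-35). The waveform templates are package inventions — only the summary
targets are sourced:

* forward flow: half-sine over the systolic span, scaled so the net
  forward volume matches the cardiac-output target;
* closing volume: triangular backflow spike (default 60 ms) immediately
  post-systole, followed by a 20 ms zero-flow gap (the valve is shut
  before leakage begins, which makes the closing/leakage split exactly
  recoverable);
* leakage: constant backflow over the remaining diastole;
* arterial pressure: systolic bump with exponential diastolic decay,
  pulse amplitude solved so the whole-cycle mean equals the MAP target
  exactly; ventricular pressure adds a half-sine gradient with PDP mean
  equal to the TPG target (default 2 mmHg, the mid-range of the measured
  groups) and relaxes exponentially (20 ms) to a 4 mmHg diastolic level.

At zero noise the analyzer recovers CO, MAP, HR, systolic fraction, TPG
and RF within 0.1 % (guaranteed within 1 %). Gaussian noise can be added
to pressures and flow; the default is zero because group variability is
modeled at the cycle level, not as sensor noise.

Cohorts draw per-cycle RF and TPG from truncated-normal distributions
(lower bound 0; plain normals would produce negative RF for the
high-variance control group) at the packaged group means and SDs, map RF
to closing and leakage volumes at a fixed 60:40 split (the split is not
reported anywhere; it is exposed as a parameter), and render one
multi-cycle waveform per valve. EOA is not matched independently: it
follows from the flow shape and the drawn TPG, which lands in the
measured range for the high-gradient groups. What passing these tests
shows is that the analysis chain is correct and that the statistical
conclusions follow from the reported group summaries — not that the
waveform shapes match any particular physical bench run.

## 6. What the simulations reproduce, and what they cannot

With the packaged placeholder material, half-scale 16x10 meshes and
seed-controlled symmetry breaking, the crimp-plus-pressure pipeline
yields a mean Pinwheeling Index near 9.4-9.9 % for the closed design and
near 8.1 % for the most-open semi-closed design — both within the
package's acceptance band around the reference finite-element values,
with the correct ordering and roughly half of the reported relative
separation. The compressed separation is expected: the hinge-bending
membrane is more compliant in the coaptation stack than full-integration
shells, and the placeholder curve is not the measured leaflet material.

The closure threshold is the one quantity the packaged conditions cannot
reproduce. Closing the central orifice below 0.5 % of the deployed lumen
area before ~13 % diameter reduction requires about 4-8 % free-edge
stretch at 20 mmHg (pure edge-length geometry), which the 1 MPa
placeholder toe does not deliver; the model closes the most-open design
at about 20 % reduction instead of within the 5-13.33 % window. A softer,
measured pericardium toe shifts the threshold directly; the packaged
curve is kept because all other comparisons are made with it and the
sensitivity is reported rather than hidden. The corresponding
acceptance check is expected to fail under the packaged conditions and
is left failing deliberately.

## 7. Reproducibility

Every stochastic element (solver symmetry breaking, cohort draws,
waveform noise) is seed-controlled; identical seeds reproduce results
bit-for-bit on one thread. `run_comparison_pipeline()` echoes its
configuration and seeds into the report it writes.
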