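# leafletlab

Comparative evaluation of closed and semi-closed transcatheter
heart-valve leaflet designs, for cardiovascular device engineers and
biomechanics researchers.

Transcatheter valves are usually manufactured in a closed shape with
initially coapting leaflets. After deployment the stent is oversized
relative to the annulus, so the excess leaflet material entangles
rotationally during closure — *pinwheeling* — which is linked to early
degeneration. Semi-closed designs retract the free edge from the valve
center (quantified by the opening degree, `OD = ΔL / R_valve × 100 %`)
and rely on oversizing plus diastolic pressure for closure, trading
coaptation reserve for less excess tissue.

`leafletlab` implements the full evaluation chain for a family of seven
30 mm reference designs (G0: closed, `OD = 0`; G1–G6: semi-closed with
increasing material reduction and linear/concave/convex free edges):

* **Geometry** — parametric trileaflet surface meshes from the design
  parameters (`valve_designs()`, `assemble_valve()`), with ASCII
  STL/VTK/OBJ export.
* **Structural simulation** — radial crimp (oversizing) plus 20 mmHg
  diastolic pressure on a nonlinear membrane model with hinge bending,
  leaflet–leaflet penalty contact and dynamic-relaxation equilibrium
  search (`solve_static()`), in compiled code.
* **Pinwheeling Index** — from simulated or digitized free-edge traces:

  `PI = (L_actual − L_ideal) / L_actual × 100 [%]`

  with both lengths measured on the top-view projection
  (`pi_from_state()`, `pinwheeling_index()`).
* **Hydrodynamics** — ISO-5840-style per-cycle metrics from
  pulse-duplicator pressure/flow waveforms: transvalvular pressure
  gradient TPG over the positive differential pressure period, RMS
  forward flow, the Gorlin-type effective orifice area
  `EOA = qvRMS / (51.6 √(TPG/ρ))`, forward/closing/leakage volumes and
  the regurgitation fraction RF (`analyze_waveform()`), plus one-way
  ANOVA and variance F tests across design groups.
* **Synthetic pulse duplicator** — seeded right-heart normotensive
  waveform generator (CO 5.0 L/min, HR 70 bpm, MAP 20 mmHg, 35 %
  systole) and per-group cohorts parameterized by the packaged reference group
  means/SDs, so the whole chain runs without any external data
  (`generate_waveform()`, `generate_cohort()`).

## Worked example

Simulate the closed control design under 10 % diameter reduction and
20 mmHg diastolic pressure (half-scale model) and extract its
Pinwheeling Index:

```r
library(leafletlab)

mesh <- assemble_valve(valve_designs()$G0, n_circ = 16, n_rad = 10,
                       scale = 0.5)
lc <- crimp_loadcase(oversizing = 10, pressure_mmHg = 20,
                     scale_factor = 0.5, seed = 7)
state <- solve_static(mesh, pericardium_material(), lc)
pi_from_state(state)
#> <pi_report G0>  deployed radius 6.750 mm
#>  leaflet l_actual l_ideal l_actual_3d    pi
#>        1    14.98    13.5       15.88 9.867
#>        2    14.98    13.5       15.88 9.867
#>        3    14.98    13.5       15.88 9.867
#>   mean PI = 9.87 %
```

The deformed free edges are about 10 % longer in top view than the
ideal unwheeled edge spanning the crimped lumen — the leaflets have
wheeled. The same pipeline on the most-open semi-closed design G6
yields a mean PI of 8.13 %: less pinwheeling with less leaflet
material, the central comparison the package is built around.

Analyze a synthetic pulse-duplicator run:

```r
wf <- generate_waveform(duplicator_settings())
met <- analyze_waveform(wf, cycle_rate = 70, n_cycles = 10)
round(colMeans(met[c("tpg", "eoa", "rf", "cardiac_output", "map")]), 3)
#>            tpg            eoa             rf cardiac_output            map
#>          2.000          3.887          6.539          5.001         20.001
```

TPG in mmHg, EOA in cm², RF in %, cardiac output in L/min, MAP in
mmHg — the analyzer recovers the generator's targets (CO 5.0, MAP 20,
TPG 2.0) to a fraction of a percent.

`run_comparison_pipeline()` chains both arms over all seven designs and
writes a JSON/CSV report with group summaries, ANOVA/F-test blocks and
the PI comparison.

## Limitations

The structural model is a membrane with discrete hinge bending, not a
shear-deformable shell; the packaged leaflet material is a documented
bilinear placeholder, not measured pericardium; and fluid–structure
interaction is out of scope. The closure threshold of the most-open
design is particularly sensitive to the material toe stiffness (see the
methods vignette), while the Pinwheeling Index comparison is
geometry-dominated and robust to it.
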