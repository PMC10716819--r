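---
title: "Models and methods behind photopath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photopath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photopath)
```

`photopath` post-processes extrusion-bioprinting toolpaths for a needle-mounted
ring of four 405 nm LED couples that photo-crosslinks the deposited strand
in-flight. This vignette is the package's own account of the models it
implements, the parameters that matter, and the choices made where the design
was genuinely open.

## Direction-aware LED scheduling

The scheduling input is an ordered list of Cartesian coordinates — the printing
path — carried as a chained sequence of `print` and `travel` moves in mm. For
each print move the XY projection defines a direction versor and its polar
angle θ, measured counterclockwise from the machine +x axis; the Z component of
a move never influences scheduling, so non-planar (conformal) paths are
scheduled exactly like their flat shadows.

The plane is divided into eight 45° sectors. Sectors are *centred* on the eight
principal directions (0°, 45°, …, 315°) with half-open boundaries
[centre − 22.5°, centre + 22.5°), so cardinal and diagonal motion are treated
symmetrically and every angle belongs to exactly one sector. The couple(s)
opposite the motion are activated: a cardinal sector drives the single couple
at (centre + 180°) mod 360°, a diagonal sector the two couples flanking the
opposite diagonal. Each sector maps to a numeric code X ∈ {1..8} (default
`code = sector + 1`, sector 0 = +x) emitted as a custom `M102 PX` G-code
command. The code↔combination table on the physical controller is a wiring
convention, so `sector_convention()` makes the mapping configurable; two
properties are invariant under any remapping:

* every active couple lies in the half-plane behind the motion
  (cos(azimuth − θ) ≤ cos 112.5°), and
* cardinal sectors drive exactly one couple, diagonal sectors exactly two.

Three conventions were fixed where the hardware documentation is silent:

* **`M102` precedes its move.** The command is emitted on the line immediately
  before the motion it governs, so the LEDs are already switched when the move
  starts. Consecutive duplicate codes are suppressed — the controller holds
  its last state.
* **Travel moves and degenerate segments hold the LED state.** Pure-Z hops and
  zero-length segments cannot be classified; switching off and back on would
  flicker mid-layer for no benefit. An `off_on_travel` option darkens travels
  for users who prefer it, and segments before the first classifiable print
  move get code 0 (all off).
* **No implicit trailing all-off.** `inject_led_commands()` emits exactly one
  command per code change; `trailing_off = TRUE` appends a final `M102 P0`
  for controllers that do not reset on program end. Keeping it explicit keeps
  the command count equal to the number of code changes, which is also the
  easiest invariant to test.

Two dialect extensions beyond the device's 1–8 range are documented as such:
code 0 (all off) and code 9 (all on — the control configuration in which every
LED is lit and the needle clogs).

## G-code dialect

The parser accepts the linear-move subset a bioprinter planner emits: `G0`
(travel) / `G1` with absolute `X/Y/Z` in mm, modal `F` (mm/min on the wire,
mm/s internally), `;` comments, `G21`/`G90`, and `M102 P<n>` preserved as move
annotations so a parse/emit cycle round-trips a schedule. Arcs (`G2`/`G3`) and
relative mode (`G91`) are rejected with the offending line number: the planner
upstream emits linear segments only, and silently linearizing arcs would hide a
planning error. Because the machine extrudes pneumatically there is usually no
`E` axis; a `G1` is therefore a print move unless it carries an `E` word whose
value does not increase. Coordinates are emitted at fixed 3-decimal precision,
which bounds round-trip error at 5·10⁻⁴ mm — an order of magnitude below the
0.4 mm needle.

## Cure-depth model

Whether a strand polymerizes through is quantified by the working curve

$$C_d = D_p \ln\frac{E}{E_c},$$

with penetration depth $D_p$ = 0.61 mm and critical energy $E_c$ = 0.48 mJ/mm²
for 5% w/v GelMA + 0.5% w/v LAP. The areal exposure of a spot of diameter
$w_0$ swept at speed $v_s$ by a couple of power $P_L$ is modeled as

$$E = \kappa\,\frac{P_L}{w_0\,v_s},$$

power spread over a strip of width $w_0$, with κ a dimensionless prefactor
absorbing the irradiance profile and dwell geometry of the real optics.
`calibrate_kappa()` anchors κ to a characterized operating point — by default
the device's worst case (one 60 mW couple, $w_0$ = 20 mm at the maximum
slider distance, $v_s$ = 5 mm/s, measured $C_d$ = 0.34 mm), giving κ ≈ 1.40.
The naive κ = 1 strip model under-predicts that anchor (0.136 mm), which is
expected: a top-hat strip ignores the overlap of successive dwell positions
and any beam convergence. Calibration against one measured point, then
extrapolation through the logarithm's parametric form, is standard
working-curve practice; `check_cure_path()` defaults to the calibrated κ and
exposes it as an argument.

The spot diameter follows the slider: the LED ring sits 1–15 mm above the
substrate and the spot grows from 10 mm to 20 mm diameter across that range.
Only the endpoints are characterized, so `spot_diameter()` interpolates
linearly — the simplest model consistent with both.

Per-segment verification walks the scheduled path: $v_s$ is the move's feed,
diagonal segments drive two couples so $P_L$ doubles (the couples are wired in
parallel, so powers add), and a segment passes when $C_d$ is at least the
layer thickness. Sub-critical exposures ($E \le E_c$) clamp to $C_d = 0$ with
a `no_cure` flag rather than erroring, keeping batch reports total. $C_d$ is
strictly increasing in $P_L$ and $D_p$ and decreasing in $v_s$ and $w_0$, so
the slowest speed and smallest spot always bound the batch from above — the
report's `worst_move` is the practical output.

## Exposure simulation

The raster simulator realizes the clogging argument quantitatively. Each
active couple projects a top-hat disk of diameter $w_0$; per (segment, couple)
the dwell time of the moving disk over each cell centre is the analytic chord
interval of the sweep — no time sub-stepping — and the deposited energy is
normalized so the emitted energy $P\,t$ is conserved exactly over a virtual
lattice that extends past the stored grid (out-of-grid cells account for lost
light). This makes conservation a machine-precision invariant rather than a
discretization-limited one, and grid totals are independent of cell size by
construction. A Gaussian spot (1/e² radius = spot radius) is available behind
`spot_model = "gaussian"`, with time quadrature.

Two geometric parameters deserve scrutiny:

* **Spot aim.** The couples are mounted 10.6 mm from the needle axis, but the
  beam axis orientation is not characterized. If each LED pointed straight
  down, its spot centre would sit 10.6 mm from the needle — *outside* the
  5–10 mm spot radius at every slider position, so a point needle would
  receive exactly zero energy under any schedule, including the all-on
  configuration that demonstrably clogs the needle within seconds. That
  observation rules the straight-down geometry out. The default model
  therefore aims the LEDs at the deposition zone: the spot centre is displaced
  toward the couple's azimuth by half the spot radius
  (`spot_offset_frac = 0.5`), so the deposition point always sits inside an
  active spot while most of the light lands on the trailing side. The
  mechanical-offset model remains available (`spot_offset_mm = 10.6`) for
  sensitivity analysis.
* **Needle extent.** The needle is tracked as a point at the nozzle XY
  position (a finite `needle_radius` is available, default 0). A couple
  contributes to needle exposure whenever the tip lies inside its offset disk;
  the contribution is the nominal top-hat irradiance $P/(\pi r^2)$ integrated
  over the segment dwell. Under the default aim geometry the needle sits
  inside every active spot, so the needle dose is proportional to
  (number of active couples) × (dwell time): the directional schedule (1–2
  couples) always receives strictly less than the all-on control (4 couples),
  with a ratio near ¼ on mostly-cardinal paths. The simulator makes that
  inequality a tested property on every generated fixture.

Not modeled: 3D light transport, substrate reflection, beam divergence beyond
the linear spot-growth law, dye absorption, and any coupling of curing back
into the optics.

## Characterization

Swelling is the relative weight change $100\,(W_i - W_0)/W_0$ over the
immersion time grid (0.5, 1, 1.5, 2, 3, 4, 24 h). Replicates are summarized as
mean ± sd per time point; the plateau onset is the first time point whose mean
changes by less than `tol` (default 0.5 percentage points) from the previous
one. On a saturating-exponential series with a 4% plateau and τ = 1 h — the
shape real samples follow — the rule fires between 2 and 3 h.

The elastic modulus is the least-squares slope of stress (kPa) against strain
(dimensionless fraction; percent accepted with an explicit unit flag) over the
linear portion of a compression curve taken to 30% strain. When the linear
window is not supplied, it is found by a lack-of-fit rule: the measurement
noise variance is estimated from the second differences of the stress series
(second differences annihilate any locally linear trend, leaving noise plus
curvature), and the widest contiguous window whose residual mean square stays
within twice that noise level is selected. This rejects the low-strain toe
region — toe points produce structural residuals far above the noise floor —
while tolerating honest noise. A fixed r² cutoff cannot do both: a noiseless
curve with a small toe fits to r² = 0.9995 while a genuinely linear curve with
realistic load-cell noise fits to r² = 0.9993. The fit reports r², the window
used and the underlying `lm` object; measured values for these gels sit around
50 kPa, which the examples mirror.

## Synthetic fixtures

Three generators emulate the printed geometries and make every module testable
without external data:

* `gen_grid_monolayer()` — serpentine raster, default 20 × 20 mm at one Z
  level. The requested pitch is rounded so an integer number of rows spans the
  box exactly (20 rows at nominal 1 mm pitch over 20 mm). Row-end connectors
  are print moves, as in a continuously extruded serpentine.
* `gen_multilayer_square()` — the 6-layer 20 × 20 mm characterization
  geometry, 0.2 mm layers, infill direction alternating 0°/90°. "50% infill"
  translates to a line spacing of 2 × the 0.4 mm line width = 0.8 mm.
* `gen_spherical_cap_infill()` — a non-planar stand-in for anatomical-defect
  printing: the same serpentine pattern draped over a spherical cap
  (default radius 30 mm over a 20 mm square → 3.5 mm of relief), rows
  subdivided to ≤ 1 mm so the path follows the curvature, layers offset
  vertically by the layer thickness (a shallow-cap approximation of a constant
  normal offset). Paths deeper than the 15 mm slider reach are flagged in the
  metadata. At infinite radius the generator reproduces the flat fixture
  exactly, which is tested.

What the fixtures do *not* emulate: real slicer output (seam placement,
variable feeds, retraction), arcs, measurement noise in the geometry, and the
actual anatomical defect meshes of the in situ experiments, which come from an
upstream non-planar slicer. Passing tests on these fixtures establish the
correctness of the scheduling logic, the cure arithmetic and the exposure
bookkeeping — not print quality on a physical machine.

## Problem sizes and numerical choices

The test suite runs the sector oracle over all 360 integer degrees plus 10 000
random angles, the rotation-equivariance property over 1 000 random paths, and
exposure simulations on 0.5 mm and 0.25 mm grids (≈10⁴–10⁵ cells); the whole
suite completes in well under a minute. Degenerate inputs are handled
explicitly: empty paths schedule to empty tables, zero-XY segments are flagged
rather than normalized, sub-critical exposures clamp with a flag, and a
zero-energy comparison denominator reports an infinite ratio with a
`zero_denominator` flag instead of NaN arithmetic. Angles are reduced modulo
360 before classification, and the sector boundary at exactly
centre + 22.5° belongs to the next sector (half-open convention), which the
brute-force oracle encodes independently.
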