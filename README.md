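# photopath

Direction-aware LED scheduling and cure-depth verification for
photo-crosslinking extrusion bioprinting.

## The problem

In extrusion bioprinting of low-viscosity photo-crosslinkable inks (e.g. GelMA
+ LAP), the deposited strand must be polymerized *during* printing or it
collapses. One hardware answer is a ring of four 405 nm LED couples mounted
around the printing needle at 90° from each other. But lighting all of them
indiscriminately floods the needle tip with stray light and polymerizes the ink
*inside* the nozzle — the needle clogs within seconds of starting. The fix is
directional: switch on only the LED couple(s) *opposite* the instantaneous
printing direction, so the light lands on the strand just deposited behind the
moving needle and the tip stays in relative shade.

`photopath` is the software side of that device, written for bioprinting
process engineers:

* **LED scheduling** — given a toolpath (G-code or an ordered list of Cartesian
  coordinates), compute each segment's XY direction versor, classify its polar
  angle θ into one of eight 45° angular sectors, and assign the numeric LED
  code X ∈ {1..8} of the couple(s) opposite the motion (one couple on cardinal
  directions, two on diagonals). Codes are injected into the G-code as a custom
  `M102 PX` command immediately before the move they govern.
* **Cure verification** — the Jacobs working curve
  `C_d = D_p · ln(E / E_c)` with `E = κ · P_L / (w_0 · v_s)`
  checks that every segment's cure depth `C_d` exceeds the layer thickness
  (`D_p`: resin penetration depth, mm; `E_c`: critical energy, mJ/mm²; `P_L`:
  couple power, mW; `w_0`: spot diameter, mm; `v_s`: scan speed, mm/s; `κ`: a
  dimensionless prefactor calibrated against a characterized operating point).
* **Exposure simulation** — an energy-conserving raster of light dose on the
  substrate plus a ledger of needle-incident energy, quantifying how much less
  stray light the needle receives under directional scheduling than under the
  all-on control.
* **Characterization utilities** — swelling percentage
  `100·(W_i − W_0)/W_0` with plateau detection, and elastic modulus by linear
  regression on the automatically detected linear portion of a compression
  stress–strain curve.
* **Synthetic toolpath generators** — serpentine monolayer grid, multilayer
  square (alternating 0°/90° infill) and a non-planar spherical-cap infill, so
  everything is testable without any external data.

## Worked example

```r
library(photopath)

# the 6-layer 20 x 20 mm, 50% infill characterization geometry
path <- gen_multilayer_square(size = 20, n_layers = 6, feed = 5)
path
#> <toolpath> 300 moves (294 print, 6 travel), layer 0.2 mm
#>   print length 3120.00 mm, bbox [0.00, 20.00] x [0.00, 20.00] x [0.00, 1.20] mm

sched <- schedule_path(path)
table(sched$code)
#>   0   1   3   5   7
#>   1 114 113  36  36

# worst-case conditions: max LED-substrate distance (spot 20 mm), 5 mm/s
report <- check_cure_path(path, sched, distance = 15)
report
#> <cure_report> 294 print segments | layer 0.2 mm | distance 15 mm
#>   PASS: every segment cures through the layer | min C_d = 0.340 mm at move 2

# stray light on the needle: directional schedule vs the all-on control
src <- source_params(P_L = 60, v_s = 5, distance = 15)
cmp <- compare_schedules(path, sched, all_on_schedule(path), src)
cmp$ratio
#> [1] 0.25
```

Reading the output: the alternating-direction infill uses only the four
cardinal codes (1 = +x, 3 = +y, 5 = −x, 7 = −y; code 0 is the initial
all-off state). Every segment's cure depth (0.34 mm at the slowest-curing
operating point) exceeds the 0.2 mm layer thickness, so each layer
polymerizes through and bonds to the one below. The directional schedule
delivers 4× less energy to the needle tip than the all-on control — the
quantitative version of "the control experiment clogged immediately, the
directional device printed fine".

Annotated G-code is one call away:

```r
writeLines(inject_led_commands(path, sched), "square.gcode")
```

and a shell entry point wraps the same pipeline
(`inst/scripts/photopath gen-path|annotate|check-cure|simulate|characterize`).

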