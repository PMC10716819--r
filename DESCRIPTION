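Package: photopath
Title: Direction-Aware LED Scheduling and Cure-Depth Verification for
    Photo-Crosslinking Extrusion Bioprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processes extrusion bioprinting toolpaths (G-code or ordered
    coordinate lists) to schedule a ring of 405 nm LED couples mounted around
    the printing needle: each path segment's XY direction versor is classified
    into one of eight 45-degree angular sectors and the LED couple(s) opposite
    the printing direction are activated through a custom M102 P<code> command
    injected into the G-code. Includes a Jacobs working-curve cure-depth model
    to verify that in-flight photopolymerization exceeds the layer thickness, a
    rasterized light-exposure simulator quantifying substrate dose and
    needle-incident energy (the needle-clogging rationale for directional
    scheduling), swelling and compression-modulus characterization utilities,
    and synthetic toolpath generators (serpentine monolayer grid, multilayer
    square, spherical-cap non-planar infill) for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
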