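Package: gcwmorph
Title: Morphometry of Gas Cell Walls in Bread Dough from Polarized
    Multiphoton Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the starch granule phase of gas cell walls (GCWs)
    in proven bread dough from label-free multiphoton image stacks.
    Polarization-resolved backward and forward second-harmonic-generation
    (SHG) channels are fused into a complete starch outline image, the
    usable imaging depth is delimited from signal attenuation, granules
    are segmented and split by watershed, the wall envelope is delimited
    from the endogenous-fluorescence (EF) channel, and per-granule and
    per-wall morphometrics are reported: Max-Feret size distributions with
    A/B/C wheat starch typing, spherical-equivalent volume shares, areal
    starch fraction with threshold-sensitivity analysis, wall dimensions
    and string/intact classification. A ground-truthed synthetic scene
    generator emulating the optical phenomenology of polarized SHG and EF
    microscopy of dough (two-lobe polarization response, dark hilum,
    depth-dependent attenuation, axial elongation, shot noise) makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
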