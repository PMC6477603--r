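Package: gfmdlayer
Title: Green's Function Molecular Dynamics for Thin Elastic Sheets on
    Rough Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the normal contact between a thin elastic sheet,
    supported from behind by a uniform fluid pressure, and a rigid,
    randomly rough, self-affine counterface.  The elastic response of the
    finite-thickness sheet is represented per Fourier mode through a
    layer Green's function with a finite-width correction factor, and
    mechanical equilibrium under a hard-wall non-penetration constraint
    (optionally with short-range exponential adhesion) is found by damped
    Verlet relaxation in the spirit of Green's function molecular
    dynamics.  Includes a spectral generator for periodic self-affine
    height fields, contact observables (area-load curves, mean
    separation, elastic and adhesion energies), width-scaling analyses of
    the load-collapse coefficient and of the adhesion parameter, and a
    Persson-theory pressure-broadening predictor for cross-checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
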