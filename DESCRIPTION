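Package: perfusim
Title: Flow, Shear Stress and Oxygen Transport in Perfused Microscaffold Chambers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finite-volume simulator for millifluidic cell-culture chambers
    hosting arrays of 3D-printed microscaffolds. Solves creeping (Stokes)
    flow with a Brinkman treatment of the porous scaffold array and a
    resolved pore-scale unit-cell sub-model, extracts fluid velocities and
    wall shear stresses at probe locations, solves steady oxygen
    advection-diffusion with Michaelis-Menten cellular consumption, and
    sweeps perfusion flow rates against physiological windows for
    interstitial velocity, wall shear stress and oxygen tension to select
    an operating point. Includes manufactured-solution verification
    problems, a synthetic configuration generator, and CSV/VTK exporters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
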