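Package: discmech
Title: Multi-Parametric MRI and Compressive Biomechanics of Intervertebral Discs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links quantitative MRI of intervertebral discs (T1, T2,
    magnetization transfer ratio, apparent diffusion coefficient and
    fractional anisotropy) to compressive moduli and hydraulic
    permeabilities. Provides seeded generators for synthetic MRI signal
    series and phantoms, stress-relaxation and permeametry experiments and
    multi-group cohorts; voxelwise and region-of-interest relaxometry and
    diffusion-tensor fitting; biphasic and viscoelastic curve fitting for
    confined and unconfined compression; Darcy permeability estimation; and
    a cohort statistics layer (one-way ANOVA with Dunn-Sidak post hoc,
    multiple linear regression with variance-inflation diagnostics,
    principal component analysis, and Ward hierarchical clustering with
    natural-division detection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    deSolve,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse
Config/testthat/edition: 3
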