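Package: limbtract
Title: Limb-Specific Thalamocortical Tractometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-tractography analysis of limb-specific thalamocortical
    tracts. Selects streamline bundles against dilated single-voxel cortical
    seed regions (manual or activation-derived), computes whole-tract and
    along-tract summaries of diffusion metrics (MD, FA, AFD), hemispheric
    asymmetry indices, composite sensorimotor scores with min-max
    normalization and group-mean imputation, and the accompanying
    nonparametric group and correlation statistics (Kruskal-Wallis,
    Conover-Iman post hoc with FDR, age-corrected Pearson correlation).
    Includes a synthetic phantom generator producing streamline bundles,
    metric volumes, activation maps and behavioral cohorts so the whole
    pipeline can be exercised end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
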