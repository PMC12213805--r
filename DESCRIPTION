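Package: pahemo
Title: Non-Invasive Pulmonary Arterial Hemodynamics and Wall Shear Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying pulmonary arterial hypertension (PAH)
    hemodynamics from non-invasive measurements. Generates synthetic 4D-flow
    MRI studies of the pulmonary bifurcation with analytically known
    (Womersley) pulsatile velocity fields, reconstructs vessel volumes by
    Boolean mask combination, quantifies inlet flow waveforms, stroke volume
    and branch flow splits, estimates pulmonary arterial pressure from
    echocardiographic measurements (simplified Bernoulli and Chemla
    relations), tunes and integrates three-element Windkessel outlet models,
    simulates pulsatile generalized-Newtonian (Quemada) flow in an
    axisymmetric vessel with a projection scheme, computes wall shear stress
    and its time average (TAWSS) at both simulation and voxel resolution, and
    reproduces cohort-level correlations between TAWSS and mean pulmonary
    arterial pressure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
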