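Package: laaplan
Title: Preprocedural Planning Computations for Left Atrial Appendage Closure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometry and statistics for fluoroscopy-guided left atrial
    appendage (LAA) occluder planning from 3D surface models. Localizes a
    fluoroscopically annotated landing zone on a triangulated LAA surface by
    projection-line/mesh intersection, sizes the cross-section (maximum,
    minimum, perimeter-derived and area-derived diameters, ovality), predicts
    the patient-specific optimal C-arm angulation that projects the maximal
    diameter without foreshortening, reformats image volumes along the landing
    plane (MPR), and provides the method-agreement statistics used to compare
    imaging modalities (Bland-Altman, Pearson, normality-driven paired tests,
    ICC(2,1) with F-based confidence intervals). Ships a synthetic phantom
    generator with analytic ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml,
    car,
    ggplot2
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
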