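Package: vtfuse
Title: Fusion of SPECT Myocardial Perfusion Geometry with Electroanatomical Voltage Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Retrospective integration of SPECT/CT-derived left-ventricular
    endocardial geometry with catheter-based electroanatomical bipolar-voltage
    maps. Provides fiducial-based rigid (Kabsch) plus thin-plate-spline
    nonrigid registration, nearest-vertex projection of voltage points onto
    the SPECT mesh with resolution-dependent point-loss accounting, AHA
    17-segment viability scoring of both modalities, ROC-based threshold
    selection and segment-level concordance statistics. A synthetic-data
    module generates ground-truth-known LV meshes, perfusion defects, voltage
    clouds and paired fiducials so that every pipeline stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
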