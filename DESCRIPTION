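Package: rodmap
Title: Spinal Rod Contour Deformation and Fusion BMD Mapping from Serial CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies permanent contour deformation of a closed-loop
    lumbopelvic rod construct and maps bony-fusion bone-mineral-density
    (BMD) change from serial postoperative CT scans. Provides
    threshold-based segmentation with Dice evaluation, landmark-based
    rigid registration (Kabsch), cuberille surface meshing with
    Metro-style Hausdorff distance quality control, geodesic centerline
    extraction for tubular implants with per-axis deformation components,
    QCT phantom Hounsfield-to-BMD calibration, single-slice voxel
    finite-element BMD category mapping, and tie-aware Spearman and
    two-way mixed absolute-agreement ICC reliability statistics. A
    synthetic CT phantom generator with full ground truth makes every
    stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    igraph,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
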