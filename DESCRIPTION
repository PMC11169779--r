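Package: aortaseg
Title: Aortic Root CTA Segmentation Post-Processing and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the post-segmentation analysis of contrast-CT
    angiography of the aortic root: isotropic resampling and intensity
    normalization, connected-component cleanup of multi-class label
    volumes, clustering-based determination of the number of valve
    cusps with K-nearest-neighbour boundary refinement and anatomical
    leaflet naming, tricuspid/bicuspid (Sievers type 0 vs type 1) valve
    classification, and a full segmentation-quality metric suite (Dice,
    precision, recall, 95th-percentile Hausdorff distance, average
    symmetric surface distance). A deterministic synthetic aortic-root
    phantom generator provides paired image and ground-truth label
    volumes so that every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    cluster,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
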