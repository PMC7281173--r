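Package: marrowrad
Title: PET Radiomics Pipeline for Bone-Marrow Involvement Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end [18F]FDG-PET radiomics pipeline for predicting
    lymphomatous bone-marrow involvement from pelvic bone uptake: relative-SUVmax
    metabolic tumor volume segmentation, 3D gray-level co-occurrence matrix
    (Haralick) texture features with SUV metrics, parametric empirical-Bayes
    ComBat scanner harmonization, a principal-component radiomic signature
    (Kaiser criterion), and repeated 70/30 multi-layer-perceptron classification
    with Mann-Whitney AUC reporting. Includes a synthetic pelvic PET phantom and
    cohort generator (Gaussian-random-field marrow texture, focal lesions,
    scanner batch effects) so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    sva,
    yaml,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
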