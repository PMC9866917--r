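Package: ihcsubtype
Title: Molecular Subtype Diagnosis from Immunohistochemical Images
Version: 0.1.0
Authors@R: person("HIAMS", "Tools", email = "tools@example.org",
    role = c("aut", "cre"))
Description: Rule-based diagnosis of breast-cancer molecular genetic
    subtypes (Luminal A, Luminal B, HER2/neu-amplified, basal-like) from a
    stack of four immunohistochemical microscopy images (ER, PR, HER2/neu,
    Ki-67). Implements adaptive preprocessing (PSNR-probed median filtering
    and step-table brightness gain), biomarker-specific threshold-band plus
    marker-controlled watershed segmentation, the two diagnostic indicators
    (relative positive area and the ordinal staining-intensity
    coefficient), an IF-THEN knowledge base for parameter selection, and a
    seeded synthetic-image generator with exact ground truth for validation
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    digest,
    jsonlite,
    jpeg,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
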