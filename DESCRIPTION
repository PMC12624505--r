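Package: lifetracer
Title: Peak Detection, Feature Alignment and Classification for GCxGC-HRTOF-MS Biosignature Screening
Version: 0.1.0
Authors@R:
    person("LifeTracer", "Developers", email = "lifetracer@example.org", role = c("aut", "cre"))
Description: Converts raw two-dimensional gas-chromatography high-resolution
    time-of-flight mass-spectrometry (GCxGC-HRTOF-MS) scan tables into total
    ion images, detects chromatographic peaks by sigma-thresholding and
    density-based pixel clustering, applies a conservative denoising cascade,
    aligns peaks across samples into binary presence/absence features, and
    trains nested cross-validated classifiers that separate abiotic
    (meteoritic) from biotic (terrestrial) organic inventories. Includes
    automatic parameter calibration against a reference compound list,
    coefficient-ranked feature grouping of coeluting fragment ions,
    distributional statistics on peak attributes, and a synthetic-data
    generator with planted ground truth so that the whole pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
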