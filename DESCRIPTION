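Package: skinquant
Title: Quantitative Morphometry and Statistics for Immunofluorescent Skin Biopsy Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mask-based quantification of immunofluorescent skin biopsy
    sections for small fiber neuropathy studies: physical-unit morphometry on
    segmentation masks (micrometer expansion, sub-epidermal band derivation,
    basement-membrane extraction), automated intraepidermal nerve fiber
    density (IENFD), mean fluorescence intensity of axonal markers restricted
    to nerve fiber masks, dermal vessel-nerve proximity analysis, DFNS-style
    quantitative sensory testing z-scores, relative gene expression by the
    2^-ddCt method, and the accompanying two-group / contingency statistics
    layer. A synthetic skin-section and cohort generator with known ground
    truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
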