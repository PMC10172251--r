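Package: ciliapol
Title: Planar Cell Polarity and Beat-Frequency Quantification for Multiciliated Epithelia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies planar cell polarity of multiciliated epithelial
    tissues from traced cell contours, ciliary-patch contours and per-cilium
    basal-body/basal-foot point pairs: per-cilium beating vectors, per-cell
    translational and rotational polarity angles (patch displacement,
    beating orientation and their alignment), circular standard deviation,
    displacement strength, and group comparison by a permutation Watson U2
    test. Also estimates ciliary beat frequency from fluorescence time-lapse
    stacks via kymogram extraction and thresholded FFT peak detection, and
    ships ground-truth generators for synthetic polarized tissues and
    beating-cilium videos so every stage of the pipeline can be validated
    without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    tiff,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
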