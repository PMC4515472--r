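Package: gutquant
Title: Quantification of Lineage-Traced Intestinal Remodelling Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based quantification of dual-marker (ReDDM) lineage tracing in the
    adult Drosophila midgut, together with the companion assays used to characterise
    mating-induced intestinal remodelling: DAPI nucleus segmentation with size-based
    ploidy classification and RFP/GFP lineage-class assignment, gut morphometry
    (area, diameter, cell density), Oil Red O and thin-layer-chromatography lipid
    quantification, DART mass-spectrometry juvenile-hormone quantification against a
    calibration curve, comparative-Ct qPCR analysis, and the statistical layer applied
    to each readout (negative-binomial likelihood-ratio tests for mitosis counts,
    Welch and paired t tests, Mann-Whitney rank tests, Holm correction). A synthetic
    data generator renders ground-truthed midgut scenes, stained-gut images, mass
    spectra, Ct tables and count tables so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    graphics,
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
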