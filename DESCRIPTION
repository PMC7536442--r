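Package: desi3d
Title: 3D DESI Mass Spectrometry Imaging Reconstruction and Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An open pipeline for three-dimensional desorption electrospray
    ionisation mass spectrometry imaging (DESI-MSI) of serial tissue
    sections: imzML reading and writing, total-ion-current normalisation,
    peak picking and cross-section m/z binning, rigid section alignment and
    isotropic volume reconstruction, non-negative matrix factorisation
    segmentation into molecularly distinct regions, exact-mass lipid
    annotation with neutral-loss MS/MS arithmetic, and co-localization of
    ion distributions with fluorescence-derived hypoxia masks. Includes a
    ground-truthed synthetic serial-section phantom generator so every
    stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
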