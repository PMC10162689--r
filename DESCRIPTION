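Package: onctools
Title: Quantification Pipeline for the Tadpole Optic Nerve Crush Regeneration Assay
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis machinery for the Xenopus laevis tadpole optic nerve
    crush (ONC) regeneration assay: contralateral-normalized fluorescence
    profiles along delineated optic nerves, injured/contralateral tectal
    innervation ratios and denervation time courses, kymograph-based
    mitochondrial transport tracking with motility classification and
    velocity estimation, TIDE-style decomposition of Sanger traces into
    indel spectra with sgRNA screening and allotetraploid F1 genotype and
    dosage calling, retinal soma detection with ring partition and
    colocalization counts, and visual collision-avoidance behavior scoring.
    Every analysis ships with a seeded synthetic-data generator that
    emulates the assay's imagery and traces with machine-readable ground
    truth, enabling end-to-end parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    jsonlite,
    yaml,
    mgcv,
    pracma,
    EBImage,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
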