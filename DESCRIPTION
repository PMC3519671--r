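Package: hookdeg
Title: Hybridization-Mode-Aware RNA Degradation Analysis for GeneChip Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probe-level RNA-quality estimation and correction for 3'-expression
    GeneChip arrays. Transforms PM/MM probe intensities into hook coordinates
    grounded in the two-species Langmuir hybridization isotherm, fits the
    theoretical hook curve, and derives hybridization-mode-aware degradation
    statistics: the degradation hook and tongs plot, the tongs-opening parameter,
    positional intensity-decay profiles and fits, the two-point degradation ratio,
    a variable "threshold hook" for the 3'/5' control probe sets, and a positional
    correction of raw probe intensities. Includes a seeded chip simulator
    implementing the same isotherm with positional degradation for end-to-end
    parameter-recovery testing, plain-text probe-table input/output, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    minpack.lm,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
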