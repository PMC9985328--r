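Package: haploscan
Title: Haplotype-Block Selection Scans via the Positional Burrows-Wheeler Transform
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scans phased population haplotype data for signatures of positive
    selection. Maximal perfect haplotype blocks are enumerated in linear time
    with the positional Burrows-Wheeler transform, each block receives a
    closed-form maximum composite likelihood selection coefficient under a
    selective sweep model, and blocks explainable by genetic drift or recent
    common ancestry are removed by two model-based filters. Includes readers
    for phased VCF, PLINK genetic maps and BED masks, genome-track output
    (BED5/bedGraph), and coalescent simulators (sequentially Markov
    approximation, sweep-conditioned genealogies) used for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    IRanges,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
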