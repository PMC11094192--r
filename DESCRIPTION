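Package: gbskaryo
Title: Karyotyping of Wheat-Rye Amphidiploids from GBS Read Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects major chromosome rearrangements in allopolyploids
    (wheat x rye amphidiploids and related hybrids) from genotyping-by-
    sequencing (GBS) read counts in non-overlapping genomic bins. Implements
    counts-per-million scaling against euploid control samples, per-bin log2
    coverage ratios, penalized least-squares changepoint segmentation into
    integer copy-number states (0-4), classification of whole-chromosome,
    arm (telosomic) and segmental (terminal, interstitial, pericentric)
    dosage events, somatic chromosome number (2n) accounting, and dosage
    queries for named loci such as the Eml incompatibility alleles. A
    negative-binomial GBS count simulator with planted dosage events and an
    emitted truth set makes every stage verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Rsamtools,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
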