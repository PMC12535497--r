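Package: karyoskim
Title: Read-Coverage Karyotyping of Wheat-Alien Introgression Lines from
    Low-Pass ddRAD Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects whole-chromosome and segmental dosage changes (nullisomy,
    monosomy, disomic alien substitution, interstitial losses) in allopolyploid
    wheat and wheat-wild-relative introgression lines from low-pass
    genotyping-by-sequencing (ddRADseq) read coverage. Reads are assigned to a
    concatenated host+alien reference, multi-mapped reads are discarded to
    avoid homoeologous mis-assignment, binned read depth is normalized to a
    robust host baseline, tracks are segmented by coverage continuity, and
    per-chromosome dosage states are combined into a named karyotype estimate.
    Includes a synthetic-data module (toy allopolyploid genomes, in-silico
    MspI/SphI double digest, size selection, paired-end read simulation under
    an arbitrary karyotype) so the whole pipeline is testable without external
    data, plus an import path for real BWA-MEM alignments in SAM/BAM form.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    BiocGenerics,
    Biostrings,
    Rsamtools,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
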