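Package: wrkyfamkit
Title: Genome-Wide Identification and Evolutionary Analysis of WRKY
    Transcription-Factor Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide characterization of the WRKY
    transcription-factor family in plant genomes: motif-pattern
    identification of WRKY domains and their C2H2/C2HC zinc fingers,
    group/subgroup classification, intron mapping onto gene models,
    progressive alignment and neighbor-joining phylogenies with bootstrap
    support, tandem and microsynteny-based segmental duplication
    detection, Nei-Gojobori Ka/Ks estimation, branch-site codon-model
    likelihood-ratio tests for episodic positive selection, RPKM and
    fold-change expression analysis with 2^-ddCt qRT-PCR support, and
    reciprocal-best-hit ortholog group construction. Includes seeded
    simulators for annotated genomes, codon alignments and expression
    matrices so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
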