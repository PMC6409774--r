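Package: mapkminer
Title: Genome-Wide Mining and Characterization of MAPK Cascade Kinase Genes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for genome-wide identification and
    characterization of mitogen-activated protein kinase (MAPK) cascade
    genes (MPK and MKK subfamilies) in plant proteomes. Screens candidate
    kinases with an internally built profile hidden Markov model scored by
    local Viterbi log-odds with Gumbel e-value calibration, confirms
    candidates with degenerate signature motifs (P-loop, catalytic C-loop,
    activation T-loop T(D/E)Y and the MKK GTxxYMSPER motif), classifies
    accepted kinases into clades A-D by best local-alignment reference hits,
    and derives orthology-based gene names with paralog suffixes. Downstream
    stages summarize exon/intron structure and chromosome distribution,
    compute theoretical isoelectric points and molecular weights, cluster
    per-tissue log2 fold-change expression profiles, and run Tajima's
    relative rate and neutrality tests. Synthetic-data generators provide
    planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
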