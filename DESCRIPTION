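Package: dupevol
Title: Directed Evolution of Duplicated Fluorescent Genes: Simulation and
    Sequence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for directed-evolution
    experiments that compare single-copy and double-copy populations of a
    dual-color fluorescent protein gene. Provides a mutagenesis and
    FACS-truncation-selection simulator over two-copy palindromic plasmid
    amplicons, orientation recovery and per-copy variant calling from
    full-length amplicon reads, rule-based classification of gene copies as
    active or inactive, population statistics (mutation burden, average
    pairwise amino-acid distance, Nei-Gojobori dN/dS, allele-frequency
    trajectories, flow-cytometry gating), and binomial-GLM likelihood-ratio
    tests for differential enrichment of mutations between selection
    regimes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    dplyr,
    rlang,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
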