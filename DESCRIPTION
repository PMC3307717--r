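Package: dnmtHMM
Title: Hidden Markov Inference of DNA Methyltransferase Processivity and
    Substrate Preference from Double-Stranded Methylation Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits a hidden Markov model to double-stranded CpG methylation
    patterns collected by hairpin-bisulfite PCR, in which three independent
    two-state association chains (DNMT1 on the daughter strand, de novo
    methyltransferases DNMT3 on the parent and daughter strands) move along
    the DNA. Bayesian Markov chain Monte Carlo inference yields posterior
    distributions of per-bp reassociation and dissociation probabilities
    (hence association tract lengths and average association levels),
    maintenance and de novo methylation probabilities (hence hemi-preference
    ratios), and bisulfite measurement-error rates. Per-molecule decoding
    recovers the most likely enzymatic explanations and the posterior
    probability of each strand being the parent. A generative simulator, a
    pattern-file format with summary statistics, an adjacent-site
    permutation test for clustered hemimethylation, and a command-line
    interface are included.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
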