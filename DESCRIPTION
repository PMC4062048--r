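Package: ddpcrlink
Title: Droplet Digital PCR Linkage and Copy Number Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of duplex droplet digital PCR (ddPCR) experiments for
    gene linkage and copy number variation, motivated by the structurally
    diverse KIR (Killer-cell Immunoglobulin-like Receptor) complex. Converts
    droplet quadrant counts to Poisson concentration estimates, computes a
    chance-corrected linkage score (%L) for pairs of targets carried on one
    DNA fragment, contrasts restriction-digested against undigested aliquots
    to call haplotype motifs, estimates diploidy-corrected copy number
    against an invariant reference gene, clusters raw copy-number estimates
    into integer bins with a Gaussian mixture model, measures concordance
    between genotyping methods with Cohen's kappa, checks Mendelian
    segregation of copy numbers in nuclear families, and simulates droplet
    experiments (fragmentation, restriction digestion, stochastic
    confinement) from configurable haplotype genotypes.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
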