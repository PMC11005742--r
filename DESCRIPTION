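Package: sweepdann
Title: Domain-Adversarial Detection and Classification of Selective Sweeps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies selective sweeps (hard, linked-hard, soft,
    linked-soft, neutral) from phased haplotype data using a domain-adversarial
    convolutional neural network trained on coalescent-style simulations and
    aligned to the target genome via a gradient-reversal discriminator. Includes
    a 40-summary-statistic feature engine (site-frequency-spectrum, haplotype
    homozygosity, EHH/iHS/nSL, HAF and SAFE families), positional encoding of
    SNP-window statistics onto fixed genomic grids, a labeled 5-class sweep
    simulator with mismatch and robustness scenarios, deep ensembling,
    smoothGrad saliency, and simulated-vs-real distribution-mismatch
    diagnostics (per-statistic two-sample tests, joint PCA, discriminative
    classifier AUC with label-shuffle controls).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
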