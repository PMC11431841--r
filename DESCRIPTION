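Package: genoconcord
Title: Cross-Platform Genotype Concordance Evaluation for Target Capture
    Sequencing and SNP Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates agreement between genotypes called from deep target
    capture sequencing and genotypes from a SNP array on the same animals.
    Computes genotype concordance with a one-/two-allele mismatch
    decomposition, per-sample and per-SNP squared Pearson correlations,
    squared-weight Cohen's kappa, VanRaden genomic relationship matrices and
    their correlation, trio Mendelian-inconsistency screening, capture-depth
    quality control (IQR outliers, off-centre capture, low mapping-quality
    regions), sex assignment from sex-chromosome markers, opposing-homozygote
    parentage verification, and binomial down-sampling of allele depths with
    genotype re-calling. Includes a synthetic dual-platform simulator
    (Hardy-Weinberg founders, trios, sex chromosomes, per-platform error and
    depth models) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
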