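Package: gwasthresh
Title: Genome-Wide Significance Thresholds Under Linkage Disequilibrium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes and compares family-wise-error-controlling significance
    thresholds for case/control genome-wide association scans: the label
    permutation minP null of the Cochran-Armitage trend test, a banded
    multivariate-normal sliding-window approximation to that null, the
    effective number of independent tests from eigenvalues of the composite
    linkage-disequilibrium correlation matrix (the simpleM rule), and
    Bonferroni corrections based on haplotype-block counts from the Gabriel
    confidence-interval, solid-spine and four-gamete block definitions.
    Every candidate threshold is gauged against the shared permutation minP
    distribution as its corresponding family-wise alpha. Includes PLINK text
    pedigree input/output, per-SNP quality-control filters (call rate, minor
    allele frequency, exact Hardy-Weinberg test), and a haplotype-pool
    simulator producing case/control genotypes with block-structured
    linkage disequilibrium and a known ground-truth partition.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
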