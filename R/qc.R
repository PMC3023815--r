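#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test from genotype counts at one biallelic SNP.
#' Conditional on the observed allele counts, the number of heterozygotes
#' under HWE has the classical levene-haldane distribution; the p-value
#' sums the probabilities of all heterozygote counts no more probable
#' than the observed one.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (homozygous a, heterozygous,
#'   homozygous b). Total must be at least 1.
#' @return P-value in `[0, 1]`.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(length(n_aa) == 1, length(n_ab) == 1, length(n_bb) == 1)
  if (any(c(n_aa, n_ab, n_bb) < 0) || anyNA(c(n_aa, n_ab, n_bb))) {
    stop("genotype counts must be non-negative", call. = FALSE)
  }
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("at least one genotyped sample required", call. = FALSE)
  n_a <- 2 * n_aa + n_ab # rarer-or-not does not matter: distribution is symmetric in allele label
  probs <- hwe_het_probs(n_a, n)
  obs <- probs$p[match(n_ab, probs$het)]
  # tiny relative tolerance so ties in floating point count as ties
  sum(probs$p[probs$p <= obs * (1 + 1e-9)])
}

# Distribution of the heterozygote count conditional on allele count n_a
# among 2n alleles: P(h) proportional to 2^h * n! / (n_aa! h! n_bb!) with
# n_aa = (n_a - h)/2. Computed in log space and normalised.
hwe_het_probs <- function(n_a, n) {
  n_b <- 2 * n - n_a
  h <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  logp <- h * log(2) - lfactorial((n_a - h) / 2) - lfactorial(h) -
    lfactorial((n_b - h) / 2)
  logp <- logp - max(logp)
  p <- exp(logp)
  list(het = h, p = p / sum(p))
}

#' Per-SNP quality-control filter
#'
#' Applies the standard per-SNP genotyping filters: call rate strictly
#' greater than `call_rate_min`, minor allele frequency at least
#' `maf_min`, and exact Hardy-Weinberg p-value at least `hwe_alpha`. A
#' SNP failing several filters is reported once, attributed in the
#' precedence order call rate, then MAF, then HWE.
#'
#' @param x A [gwas_genotypes()] object.
#' @param call_rate_min Minimum call rate, exclusive (default 0.95).
#' @param maf_min Minimum minor allele frequency, inclusive (default 0.01).
#' @param hwe_alpha HWE exact-test p-value cutoff, inclusive
#'   (default `1e-6`).
#' @return A list with elements `data` (the filtered
#'   [gwas_genotypes()]) and `report`, a one-row tibble with columns
#'   `n_input_snps`, `n_removed_call_rate`, `n_removed_maf`,
#'   `n_removed_hwe`, `n_output_snps`.
#' @export
qc_filter <- function(x, call_rate_min = 0.95, maf_min = 0.01,
                      hwe_alpha = 1e-6) {
  stopifnot(inherits(x, "gwas_genotypes"), ncol(x$dosages) >= 1)
  st <- snp_stats(x)
  fail_cr <- !(st$call_rate > call_rate_min) | st$n_called == 0
  maf <- ifelse(is.na(st$maf), 0, st$maf)
  fail_maf <- maf < maf_min
  hwe_p <- purrr::pmap_dbl(
    list(st$n_aa, st$n_ab, st$n_bb),
    function(a, h, b) if (a + h + b == 0) 1 else hwe_exact_test(a, h, b)
  )
  fail_hwe <- hwe_p < hwe_alpha

  removed_cr <- fail_cr
  removed_maf <- !removed_cr & fail_maf
  removed_hwe <- !removed_cr & !removed_maf & fail_hwe
  keep <- !(removed_cr | removed_maf | removed_hwe)

  report <- tibble::tibble(
    n_input_snps = ncol(x$dosages),
    n_removed_call_rate = sum(removed_cr),
    n_removed_maf = sum(removed_maf),
    n_removed_hwe = sum(removed_hwe),
    n_output_snps = sum(keep)
  )
  list(data = subset_genotypes(x, snps = which(keep)), report = report)
}
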