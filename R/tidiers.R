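#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a minP null distribution
#'
#' @param x A `minp_null` object.
#' @param ... Unused.
#' @return A tibble with one row per replicate: `replicate`, `min_p`
#'   (ascending).
#' @export
tidy.minp_null <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x), min_p = as.numeric(x))
}

#' Summarise a minP null distribution
#'
#' @param x A `minp_null` object.
#' @param alpha Levels at which to report thresholds (default 0.05,
#'   0.01).
#' @param ... Unused.
#' @return A one-row tibble: `method`, `B`, `n_snps_tested`, `seed`,
#'   and one `threshold_<alpha>` column per level.
#' @export
glance.minp_null <- function(x, alpha = c(0.05, 0.01), ...) {
  out <- tibble::tibble(
    method = attr(x, "method"), B = attr(x, "B"),
    n_snps_tested = attr(x, "n_snps_tested"), seed = attr(x, "seed")
  )
  for (a in alpha) out[[paste0("threshold_", a)]] <- null_threshold(x, a)
  out
}

#' Tidy an LD block partition
#'
#' @param x An `ld_partition` object.
#' @param ... Unused.
#' @return The block tibble: `chrom`, `start_index`, `end_index`,
#'   `n_snps` (multi-SNP blocks only; singletons are implicit).
#' @export
tidy.ld_partition <- function(x, ...) x$blocks

#' Summarise an LD block partition
#'
#' @param x An `ld_partition` object.
#' @param ... Unused.
#' @return A one-row tibble: `algorithm`, `n_snps`, `n_blocks`,
#'   `n_singletons`, `n_tests`, `mean_block_size`.
#' @export
glance.ld_partition <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm, n_snps = x$n_snps,
    n_blocks = nrow(x$blocks), n_singletons = n_singletons(x),
    n_tests = block_test_count(x),
    mean_block_size = if (nrow(x$blocks)) mean(x$blocks$n_snps) else NA_real_
  )
}

#' Tidy a simpleM result
#'
#' @param x A `meff_result` object.
#' @param ... Unused.
#' @return The per-region tibble: `chrom`, `start_index`, `end_index`,
#'   `n_snps`, `m_eff`.
#' @export
tidy.meff_result <- function(x, ...) x$per_region

#' Summarise a simpleM result
#'
#' @param x A `meff_result` object.
#' @param alpha Level for the implied Bonferroni threshold
#'   (default 0.05).
#' @param ... Unused.
#' @return A one-row tibble: `m_eff_total`, `n_snps`, `n_regions`, `C`,
#'   `threshold`.
#' @export
glance.meff_result <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    m_eff_total = x$total, n_snps = x$n_snps,
    n_regions = nrow(x$per_region), C = x$C,
    threshold = bonferroni_threshold(alpha, x$total)
  )
}

#' Summarise a method comparison
#'
#' @param x A `threshold_comparison` from [compare_methods()].
#' @param ... Unused.
#' @return A one-row tibble of run metadata: `n_methods`, `n_snps`,
#'   `n_samples`, `B`, `n_iter`, `seed`.
#' @export
glance.threshold_comparison <- function(x, ...) {
  tibble::tibble(
    n_methods = length(unique(x$method)), n_snps = attr(x, "n_snps"),
    n_samples = attr(x, "n_samples"), B = attr(x, "B"),
    n_iter = attr(x, "n_iter"), seed = attr(x, "seed")
  )
}
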