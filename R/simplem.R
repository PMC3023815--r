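#' Composite LD correlation matrix for a SNP region
#'
#' Pearson correlation of dosage columns (composite LD, estimable
#' without phase), pairwise-complete over missing data. Monomorphic
#' columns get a unit diagonal and zero off-diagonals.
#'
#' @param x A [gwas_genotypes()] object.
#' @param cols Integer vector of SNP column indices (default: all).
#' @return A symmetric correlation matrix.
#' @export
composite_correlation <- function(x, cols = seq_len(ncol(x$dosages))) {
  stopifnot(inherits(x, "gwas_genotypes"), length(cols) >= 1)
  g <- x$dosages[, cols, drop = FALSE]
  if (anyNA(g)) {
    r <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
  } else {
    sds <- apply(g, 2, stats::sd)
    r <- suppressWarnings(stats::cor(g))
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  r[is.na(r)] <- 0
  diag(r) <- 1
  r
}

#' Effective number of tests from eigenvalues
#'
#' The simpleM rule: the smallest `m` such that the `m` largest
#' eigenvalues of the region's correlation matrix account for at least
#' a fraction `C` (default 99.5%) of the total variance.
#'
#' @param eigvals Non-negative eigenvalues (tiny negatives down to
#'   `-1e-8` are clipped to zero; anything more negative errors).
#' @param C Variance fraction in (0, 1], default 0.995.
#' @return Integer `m` in `[1, length(eigvals)]`.
#' @export
meff_from_eigenvalues <- function(eigvals, C = 0.995) {
  stopifnot(length(eigvals) >= 1, C > 0, C <= 1)
  if (any(eigvals < -1e-8)) {
    stop("correlation matrix has a substantially negative eigenvalue",
         call. = FALSE)
  }
  eigvals <- pmax(eigvals, 0)
  total <- sum(eigvals)
  if (total <= 0) stop("all eigenvalues are zero", call. = FALSE)
  cum <- cumsum(sort(eigvals, decreasing = TRUE))
  which(cum >= C * total - 1e-12)[1]
}

#' Cut the genome into analysis regions at LD-block boundaries
#'
#' Greedy accumulation of whole LD blocks (and singleton SNPs) per
#' chromosome: a region closes at the first block boundary reaching
#' `target_size` SNPs, or at the chromosome end. No region ever splits
#' a block, so between-region LD is minimal by construction.
#'
#' @param x A [gwas_genotypes()] object.
#' @param partition An `ld_partition` (e.g. [solid_spine_blocks()]); the
#'   source of cut points.
#' @param target_size Region size target in SNPs (default 5000).
#' @return A tibble of regions: `chrom`, `start_index`, `end_index`
#'   (1-based, inclusive, into the dataset's SNP columns), `n_snps`.
#' @export
choose_regions <- function(x, partition, target_size = 5000) {
  stopifnot(inherits(x, "gwas_genotypes"), inherits(partition, "ld_partition"),
            target_size >= 1)
  m <- ncol(x$dosages)
  units <- partition_units(partition, x$snps$chrom, m)
  out <- list()
  for (ch in unique(units$chrom)) {
    u <- units[units$chrom == ch, , drop = FALSE]
    start <- u$start[1]
    count <- 0L
    for (i in seq_len(nrow(u))) {
      count <- count + (u$end[i] - u$start[i] + 1L)
      closes <- count >= target_size || i == nrow(u)
      if (closes) {
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = ch, start_index = start, end_index = u$end[i],
          n_snps = as.integer(u$end[i] - start + 1L)
        )
        if (i < nrow(u)) start <- u$start[i + 1]
        count <- 0L
      }
    }
  }
  dplyr::bind_rows(out)
}

# every SNP as a unit: blocks as-is, inter-block SNPs as singletons
partition_units <- function(partition, chrom, m) {
  blk <- partition$blocks
  covered <- rep(FALSE, m)
  for (i in seq_len(nrow(blk))) {
    covered[blk$start_index[i]:blk$end_index[i]] <- TRUE
  }
  singles <- which(!covered)
  units <- rbind(
    data.frame(start = blk$start_index, end = blk$end_index),
    data.frame(start = singles, end = singles)
  )
  units <- units[order(units$start), , drop = FALSE]
  units$chrom <- chrom[units$start]
  units
}

#' simpleM effective test count
#'
#' Applies [meff_from_eigenvalues()] to the composite correlation of
#' every region and sums: the genome-wide effective number of
#' independent tests, used in place of the SNP count in a Bonferroni
#' adjustment.
#'
#' @param x A [gwas_genotypes()] object.
#' @param regions Region tibble from [choose_regions()]; default: one
#'   region per chromosome.
#' @param C Variance fraction (default 0.995).
#' @return An object of class `meff_result`: list with `per_region`
#'   (region tibble plus `m_eff`), `total` (integer), `C`, `n_snps`.
#' @export
simplem_meff <- function(x, regions = NULL, C = 0.995) {
  stopifnot(inherits(x, "gwas_genotypes"))
  m <- ncol(x$dosages)
  if (is.null(regions)) {
    chrom <- x$snps$chrom
    idx <- seq_len(m)
    regions <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(chrom = chrom, idx = idx), chrom),
      start_index = min(idx), end_index = max(idx),
      n_snps = dplyr::n(), .groups = "drop"
    )
  }
  covered <- unlist(purrr::map2(
    regions$start_index, regions$end_index, seq
  ))
  if (!identical(as.integer(sort(covered)), seq_len(m))) {
    stop("regions must cover every SNP exactly once", call. = FALSE)
  }
  meff <- purrr::map2_int(regions$start_index, regions$end_index, function(s, e) {
    r <- composite_correlation(x, s:e)
    ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
    as.integer(meff_from_eigenvalues(ev, C))
  })
  per_region <- dplyr::mutate(regions, m_eff = meff)
  structure(
    list(per_region = per_region, total = sum(meff), C = C, n_snps = m),
    class = "meff_result"
  )
}

#' @export
print.meff_result <- function(x, ...) {
  cat(sprintf(
    "<meff_result> M_eff = %d of %d SNPs over %d region(s) (C = %.3f)\n",
    x$total, x$n_snps, nrow(x$per_region), x$C
  ))
  invisible(x)
}
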