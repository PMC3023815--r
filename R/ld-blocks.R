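new_ld_partition <- function(blocks, n_snps, algorithm, params) {
  blocks <- tibble::as_tibble(blocks)
  stopifnot(all(c("chrom", "start_index", "end_index") %in% names(blocks)))
  blocks <- dplyr::arrange(blocks, .data$start_index)
  if (nrow(blocks)) {
    stopifnot(
      all(blocks$end_index >= blocks$start_index + 1L),
      all(blocks$start_index >= 1), all(blocks$end_index <= n_snps)
    )
    if (nrow(blocks) > 1 &&
        any(blocks$start_index[-1] <= blocks$end_index[-nrow(blocks)])) {
      stop("blocks overlap", call. = FALSE)
    }
  }
  structure(
    list(
      blocks = dplyr::mutate(
        blocks,
        n_snps = as.integer(.data$end_index - .data$start_index + 1L)
      ),
      n_snps = as.integer(n_snps), algorithm = algorithm, params = params
    ),
    class = "ld_partition"
  )
}

#' @export
print.ld_partition <- function(x, ...) {
  cat(sprintf(
    "<ld_partition:%s> %d blocks + %d singletons over %d SNPs (%d tests)\n",
    x$algorithm, nrow(x$blocks), n_singletons(x), x$n_snps,
    block_test_count(x)
  ))
  invisible(x)
}

n_singletons <- function(partition) {
  partition$n_snps - sum(partition$blocks$n_snps)
}

#' Number of tests implied by an LD block partition
#'
#' Blocks plus singleton (inter-block) SNPs, each counted as one test;
#' the count that the block-based Bonferroni corrections divide alpha
#' by.
#'
#' @param partition An `ld_partition` object.
#' @return Integer test count.
#' @export
block_test_count <- function(partition) {
  stopifnot(inherits(partition, "ld_partition"))
  nrow(partition$blocks) + n_singletons(partition)
}

#' Gabriel confidence-interval haplotype blocks
#'
#' The Gabriel et al. block definition as implemented in Haploview: a
#' pair is in "strong LD" when its |D'| CI lower bound reaches
#' `ci_lower_min` and upper bound reaches `ci_upper_min`; it shows
#' "strong evidence of recombination" when the upper bound falls below
#' `recomb_upper`; other pairs are uninformative. A candidate block is
#' a contiguous range whose endpoint pair is in strong LD and in which
#' at least `strong_fraction` of informative pairs are strong; blocks
#' are accepted greedily by decreasing length (ties to the leftmost),
#' skipping overlaps.
#'
#' @param x A [gwas_genotypes()] object.
#' @param ci_upper_min,ci_lower_min Strong-LD CI bounds
#'   (defaults 0.98 / 0.70).
#' @param strong_fraction Minimum fraction of informative pairs in
#'   strong LD (default 0.95).
#' @param recomb_upper CI upper bound below which a pair counts as
#'   recombinant (default 0.90).
#' @param window Maximum pair distance in SNPs (default 250).
#' @param pairs Optional precomputed [ld_pairs()] table (must cover
#'   `window`).
#' @return An `ld_partition` object.
#' @export
gabriel_blocks <- function(x, ci_upper_min = 0.98, ci_lower_min = 0.70,
                           strong_fraction = 0.95, recomb_upper = 0.90,
                           window = 250, pairs = NULL) {
  stopifnot(inherits(x, "gwas_genotypes"))
  m <- ncol(x$dosages)
  if (is.null(pairs)) pairs <- ld_pairs(x, window = window)
  strong <- pairs$ci_low >= ci_lower_min & pairs$ci_high >= ci_upper_min
  recomb <- pairs$ci_high < recomb_upper

  lag <- pairs$j - pairs$i
  nlag <- max(lag, 1L)
  csum <- function(flag) {
    # per-lag cumulative counts over start index i, for range sums
    out <- vector("list", nlag)
    for (d in seq_len(nlag)) {
      v <- numeric(m)
      sel <- lag == d
      v[pairs$i[sel]] <- as.numeric(flag[sel])
      out[[d]] <- cumsum(v)
    }
    out
  }
  cs_s <- csum(strong)
  cs_r <- csum(recomb)
  range_count <- function(cs, a, b) {
    # pairs (i, i + d) wholly inside [a, b]
    tot <- 0
    for (d in seq_len(min(nlag, b - a))) {
      hi <- cs[[d]][b - d]
      lo <- if (a > 1) cs[[d]][a - 1] else 0
      tot <- tot + (hi - lo)
    }
    tot
  }

  cand <- pairs[strong, c("i", "j"), drop = FALSE]
  if (nrow(cand)) {
    cand <- cand[order(-(cand$j - cand$i), cand$i), , drop = FALSE]
  }
  taken <- rep(FALSE, m)
  blocks <- list()
  for (r in seq_len(nrow(cand))) {
    a <- cand$i[r]; b <- cand$j[r]
    if (any(taken[a:b])) next
    ns <- range_count(cs_s, a, b)
    nr <- range_count(cs_r, a, b)
    if (ns + nr == 0) next
    if (ns / (ns + nr) >= strong_fraction) {
      taken[a:b] <- TRUE
      blocks[[length(blocks) + 1]] <- tibble::tibble(
        chrom = x$snps$chrom[a], start_index = a, end_index = b
      )
    }
  }
  new_ld_partition(
    if (length(blocks)) dplyr::bind_rows(blocks) else
      tibble::tibble(chrom = character(), start_index = integer(),
                     end_index = integer()),
    n_snps = m, algorithm = "gabriel",
    params = list(ci_upper_min = ci_upper_min, ci_lower_min = ci_lower_min,
                  strong_fraction = strong_fraction,
                  recomb_upper = recomb_upper, window = window)
  )
}

#' Solid-spine-of-LD haplotype blocks
#'
#' A block is a maximal contiguous run in which the first and last SNP
#' each have |D'| at least `dprime_min` with every SNP between them
#' (and with each other) — a "spine" of LD running end to end. Blocks
#' are grown greedily left to right.
#'
#' @param x A [gwas_genotypes()] object.
#' @param dprime_min Minimum |D'| (default 0.8).
#' @param window Maximum pair distance in SNPs (default 250); pairs
#'   beyond the window count as |D'| = 0.
#' @param pairs Optional precomputed [ld_pairs()] table.
#' @return An `ld_partition` object.
#' @export
solid_spine_blocks <- function(x, dprime_min = 0.8, window = 250,
                               pairs = NULL) {
  stopifnot(inherits(x, "gwas_genotypes"))
  m <- ncol(x$dosages)
  if (is.null(pairs)) pairs <- ld_pairs(x, window = window)
  dp <- pair_lookup(pairs, "d_prime", m)
  chrom <- x$snps$chrom
  blocks <- list()
  a <- 1L
  while (a < m) {
    b <- a
    # extend while the new endpoint has D' >= min with every block member
    while (b < m && chrom[b + 1L] == chrom[a]) {
      ok <- all(dp(a:b, b + 1L) >= dprime_min)
      if (!ok) break
      b <- b + 1L
    }
    if (b > a) {
      blocks[[length(blocks) + 1]] <- tibble::tibble(
        chrom = chrom[a], start_index = a, end_index = b
      )
      a <- b + 1L
    } else {
      a <- a + 1L
    }
  }
  new_ld_partition(
    if (length(blocks)) dplyr::bind_rows(blocks) else
      tibble::tibble(chrom = character(), start_index = integer(),
                     end_index = integer()),
    n_snps = m, algorithm = "solid_spine",
    params = list(dprime_min = dprime_min, window = window)
  )
}

#' Four-gamete haplotype blocks
#'
#' A SNP pair "shows recombination" when all four two-locus haplotypes
#' have estimated frequency at least `fourth_freq_cutoff` (the fourth
#' gamete can only arise by recombination or recurrent mutation).
#' Blocks are grown left to right, breaking before a SNP that shows
#' recombination with any SNP already in the current block.
#'
#' @param x A [gwas_genotypes()] object.
#' @param fourth_freq_cutoff Frequency cutoff for the rarest haplotype
#'   (default 0.01).
#' @param window Maximum pair distance in SNPs (default 250).
#' @param pairs Optional precomputed [ld_pairs()] table.
#' @return An `ld_partition` object.
#' @export
four_gamete_blocks <- function(x, fourth_freq_cutoff = 0.01, window = 250,
                               pairs = NULL) {
  stopifnot(inherits(x, "gwas_genotypes"))
  m <- ncol(x$dosages)
  if (is.null(pairs)) pairs <- ld_pairs(x, window = window)
  mh <- pair_lookup(pairs, "min_hap_freq", m, default = 0)
  chrom <- x$snps$chrom
  blocks <- list()
  a <- 1L
  while (a <= m) {
    b <- a
    while (b < m && chrom[b + 1L] == chrom[a]) {
      recombs <- mh(a:b, b + 1L) >= fourth_freq_cutoff
      if (any(recombs)) break
      b <- b + 1L
    }
    if (b > a) {
      blocks[[length(blocks) + 1]] <- tibble::tibble(
        chrom = chrom[a], start_index = a, end_index = b
      )
    }
    a <- b + 1L
  }
  new_ld_partition(
    if (length(blocks)) dplyr::bind_rows(blocks) else
      tibble::tibble(chrom = character(), start_index = integer(),
                     end_index = integer()),
    n_snps = m, algorithm = "four_gamete",
    params = list(fourth_freq_cutoff = fourth_freq_cutoff, window = window)
  )
}

# fast (i, j) -> statistic lookup from a pairs table; vectorised over i.
# Pairs absent from the table (beyond window, cross-chromosome, or
# monomorphic members) return `default`.
pair_lookup <- function(pairs, stat, m, default = 0) {
  key <- (pairs$i - 1) * m + pairs$j
  val <- pairs[[stat]]
  ord <- order(key)
  key <- key[ord]; val <- val[ord]
  function(i, j) {
    k <- (i - 1) * m + j
    pos <- findInterval(k, key)
    out <- rep(default, length(k))
    hit <- pos >= 1 & pos <= length(key)
    hit[hit] <- key[pos[hit]] == k[hit]
    out[hit] <- val[pos[hit]]
    out
  }
}

#' Memory-bounded chunked block detection
#'
#' Runs a block algorithm over successive SNP chunks, carrying the last
#' full LD block of each chunk into the next so no block is truncated
#' at a chunk boundary — the standard way to partition a chromosome
#' too large to analyse in one pass. On data whose LD range is well
#' inside `chunk_size` the stitched partition equals the single-pass
#' one.
#'
#' @param x A [gwas_genotypes()] object.
#' @param method One of `"gabriel"`, `"spine"`, `"fourgamete"`.
#' @param chunk_size SNPs per chunk (must exceed the longest block).
#' @param ... Passed to the block algorithm.
#' @return An `ld_partition` object.
#' @export
chunked_blocks <- function(x, method = c("spine", "gabriel", "fourgamete"),
                           chunk_size = 1000, ...) {
  stopifnot(inherits(x, "gwas_genotypes"), chunk_size >= 2)
  method <- match.arg(method)
  fn <- switch(method,
    gabriel = gabriel_blocks,
    spine = solid_spine_blocks,
    fourgamete = four_gamete_blocks
  )
  m <- ncol(x$dosages)
  blocks <- list()
  pos <- 1L
  while (pos <= m) {
    end <- min(pos + chunk_size - 1L, m)
    part <- fn(subset_genotypes(x, snps = pos:end), ...)
    blk <- part$blocks
    blk$start_index <- blk$start_index + pos - 1L
    blk$end_index <- blk$end_index + pos - 1L
    if (end >= m || nrow(blk) == 0) {
      blocks[[length(blocks) + 1]] <- blk
      pos <- end + 1L
    } else {
      # re-analyse from the start of the last full block next round
      lb_start <- max(blk$start_index)
      keep <- blk$end_index < lb_start
      blocks[[length(blocks) + 1]] <- blk[keep, , drop = FALSE]
      pos <- if (lb_start > pos) lb_start else end + 1L
      if (lb_start == pos && !any(keep)) {
        # single block spanning the whole chunk: accept it and move on
        blocks[[length(blocks)]] <- blk[which.max(blk$start_index), ,
                                        drop = FALSE]
        pos <- max(blk$end_index) + 1L
      }
    }
  }
  blk <- dplyr::bind_rows(blocks)
  alg <- switch(method, gabriel = "gabriel", spine = "solid_spine",
                fourgamete = "four_gamete")
  new_ld_partition(blk, n_snps = m, algorithm = paste0(alg, "_chunked"),
                   params = list(chunk_size = chunk_size))
}
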