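#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic
#' SNPs from unphased genotype counts. Every genotype cell is
#' phase-unambiguous except the double heterozygote, which the E-step
#' splits between the cis (AB/ab) and trans (Ab/aB) phases in
#' proportion to their current likelihood.
#'
#' @param counts 3x3 matrix of joint dosage counts: `counts[a + 1, b + 1]`
#'   is the number of samples with dosage `a` at the first SNP and `b`
#'   at the second.
#' @param tol Convergence tolerance on the largest frequency change
#'   (default `1e-8`).
#' @param max_iter Iteration cap (default 1000).
#' @return A list: `freqs` named vector `(p_ab, p_aB, p_Ab, p_AB)` where
#'   upper case marks the dosage-counted allele; `loglik`; `converged`;
#'   `n_iter`. Frequencies sum to 1.
#' @export
em_haplotype_freqs <- function(counts, tol = 1e-8, max_iter = 1000) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)), all(counts >= 0))
  n9 <- matrix(as.numeric(t(counts)), 1, 9) # row-major: (a,b) = 00,01,02,10,11,12,20,21,22
  fit <- em_freqs_vec(n9, tol = tol, max_iter = max_iter)
  list(
    freqs = c(p_ab = fit$p00[1], p_aB = fit$p01[1],
              p_Ab = fit$p10[1], p_AB = fit$p11[1]),
    loglik = fit$loglik[1],
    converged = fit$converged[1],
    n_iter = fit$n_iter[1]
  )
}

# Vectorised two-locus EM over many pairs. n9: pairs x 9 count matrix,
# columns in row-major (a, b) order 00,01,02,10,11,12,20,21,22 with a =
# dosage at SNP i, b = dosage at SNP j. Returns haplotype frequencies
# p00, p01, p10, p11 (first digit = allele at i, second at j).
em_freqs_vec <- function(n9, tol = 1e-8, max_iter = 1000) {
  ntot <- rowSums(n9)
  stopifnot(all(ntot > 0))
  two_n <- 2 * ntot
  # fixed haplotype contributions from phase-unambiguous cells
  k11 <- 2 * n9[, 9] + n9[, 8] + n9[, 6]  # (2,2)*2 + (2,1) + (1,2)
  k10 <- 2 * n9[, 7] + n9[, 8] + n9[, 4]  # (2,0)*2 + (2,1) + (1,0)
  k01 <- 2 * n9[, 3] + n9[, 6] + n9[, 2]  # (0,2)*2 + (1,2) + (0,1)
  k00 <- 2 * n9[, 1] + n9[, 2] + n9[, 4]  # (0,0)*2 + (0,1) + (1,0)
  ndh <- n9[, 5]                          # double heterozygotes
  # linkage-equilibrium start from observed allele frequencies
  pa <- (k11 + k10 + ndh) / two_n # alt-allele freq at i, double hets carry one
  pb <- (k11 + k01 + ndh) / two_n
  p11 <- pa * pb; p10 <- pa * (1 - pb); p01 <- (1 - pa) * pb
  p00 <- (1 - pa) * (1 - pb)
  # tiny cis-ward nudge: a table of pure double heterozygotes makes the
  # linkage-equilibrium start a stationary saddle of the EM map; any
  # informative cell swamps this perturbation otherwise
  eps <- 1e-4 * pmin(p10, p01)
  p11 <- p11 + eps; p00 <- p00 + eps
  p10 <- p10 - eps; p01 <- p01 - eps
  converged <- rep(FALSE, nrow(n9))
  it <- 0L
  repeat {
    it <- it + 1L
    cis <- p11 * p00
    trans <- p10 * p01
    frac <- ifelse(cis + trans > 0, cis / (cis + trans), 0.5)
    q11 <- (k11 + ndh * frac) / two_n
    q00 <- (k00 + ndh * frac) / two_n
    q10 <- (k10 + ndh * (1 - frac)) / two_n
    q01 <- (k01 + ndh * (1 - frac)) / two_n
    delta <- pmax(abs(q11 - p11), abs(q10 - p10),
                  abs(q01 - p01), abs(q00 - p00))
    p11 <- q11; p10 <- q10; p01 <- q01; p00 <- q00
    converged <- converged | delta < tol
    if (all(converged) || it >= max_iter) break
  }
  list(
    p00 = p00, p01 = p01, p10 = p10, p11 = p11,
    loglik = geno_table_loglik(n9, p00, p01, p10, p11),
    converged = converged, n_iter = it
  )
}

# log-likelihood of the 3x3 genotype table under random mating given
# haplotype frequencies (vectorised over pairs)
geno_table_loglik <- function(n9, p00, p01, p10, p11) {
  lg <- function(x) log(pmax(x, 1e-300))
  n9[, 1] * lg(p00^2) + n9[, 2] * lg(2 * p00 * p01) + n9[, 3] * lg(p01^2) +
    n9[, 4] * lg(2 * p00 * p10) +
    n9[, 5] * lg(2 * p11 * p00 + 2 * p10 * p01) +
    n9[, 6] * lg(2 * p01 * p11) +
    n9[, 7] * lg(p10^2) + n9[, 8] * lg(2 * p10 * p11) + n9[, 9] * lg(p11^2)
}

#' Pairwise LD statistics from haplotype frequencies
#'
#' Standard two-locus disequilibrium measures: `D = p_AB - p_A p_B`,
#' normalised `D' = |D| / D_max` with `D_max` the usual bound given the
#' allele frequencies, and `r2 = D^2 / (p_A p_a p_B p_b)`.
#'
#' @param freqs Haplotype frequency vector or list as returned by
#'   [em_haplotype_freqs()] (`p_ab`, `p_aB`, `p_Ab`, `p_AB` order when
#'   unnamed).
#' @return A one-row tibble: `d`, `d_prime`, `r2`.
#' @export
ld_stats <- function(freqs) {
  if (is.list(freqs) && !is.null(freqs$freqs)) freqs <- freqs$freqs
  p00 <- freqs[[1]]; p01 <- freqs[[2]]; p10 <- freqs[[3]]; p11 <- freqs[[4]]
  st <- ld_stats_vec(p00, p01, p10, p11)
  tibble::tibble(d = st$d, d_prime = st$d_prime, r2 = st$r2)
}

ld_stats_vec <- function(p00, p01, p10, p11) {
  pa <- p11 + p10 # allele A freq at locus 1
  pb <- p11 + p01
  if (any(pa <= 0 | pa >= 1 | pb <= 0 | pb >= 1)) {
    stop("monomorphic marginal: LD undefined", call. = FALSE)
  }
  d <- p11 - pa * pb
  dmax <- ifelse(d > 0,
    pmin(pa * (1 - pb), (1 - pa) * pb),
    pmin(pa * pb, (1 - pa) * (1 - pb))
  )
  d_prime <- ifelse(d == 0, 0, abs(d) / dmax)
  r2 <- d^2 / (pa * (1 - pa) * pb * (1 - pb))
  list(d = d, d_prime = pmin(d_prime, 1), r2 = pmin(r2, 1))
}

#' Likelihood-based confidence interval for |D'|
#'
#' Evaluates the genotype-table likelihood on a grid of |D'| values in
#' `[0, 1]` (haplotype frequencies parameterised by |D'| at the
#' observed allele frequencies, in the direction of the EM sign of D;
#' double heterozygotes summed over phases), normalises the grid to
#' unit mass, and reads off two-sided tail bounds — the construction
#' behind the Gabriel block definition's CI criteria.
#'
#' @param counts 3x3 joint dosage count matrix (as
#'   [em_haplotype_freqs()]).
#' @param grid Number of grid points (default 101).
#' @param coverage Two-sided coverage (default 0.90, giving 5% tails).
#' @return A one-row tibble: `ci_low`, `ci_high`.
#' @export
dprime_ci <- function(counts, grid = 101, coverage = 0.90) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)), sum(counts) > 0)
  n9 <- matrix(as.numeric(t(counts)), 1, 9)
  fit <- em_freqs_vec(n9)
  d_hat <- fit$p11 - (fit$p11 + fit$p10) * (fit$p11 + fit$p01)
  ci <- dprime_ci_vec(n9, sign(d_hat), grid = grid, coverage = coverage)
  tibble::tibble(ci_low = ci$lo[1], ci_high = ci$hi[1])
}

# Vectorised |D'| likelihood CI. n9 as in em_freqs_vec; d_sign gives the
# direction in which D' is swept (sign of the EM D estimate; 0 treated
# as positive). Allele frequencies are fixed at their observed values.
dprime_ci_vec <- function(n9, d_sign, grid = 101, coverage = 0.90) {
  np <- nrow(n9)
  ntot <- rowSums(n9)
  a_dos <- n9 %*% c(0, 0, 0, 1, 1, 1, 2, 2, 2)
  b_dos <- n9 %*% c(0, 1, 2, 0, 1, 2, 0, 1, 2)
  pa <- as.numeric(a_dos / (2 * ntot))
  pb <- as.numeric(b_dos / (2 * ntot))
  sgn <- ifelse(d_sign < 0, -1, 1)
  dmax <- ifelse(sgn > 0,
    pmin(pa * (1 - pb), (1 - pa) * pb),
    pmin(pa * pb, (1 - pa) * (1 - pb))
  )
  dmax <- pmax(dmax, 1e-12)
  gridv <- seq(0, 1, length.out = grid)
  ll <- matrix(NA_real_, np, grid)
  for (k in seq_len(grid)) {
    d <- sgn * gridv[k] * dmax
    p11 <- pmax(pa * pb + d, 0)
    p10 <- pmax(pa * (1 - pb) - d, 0)
    p01 <- pmax((1 - pa) * pb - d, 0)
    p00 <- pmax((1 - pa) * (1 - pb) + d, 0)
    ll[, k] <- geno_table_loglik(n9, p00, p01, p10, p11)
  }
  ll <- ll - apply(ll, 1, max)
  w <- exp(ll)
  w <- w / rowSums(w)
  cum <- t(apply(w, 1, cumsum))
  tail <- (1 - coverage) / 2
  lo <- numeric(np)
  hi <- numeric(np)
  for (i in seq_len(np)) {
    below <- c(0, cum[i, -grid]) # mass strictly below each grid point
    above <- 1 - cum[i, ]        # mass strictly above
    loi <- which(below <= tail + 1e-12)
    hii <- which(above <= tail + 1e-12)
    lo[i] <- gridv[max(loi)]
    hi[i] <- gridv[min(hii)]
  }
  list(lo = lo, hi = hi, mass = w, grid = gridv)
}

#' Pairwise LD table over a sliding window
#'
#' The package's pairwise engine: for every same-chromosome SNP pair at
#' most `window` positions apart it builds the joint dosage table,
#' fits two-locus haplotype frequencies by EM, and computes D', r2, the
#' |D'| likelihood CI and the minimum haplotype frequency (the
#' four-gamete statistic). All computations are vectorised across
#' pairs.
#'
#' @param x A [gwas_genotypes()] object.
#' @param window Maximum index distance between pair members
#'   (default 250).
#' @param grid,coverage CI construction parameters (see [dprime_ci()]).
#' @param chunk Pairs per CI batch (memory cap).
#' @return A tibble with one row per polymorphic pair: `i`, `j` (column
#'   indices, `i < j`), `chrom`, `d`, `d_prime`, `r2`, `ci_low`,
#'   `ci_high`, `min_hap_freq`.
#' @export
ld_pairs <- function(x, window = 250, grid = 101, coverage = 0.90,
                     chunk = 25000L) {
  stopifnot(inherits(x, "gwas_genotypes"), window >= 1)
  g <- x$dosages
  m <- ncol(g)
  if (m < 2) {
    return(tibble::tibble(
      i = integer(), j = integer(), chrom = character(),
      d = numeric(), d_prime = numeric(), r2 = numeric(),
      ci_low = numeric(), ci_high = numeric(), min_hap_freq = numeric()
    ))
  }
  chrom <- x$snps$chrom
  ind <- lapply(0:2, function(v) {
    z <- (g == v) * 1
    z[is.na(z)] <- 0
    z
  })
  res_i <- list(); res_n9 <- list()
  for (d in seq_len(min(window, m - 1))) {
    ii <- seq_len(m - d)
    jj <- ii + d
    same <- chrom[ii] == chrom[jj]
    if (!any(same)) next
    ii <- ii[same]; jj <- jj[same]
    n9 <- matrix(0, length(ii), 9)
    col <- 0L
    for (a in 0:2) {
      for (b in 0:2) {
        col <- col + 1L
        n9[, col] <- colSums(ind[[a + 1]][, ii, drop = FALSE] *
                               ind[[b + 1]][, jj, drop = FALSE])
      }
    }
    res_i[[d]] <- cbind(ii, jj)
    res_n9[[d]] <- n9
  }
  ij <- do.call(rbind, res_i)
  n9 <- do.call(rbind, res_n9)
  # drop pairs with a monomorphic member (LD undefined)
  ntot <- rowSums(n9)
  pa <- as.numeric(n9 %*% c(0, 0, 0, 1, 1, 1, 2, 2, 2)) / (2 * pmax(ntot, 1))
  pb <- as.numeric(n9 %*% c(0, 1, 2, 0, 1, 2, 0, 1, 2)) / (2 * pmax(ntot, 1))
  poly <- ntot > 0 & pa > 0 & pa < 1 & pb > 0 & pb < 1
  ij <- ij[poly, , drop = FALSE]
  n9 <- n9[poly, , drop = FALSE]
  if (!nrow(n9)) {
    return(tibble::tibble(
      i = integer(), j = integer(), chrom = character(),
      d = numeric(), d_prime = numeric(), r2 = numeric(),
      ci_low = numeric(), ci_high = numeric(), min_hap_freq = numeric()
    ))
  }
  fit <- em_freqs_vec(n9)
  st <- ld_stats_vec(fit$p00, fit$p01, fit$p10, fit$p11)
  lo <- numeric(nrow(n9)); hi <- numeric(nrow(n9))
  idx <- seq_len(nrow(n9))
  for (part in split(idx, ceiling(idx / chunk))) {
    ci <- dprime_ci_vec(n9[part, , drop = FALSE], sign(st$d[part]),
                        grid = grid, coverage = coverage)
    lo[part] <- ci$lo
    hi[part] <- ci$hi
  }
  out <- tibble::tibble(
    i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
    chrom = chrom[ij[, 1]],
    d = st$d, d_prime = st$d_prime, r2 = st$r2,
    ci_low = lo, ci_high = hi,
    min_hap_freq = pmin(fit$p00, fit$p01, fit$p10, fit$p11)
  )
  dplyr::arrange(out, .data$i, .data$j)
}
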