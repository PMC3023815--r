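#' Cochran-Armitage trend test for one SNP
#'
#' One-degree-of-freedom trend test of association between genotype
#' dosage and case status, with additive scores (0, 1, 2) — the test
#' permutation GWAS engines permute. The signed statistic is
#' \deqn{Z = \frac{\sum_i x_i (y_i - \bar y)}
#'   {\sqrt{\bar y (1 - \bar y) \sum_i (x_i - \bar x)^2}},}
#' asymptotically standard normal under the null; the p-value is
#' two-sided. Missing dosages are dropped pairwise.
#'
#' @param dosages Vector in `{0, 1, 2, NA}`.
#' @param labels Binary vector (1 = case, 0 = control), same length.
#' @return A one-row tibble: `z`, `p`, `n_used`, `monomorphic`. A SNP
#'   with zero genotype variance among used samples gets `z = 0`,
#'   `p = 1` and `monomorphic = TRUE`.
#' @export
trend_test <- function(dosages, labels) {
  stopifnot(length(dosages) == length(labels))
  use <- !is.na(dosages) & !is.na(labels)
  x <- dosages[use]
  y <- labels[use]
  if (sum(y == 1) < 1 || sum(y == 0) < 1) {
    stop("need at least one case and one control among non-missing samples",
         call. = FALSE)
  }
  ybar <- mean(y)
  ssx <- sum((x - mean(x))^2)
  if (ssx == 0) {
    return(tibble::tibble(z = 0, p = 1, n_used = length(x), monomorphic = TRUE))
  }
  z <- sum(x * (y - ybar)) / sqrt(ybar * (1 - ybar) * ssx)
  tibble::tibble(
    z = z, p = 2 * stats::pnorm(-abs(z)),
    n_used = length(x), monomorphic = FALSE
  )
}

#' Genome-wide trend-test scan
#'
#' Applies [trend_test()] to every SNP column, vectorised. Row order
#' follows the dataset's (chromosome, position) SNP order.
#'
#' @param x A [gwas_genotypes()] object.
#' @param labels Binary phenotype vector; defaults to `x$labels`.
#' @return A tibble with one row per SNP: `id`, `chrom`, `pos`, `z`,
#'   `p`, `n_used`, `monomorphic`.
#' @export
assoc_scan <- function(x, labels = x$labels) {
  stopifnot(inherits(x, "gwas_genotypes"))
  if (is.null(labels)) stop("dataset has no phenotypes", call. = FALSE)
  labels <- as.numeric(labels)
  st <- scan_stats(x$dosages, labels)
  tibble::tibble(
    id = x$snps$id, chrom = x$snps$chrom, pos = x$snps$pos,
    z = st$z, p = st$p, n_used = st$n_used, monomorphic = st$monomorphic
  )
}

# Vectorised trend statistics for a dosage matrix against one or many
# label vectors. `labels` may be a vector (returns per-SNP stats) or an
# n x B matrix of permuted labels (returns a SNPs x B matrix of |Z|,
# used by the permutation engine). Any missing dosage forces the slow
# per-SNP path for that SNP.
scan_stats <- function(g, labels) {
  n <- nrow(g)
  miss <- is.na(g)
  any_miss_col <- colSums(miss) > 0L
  z <- numeric(ncol(g))
  n_used <- integer(ncol(g))
  mono <- logical(ncol(g))

  ok <- !is.na(labels)
  if (!all(ok)) {
    g <- g[ok, , drop = FALSE]
    labels <- labels[ok]
    return(scan_stats(g, labels))
  }

  ybar <- mean(labels)
  yc <- labels - ybar
  # complete columns in one BLAS pass
  cc <- which(!any_miss_col)
  if (length(cc)) {
    gc <- g[, cc, drop = FALSE]
    num <- as.numeric(crossprod(gc, yc))
    ssx <- colSums(gc^2) - colSums(gc)^2 / n
    den <- sqrt(ybar * (1 - ybar) * ssx)
    zi <- ifelse(ssx == 0, 0, num / ifelse(den == 0, 1, den))
    z[cc] <- zi
    mono[cc] <- ssx == 0
    n_used[cc] <- n
  }
  for (j in which(any_miss_col)) {
    use <- !miss[, j]
    x <- g[use, j]
    y <- labels[use]
    n_used[j] <- length(x)
    yb <- mean(y)
    ssx <- sum((x - mean(x))^2)
    if (ssx == 0 || yb %in% c(0, 1)) {
      z[j] <- 0
      mono[j] <- TRUE
    } else {
      z[j] <- sum(x * (y - yb)) / sqrt(yb * (1 - yb) * ssx)
    }
  }
  list(
    z = z, p = ifelse(mono, 1, 2 * stats::pnorm(-abs(z))),
    n_used = n_used, monomorphic = mono
  )
}
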