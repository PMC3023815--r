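#' Banded genotype correlation structure
#'
#' Pearson correlations between dosage columns within a sliding window,
#' the dependence structure the multivariate-normal null sampler uses.
#' Correlations are computed per chromosome over pairwise-complete
#' samples; the implied matrix is 1 on the diagonal, 0 beyond the band
#' and across chromosomes. Under both binary and quantitative phenotype
#' codings the correlation of per-SNP trend statistics equals the
#' genotype correlation, which is why a single banded structure serves
#' the case/control scan.
#'
#' @param x A [gwas_genotypes()] object.
#' @param window Window width in SNPs: SNP `i` is correlated with the
#'   `window - 1` preceding SNPs (default 100). `window = 1` is the
#'   independence model.
#' @return An object of class `banded_corr`: list with `band` (a
#'   `(window - 1) x n_snps` matrix; `band[d, i]` = r(i - d, i), `NA`
#'   outside the chromosome), `window`, `chrom`, `monomorphic`.
#' @export
band_correlation <- function(x, window = 100) {
  stopifnot(inherits(x, "gwas_genotypes"), ncol(x$dosages) >= 1, window >= 1)
  g <- x$dosages
  m <- ncol(g)
  w <- as.integer(window)
  sds <- apply(g, 2, stats::sd, na.rm = TRUE)
  mono <- is.na(sds) | sds == 0
  band <- matrix(NA_real_, max(w - 1, 0), m)
  chrom <- x$snps$chrom
  if (w > 1 && m > 1) {
    for (d in seq_len(w - 1)) {
      if (d >= m) break
      i <- (d + 1):m
      same <- chrom[i] == chrom[i - d]
      r <- pair_cor(g[, i - d, drop = FALSE], g[, i, drop = FALSE])
      r[!same] <- NA_real_
      r[mono[i] | mono[i - d]] <- 0
      band[d, i] <- r
    }
  }
  structure(
    list(band = band, window = w, chrom = chrom, monomorphic = mono),
    class = "banded_corr"
  )
}

# columnwise Pearson correlation between matched columns of two
# matrices, pairwise-complete
pair_cor <- function(a, b) {
  out <- numeric(ncol(a))
  comp <- !(anyNA(a) || anyNA(b))
  if (comp) {
    n <- nrow(a)
    sa <- colSums(a); sb <- colSums(b)
    num <- colSums(a * b) - sa * sb / n
    den <- sqrt((colSums(a^2) - sa^2 / n) * (colSums(b^2) - sb^2 / n))
    out <- ifelse(den == 0, 0, num / den)
  } else {
    for (j in seq_len(ncol(a))) {
      u <- a[, j]; v <- b[, j]
      use <- !is.na(u) & !is.na(v)
      if (sum(use) < 2 || stats::sd(u[use]) == 0 || stats::sd(v[use]) == 0) {
        out[j] <- 0
      } else {
        out[j] <- stats::cor(u[use], v[use])
      }
    }
  }
  pmin(1, pmax(-1, out))
}

#' Sample the minP null from a banded MVN model
#'
#' Approximates the permutation minP distribution without touching the
#' phenotype: per-SNP Z-scores are drawn from a zero-mean multivariate
#' normal with the banded genotype correlation, each `Z_i` sampled from
#' its normal conditional on the previous `min(window - 1, i - 1)`
#' coordinates (restarting at chromosome boundaries), and each
#' replicate records the minimum two-sided p-value `2 * pnorm(-max|Z|)`.
#'
#' @param corr A [band_correlation()] object.
#' @param n_iter Number of MVN replicates (the reference analysis used
#'   10,000).
#' @param seed Integer seed.
#' @param ridge Conditional variances below `ridge` are raised to it
#'   (duplicated SNPs make the band singular); default `1e-6`.
#' @return A `minp_null` object (subclass `mvn_minp`) of length
#'   `n_iter`, usable with [null_threshold()], [null_corrected_p()] and
#'   [corresponding_alpha()].
#' @export
sample_null_minp <- function(corr, n_iter = 10000, seed = 1L, ridge = 1e-6) {
  stopifnot(inherits(corr, "banded_corr"), n_iter >= 1)
  m <- length(corr$chrom)
  w <- corr$window
  coefs <- mvn_band_coefs(corr, ridge)
  set.seed(seed)
  z <- matrix(0, n_iter, m)
  zmax <- rep(0, n_iter)
  for (i in seq_len(m)) {
    ci <- coefs[[i]]
    eps <- stats::rnorm(n_iter)
    zi <- if (length(ci$idx)) {
      z[, ci$idx, drop = FALSE] %*% ci$beta + ci$sd * eps
    } else {
      eps
    }
    z[, i] <- zi
    zmax <- pmax(zmax, abs(as.numeric(zi)))
  }
  new_minp_null(sort(2 * stats::pnorm(-zmax)),
                B = n_iter, seed = seed, n_snps_tested = m,
                method = "mvn", class = "mvn_minp")
}

# per-SNP conditioning coefficients: regression of Z_i on the previous
# in-window, same-chromosome Z's, from the banded correlation
mvn_band_coefs <- function(corr, ridge) {
  m <- length(corr$chrom)
  w <- corr$window
  band <- corr$band
  nb <- nrow(band)
  # r_mat(i, j): correlations for vectors of pairs i <= j, 0 beyond band
  r_pairs <- function(i, j) {
    d <- j - i
    out <- numeric(length(d))
    out[d == 0] <- 1
    inb <- d >= 1 & d <= nb
    if (any(inb)) {
      v <- band[cbind(d[inb], j[inb])]
      v[is.na(v)] <- 0
      out[inb] <- v
    }
    out
  }
  lapply(seq_len(m), function(i) {
    k <- min(w - 1, i - 1)
    if (k <= 0) return(list(idx = integer(0), beta = NULL, sd = 1))
    idx <- (i - k):(i - 1)
    idx <- idx[corr$chrom[idx] == corr$chrom[i]]
    k <- length(idx)
    if (k == 0) return(list(idx = integer(0), beta = NULL, sd = 1))
    a <- rep(idx, times = k)
    b <- rep(idx, each = k)
    sig <- matrix(r_pairs(pmin(a, b), pmax(a, b)), k, k)
    rho <- r_pairs(idx, rep(i, k))
    beta <- tryCatch(
      solve(sig, rho),
      error = function(e) solve(sig + diag(1e-8, k), rho)
    )
    v <- 1 - sum(beta * rho)
    if (!is.finite(v)) {
      stop("non-positive-definite conditional covariance in MVN band; ",
           "increase ridge or reduce window", call. = FALSE)
    }
    list(idx = idx, beta = beta, sd = sqrt(max(v, ridge)))
  })
}
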