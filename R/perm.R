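#' Permutation minP null distribution
#'
#' The gold standard against which every other correction is gauged.
#' Case/control labels are permuted `B` times; for each permutation the
#' genome-wide trend-test scan is re-run and the minimum p-value over
#' testable SNPs recorded. SNPs monomorphic in the sample are excluded.
#' The case count is invariant under permutation, so the whole run
#' reduces to one batched cross-product per chunk of permutations.
#'
#' @param x A [gwas_genotypes()] object.
#' @param labels Binary phenotype vector; defaults to `x$labels`.
#' @param B Number of permutations (the reference analysis used 10,000).
#' @param seed Integer seed; results are deterministic given it.
#' @param chunk Permutations per batch (memory/speed trade-off).
#' @return An object of class `minp_null` (subclass `perm_minp`):
#'   sorted ascending vector of `B` minimum p-values with attributes
#'   `B`, `seed`, `n_snps_tested`, `method`.
#' @export
permute_minp <- function(x, labels = x$labels, B = 10000, seed = 1L,
                         chunk = 500L) {
  stopifnot(inherits(x, "gwas_genotypes"), B >= 1)
  if (is.null(labels)) stop("dataset has no phenotypes", call. = FALSE)
  labels <- as.numeric(labels)
  ok <- !is.na(labels)
  labels <- labels[ok]
  g <- x$dosages[ok, , drop = FALSE]
  n <- length(labels)

  miss_col <- colSums(is.na(g)) > 0L
  # testable = non-monomorphic among complete columns; columns with
  # missingness handled per permutation below
  keep <- rep(TRUE, ncol(g))
  ssx_full <- colSums(g^2, na.rm = TRUE) -
    colSums(g, na.rm = TRUE)^2 / pmax(colSums(!is.na(g)), 1)
  keep[ssx_full <= 0] <- FALSE
  if (!any(keep)) stop("no testable (polymorphic) SNPs", call. = FALSE)
  g <- g[, keep, drop = FALSE]
  miss_col <- miss_col[keep]

  set.seed(seed)
  minp <- numeric(B)
  ybar <- mean(labels)
  if (ybar <= 0 || ybar >= 1) stop("need both cases and controls", call. = FALSE)

  gc_ <- g[, !miss_col, drop = FALSE]
  ssx <- colSums(gc_^2) - colSums(gc_)^2 / n
  den <- sqrt(ybar * (1 - ybar) * ssx)
  gm <- g[, miss_col, drop = FALSE]

  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    perm <- matrix(0, n, b)
    for (k in seq_len(b)) perm[, k] <- labels[sample.int(n)]
    permc <- perm - ybar
    zmax <- rep(0, b)
    if (ncol(gc_)) {
      zmat <- crossprod(gc_, permc) / den # SNPs x b
      zmax <- apply(abs(zmat), 2, max)
    }
    if (ncol(gm)) {
      for (k in seq_len(b)) {
        st <- scan_stats(gm, perm[, k])
        zmax[k] <- max(zmax[k], abs(st$z[!st$monomorphic]), 0)
      }
    }
    minp[done + seq_len(b)] <- 2 * stats::pnorm(-zmax)
    done <- done + b
  }
  new_minp_null(sort(minp), B = B, seed = seed,
                n_snps_tested = ncol(g), method = "permutation",
                class = "perm_minp")
}

new_minp_null <- function(values, B, seed, n_snps_tested, method,
                          class = character()) {
  structure(
    values,
    B = as.integer(B), seed = as.integer(seed),
    n_snps_tested = as.integer(n_snps_tested), method = method,
    class = c(class, "minp_null")
  )
}

#' @export
print.minp_null <- function(x, ...) {
  cat(sprintf(
    "<minp_null:%s> B = %d over %d SNPs; alpha = 0.05 threshold = %.3g\n",
    attr(x, "method"), attr(x, "B"), attr(x, "n_snps_tested"),
    null_threshold(x, 0.05)
  ))
  invisible(x)
}

#' Study-wide significance threshold from a minP null
#'
#' The empirical alpha-quantile of the minP distribution: the
#' `ceiling(alpha * B)`-th smallest minimum p-value. A per-SNP p-value
#' at or below this threshold is study-wide significant at level
#' `alpha`.
#'
#' @param dist A `minp_null` object ([permute_minp()] or
#'   [sample_null_minp()]).
#' @param alpha Study-wide significance level in (0, 1).
#' @return The per-test threshold.
#' @export
null_threshold <- function(dist, alpha = 0.05) {
  stopifnot(inherits(dist, "minp_null"), alpha > 0, alpha < 1)
  v <- as.numeric(dist)
  v[max(1L, ceiling(alpha * length(v)))]
}

#' Study-wide corrected p-value from a minP null
#'
#' Corrects a per-SNP p-value to the study-wide scale by its percentile
#' in the minP null, with add-one smoothing:
#' `(# {minP <= p} + 1) / (B + 1)`.
#'
#' @param dist A `minp_null` object.
#' @param p Raw p-value(s) in `[0, 1]`; vectorised.
#' @return Corrected p-value(s) in (0, 1].
#' @export
null_corrected_p <- function(dist, p) {
  stopifnot(inherits(dist, "minp_null"), all(p >= 0 & p <= 1))
  v <- as.numeric(dist)
  b <- length(v)
  (findInterval(p, v) + 1) / (b + 1)
}

#' Corresponding study-wide alpha of a candidate threshold
#'
#' The empirical family-wise error a per-test threshold implies: the
#' ECDF of the permutation minP distribution at the threshold. This is
#' the common gauge by which every correction method is judged.
#'
#' @param dist A `minp_null` object.
#' @param threshold Per-test threshold(s) in `[0, 1]`; vectorised.
#' @return Corresponding alpha value(s) in `[0, 1]`.
#' @export
corresponding_alpha <- function(dist, threshold) {
  stopifnot(inherits(dist, "minp_null"), all(threshold >= 0 & threshold <= 1))
  v <- as.numeric(dist)
  findInterval(threshold, v) / length(v)
}

#' Family-wise error rate under independence
#'
#' Probability of at least one Type I error among `n` independent tests
#' each run at level `alpha`: `1 - (1 - alpha)^n`.
#'
#' @param alpha Per-test significance level in `[0, 1]`.
#' @param n Number of independent comparisons (non-negative).
#' @return The study-wide Type I error probability.
#' @export
familywise_error <- function(alpha, n) {
  stopifnot(all(alpha >= 0 & alpha <= 1), all(n >= 0))
  1 - (1 - alpha)^n
}

#' Bonferroni per-test threshold
#'
#' `alpha / n_tests`, where `n_tests` may be the raw SNP count, an
#' effective number of tests, or an LD-block count.
#'
#' @param alpha Study-wide significance level.
#' @param n_tests Number of (effective) tests, at least 1.
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(all(n_tests >= 1))
  alpha / n_tests
}

#' Sidak per-test threshold
#'
#' `1 - (1 - alpha)^(1/n)`: exact under independence, the closed-form
#' limit the permutation threshold approaches when SNPs are
#' uncorrelated.
#'
#' @inheritParams bonferroni_threshold
#' @param n Number of independent tests.
#' @return The per-test threshold.
#' @export
sidak_threshold <- function(alpha, n) {
  stopifnot(all(n >= 1))
  1 - (1 - alpha)^(1 / n)
}
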