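# grid-search oracle: maximise the genotype-table likelihood over p_AB
# at the EM solution's allele frequencies
grid_loglik_max <- function(counts, npts = 4001) {
  n9 <- matrix(as.numeric(t(counts)), 1, 9)
  ntot <- sum(counts)
  pa <- sum(n9 * c(0, 0, 0, 1, 1, 1, 2, 2, 2)) / (2 * ntot)
  pb <- sum(n9 * c(0, 1, 2, 0, 1, 2, 0, 1, 2)) / (2 * ntot)
  lo <- max(0, pa + pb - 1)
  hi <- min(pa, pb)
  p11 <- seq(lo, hi, length.out = npts)
  ll <- vapply(p11, function(t) {
    gwasthresh:::geno_table_loglik(
      n9, 1 - pa - pb + t, pb - t, pa - t, t
    )
  }, 0)
  max(ll)
}

test_that("phase-unambiguous tables are solved exactly without iteration", {
  # no double heterozygotes: haplotypes countable by hand
  counts <- matrix(c(
    10, 2, 0,
    3, 0, 1,
    0, 2, 5
  ), 3, 3, byrow = TRUE)
  fit <- em_haplotype_freqs(counts)
  n9 <- as.numeric(t(counts))
  two_n <- 2 * sum(counts)
  k11 <- (2 * counts[3, 3] + counts[3, 2] + counts[2, 3]) / two_n
  k10 <- (2 * counts[3, 1] + counts[3, 2] + counts[2, 1]) / two_n
  k01 <- (2 * counts[1, 3] + counts[2, 3] + counts[1, 2]) / two_n
  k00 <- (2 * counts[1, 1] + counts[1, 2] + counts[2, 1]) / two_n
  expect_equal(unname(fit$freqs["p_AB"]), k11, tolerance = 1e-9)
  expect_equal(unname(fit$freqs["p_Ab"]), k10, tolerance = 1e-9)
  expect_equal(unname(fit$freqs["p_aB"]), k01, tolerance = 1e-9)
  expect_equal(unname(fit$freqs["p_ab"]), k00, tolerance = 1e-9)
  expect_true(fit$converged)
})

test_that("EM attains the grid-search likelihood maximum", {
  tables <- list(
    matrix(c(10, 2, 0, 3, 8, 1, 0, 2, 5), 3, 3, byrow = TRUE),
    matrix(c(30, 5, 1, 6, 12, 2, 0, 3, 9), 3, 3, byrow = TRUE),
    matrix(c(0, 0, 0, 0, 20, 0, 0, 0, 0), 3, 3, byrow = TRUE), # all double het
    matrix(c(5, 0, 4, 0, 6, 0, 4, 0, 5), 3, 3, byrow = TRUE)
  )
  for (tab in tables) {
    fit <- em_haplotype_freqs(tab)
    expect_gte(fit$loglik, grid_loglik_max(tab) - 1e-6)
    expect_equal(sum(fit$freqs), 1, tolerance = 1e-9)
  }
})

test_that("EM recovers generating haplotype frequencies at large N", {
  truth <- list(
    c(0.4, 0.1, 0.1, 0.4),
    c(0.25, 0.25, 0.25, 0.25),
    c(0.7, 0.1, 0.15, 0.05)
  )
  for (k in seq_along(truth)) {
    tr <- truth[[k]]
    tab <- sample_pair_counts(tr[1], tr[2], tr[3], tr[4], 10000, seed = k)
    fit <- em_haplotype_freqs(tab)
    est <- unname(fit$freqs[c("p_ab", "p_aB", "p_Ab", "p_AB")])
    expect_lt(max(abs(est - tr)), 0.02)
  }
})

test_that("EM iterations never decrease the observed-data likelihood", {
  set.seed(8)
  for (k in 1:10) {
    tab <- matrix(rpois(9, 6), 3, 3)
    if (sum(tab) == 0) next
    n9 <- matrix(as.numeric(t(tab)), 1, 9)
    # re-run EM step by step, tracking the likelihood
    prev <- -Inf
    for (it in 1:50) {
      fit <- gwasthresh:::em_freqs_vec(n9, tol = 0, max_iter = it)
      expect_gte(fit$loglik, prev - 1e-9)
      prev <- fit$loglik
    }
  }
})

test_that("LD statistics match hand-expanded formulas", {
  st <- ld_stats(c(0.5, 0, 0, 0.5))
  expect_equal(st$d_prime, 1)
  expect_equal(st$r2, 1)
  # independence
  st0 <- ld_stats(c(0.42, 0.28, 0.18, 0.12)) # pA = 0.3, pB = 0.4, D = 0
  expect_equal(st0$d, 0)
  expect_equal(st0$d_prime, 0)
  expect_equal(st0$r2, 0)
  # (p_ab, p_aB, p_Ab, p_AB) = (0.4, 0.1, 0.1, 0.4)
  st1 <- ld_stats(c(0.4, 0.1, 0.1, 0.4))
  pa <- 0.5; pb <- 0.5
  d <- 0.4 - pa * pb
  expect_equal(st1$d, d)
  expect_equal(st1$d_prime, d / min(pa * (1 - pb), (1 - pa) * pb))
  expect_equal(st1$r2, d^2 / (pa * (1 - pa) * pb * (1 - pb)))
  expect_error(ld_stats(c(0.5, 0.5, 0, 0)), "monomorphic")
})

test_that("r2 never exceeds D-prime on random tables", {
  set.seed(5)
  for (k in 1:50) {
    tab <- matrix(rpois(9, 5), 3, 3)
    n9 <- matrix(as.numeric(t(tab)), 1, 9)
    ntot <- sum(tab)
    if (ntot == 0) next
    pa <- sum(n9 * c(0, 0, 0, 1, 1, 1, 2, 2, 2)) / (2 * ntot)
    pb <- sum(n9 * c(0, 1, 2, 0, 1, 2, 0, 1, 2)) / (2 * ntot)
    if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) next
    fit <- em_haplotype_freqs(tab)
    st <- ld_stats(fit$freqs)
    expect_lte(st$r2, st$d_prime + 1e-9)
  }
})

test_that("D-prime CI narrows onto 1 without recombinant gametes", {
  lo_prev <- -1
  for (n in c(10, 50, 400)) {
    tab <- sample_pair_counts(0.5, 0, 0, 0.5, n, seed = n)
    ci <- dprime_ci(tab)
    expect_equal(ci$ci_high, 1)
    expect_gte(ci$ci_low, lo_prev) # interval tightens with information
    lo_prev <- ci$ci_low
  }
  expect_gte(dprime_ci(sample_pair_counts(0.5, 0, 0, 0.5, 400, 1))$ci_low,
             0.98)
})

test_that("tiny samples give wide D-prime CIs", {
  tab <- sample_pair_counts(0.3, 0.2, 0.2, 0.3, 4, seed = 2)
  ci <- dprime_ci(tab)
  expect_lt(ci$ci_low, 0.3)
  expect_gt(ci$ci_high - ci$ci_low, 0.5)
})

test_that("the CI grid mass normalises to one", {
  set.seed(17)
  for (k in 1:10) {
    tab <- matrix(rpois(9, 4) + 1, 3, 3)
    n9 <- matrix(as.numeric(t(tab)), 1, 9)
    fit <- gwasthresh:::em_freqs_vec(n9)
    d_hat <- fit$p11 - (fit$p11 + fit$p10) * (fit$p11 + fit$p01)
    ci <- gwasthresh:::dprime_ci_vec(n9, sign(d_hat))
    expect_equal(rowSums(ci$mass), 1, tolerance = 1e-12)
  }
})
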