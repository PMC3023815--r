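test_that("composite correlation handles edge cases", {
  d <- make_dataset(matrix(c(0, 1, 2, 0, 1, 2), 3, 2))
  expect_equal(unname(composite_correlation(d, 1)), matrix(1, 1, 1))
  r <- composite_correlation(d)
  expect_equal(unname(r[1, 2]), 1) # duplicated columns
  dm <- make_dataset(cbind(c(1, 1, 1, 1), c(0, 1, 2, 0)))
  rm_ <- composite_correlation(dm)
  expect_equal(unname(rm_[1, 2]), 0) # monomorphic column: zero off-diagonal
  expect_equal(unname(diag(rm_)), c(1, 1))
})

test_that("independent columns give small off-diagonal correlation", {
  d <- random_dataset(10000, 20, seed = 13, labels = FALSE)
  r <- composite_correlation(d)
  off <- abs(r[upper.tri(r)])
  expect_lt(max(off), 4.5 / sqrt(10000))
})

test_that("eigenvalue truncation rule reproduces analytic cases", {
  expect_equal(meff_from_eigenvalues(rep(1, 200)), 199L)
  expect_equal(meff_from_eigenvalues(c(7, 0, 0, 0)), 1L)
  # 100 duplicated pairs: eigenvalues are one hundred 2s and one
  # hundred 0s; at m = 100 the top sum is 200 >= 199, at 99 it is 198
  expect_equal(meff_from_eigenvalues(rep(c(2, 0), each = 100)), 100L)
  expect_error(meff_from_eigenvalues(numeric(0)))
  expect_error(meff_from_eigenvalues(c(0, 0)), "zero")
  expect_error(meff_from_eigenvalues(c(1, -0.1)), "negative")
})

test_that("region chooser closes at block boundaries and never splits blocks", {
  # all singletons: arithmetic split
  d <- random_dataset(10, 120, seed = 2, labels = FALSE)
  d$snps$chrom <- rep("1", 120) # one chromosome for this check
  d <- gwas_genotypes(d$dosages, d$snps, labels = NULL)
  empty <- gwasthresh:::new_ld_partition(
    tibble::tibble(chrom = character(), start_index = integer(),
                   end_index = integer()),
    n_snps = 120, algorithm = "none", params = list()
  )
  reg <- choose_regions(d, empty, target_size = 50)
  expect_equal(reg$n_snps, c(50L, 50L, 20L))
  # one block larger than the target is kept whole
  big <- gwasthresh:::new_ld_partition(
    tibble::tibble(chrom = "1", start_index = 10L, end_index = 70L),
    n_snps = 120, algorithm = "none", params = list()
  )
  reg2 <- choose_regions(d, big, target_size = 50)
  expect_true(any(reg2$start_index <= 10 & reg2$end_index >= 70))
  # random partitions: concatenated regions reproduce the SNP order
  set.seed(77)
  for (k in 1:5) {
    cuts <- sort(sample(2:119, 8))
    blocks <- tibble::tibble(
      chrom = "1",
      start_index = c(1L, cuts[c(2, 4, 6)]),
      end_index = c(cuts[1], cuts[c(3, 5, 7)])
    )
    part <- gwasthresh:::new_ld_partition(blocks, 120, "rand", list())
    reg <- choose_regions(d, part, target_size = sample(10:60, 1))
    idx <- unlist(purrr::map2(reg$start_index, reg$end_index, seq))
    expect_equal(as.integer(idx), 1:120)
  }
})

test_that("simpleM total tracks the independence and duplication limits", {
  p <- independent_panel(300, seed = 101)
  g <- simulate_genotypes(p, 2000, seed = 102)
  me <- simplem_meff(g, choose_regions(g, panel_partition(p), 100))
  expect_gte(me$total, 0.95 * 300)
  expect_lte(me$total, 300)
  # duplicate every SNP: M_eff stays close to the original count
  g2 <- g
  dup <- cbind(g$dosages, g$dosages)
  snps2 <- dplyr::bind_rows(
    g$snps,
    dplyr::mutate(g$snps, id = paste0(.data$id, "_dup"),
                  pos = .data$pos + 1L)
  )
  gd <- gwas_genotypes(dup, snps2)
  med <- simplem_meff(gd) # single whole-chromosome region
  expect_lt(med$total, 1.1 * 300)
  expect_gte(med$total, 0.9 * 300)
})

test_that("M_eff never exceeds the SNP count and respects Bonferroni ordering", {
  p <- blocky_panel(30, seed = 111)
  g <- simulate_genotypes(p, 500, seed = 112)
  me <- simplem_meff(g, choose_regions(g, panel_partition(p), 50))
  expect_lte(me$total, ncol(g$dosages))
  expect_true(all(me$per_region$m_eff >= 1))
  expect_true(all(me$per_region$m_eff <= me$per_region$n_snps))
  expect_gte(
    bonferroni_threshold(0.05, me$total),
    bonferroni_threshold(0.05, ncol(g$dosages))
  )
})

test_that("splitting a region at a zero-LD boundary barely moves the total", {
  p <- blocky_panel(150, seed = 121)
  g <- simulate_genotypes(p, 2000, seed = 122)
  whole <- tibble::tibble(chrom = "1", start_index = 1L, end_index = 750L,
                          n_snps = 750L)
  halves <- tibble::tibble(chrom = "1", start_index = c(1L, 376L),
                           end_index = c(375L, 750L), n_snps = 375L)
  m1 <- simplem_meff(g, whole)
  m2 <- simplem_meff(g, halves)
  expect_lte(abs(m1$total - m2$total) / m1$total, 0.01)
})
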