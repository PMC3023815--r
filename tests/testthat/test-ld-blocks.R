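partition_is_valid <- function(part) {
  blk <- part$blocks
  ok <- TRUE
  if (nrow(blk) > 1) {
    ok <- ok && all(diff(blk$start_index) > 0) &&
      all(blk$start_index[-1] > blk$end_index[-nrow(blk)])
  }
  ok && all(blk$n_snps >= 2) && all(blk$end_index <= part$n_snps)
}

test_that("block and singleton counting follows the partition", {
  mk <- function(starts, ends, m) {
    gwasthresh:::new_ld_partition(
      tibble::tibble(chrom = "1", start_index = starts, end_index = ends),
      n_snps = m, algorithm = "manual", params = list()
    )
  }
  expect_equal(block_test_count(mk(integer(0), integer(0), 8)), 8L)
  expect_equal(block_test_count(mk(1L, 12L, 12)), 1L)
  # 10 blocks of 5 + 7 singletons
  starts <- seq(1L, by = 5L, length.out = 10)
  p <- mk(starts, starts + 4L, 57)
  expect_equal(block_test_count(p), 17L)
})

test_that("all three algorithms recover the panel's ground-truth blocks", {
  # common haplotypes (MAF floor 0.2): rare haplotypes sit below the
  # detection sensitivity of the four-gamete cutoff by design
  p <- simulate_panel(12, block_sizes = 5, pool_size = 2, maf_min = 0.2,
                      seed = 131)
  g <- simulate_genotypes(p, 2000, seed = 132)
  truth <- panel_partition(p)$blocks
  pr <- ld_pairs(g, window = 30)
  for (part in list(
    gabriel_blocks(g, pairs = pr),
    solid_spine_blocks(g, pairs = pr),
    four_gamete_blocks(g, pairs = pr)
  )) {
    expect_true(partition_is_valid(part))
    # every true 5-SNP block recovered exactly (2-haplotype pools give
    # |D'| = 1 within blocks and free recombination between them)
    expect_equal(part$blocks$start_index, truth$start_index)
    expect_equal(part$blocks$end_index, truth$end_index)
  }
})

test_that("independent common SNPs yield all-singleton partitions", {
  p <- independent_panel(60, seed = 141)
  g <- simulate_genotypes(p, 1500, seed = 142)
  pr <- ld_pairs(g, window = 30)
  expect_equal(nrow(gabriel_blocks(g, pairs = pr)$blocks), 0L)
  expect_equal(nrow(four_gamete_blocks(g, pairs = pr)$blocks), 0L)
  expect_equal(nrow(solid_spine_blocks(g, pairs = pr)$blocks), 0L)
})

test_that("a planted recombinant haplotype splits the four-gamete block", {
  # two 3-SNP halves in complete LD, joined by 5% recombinant
  # haplotypes so that all four gametes segregate across the join
  hap <- rbind(
    c(1, 1, 1, 0, 0, 0),
    c(0, 0, 0, 1, 1, 1),
    c(1, 1, 1, 1, 1, 1),
    c(0, 0, 0, 0, 0, 0)
  )
  panel <- structure(
    list(
      blocks = list(list(haplotypes = hap,
                         weights = c(0.45, 0.45, 0.05, 0.05),
                         size = 6L)),
      n_snps = 6L, pool_size = 4L, maf_min = 0, seed = 1L
    ),
    class = "haplotype_panel"
  )
  g <- simulate_genotypes(panel, 3000, seed = 7)
  part <- four_gamete_blocks(g, window = 10)
  # fourth gamete crosses the halves at ~5%: the pair (3, 4) shows
  # recombination, so the block must split between SNPs 3 and 4
  expect_true(all(part$blocks$end_index[part$blocks$start_index <= 3] <= 3))
  expect_equal(nrow(part$blocks), 2L)
})

test_that("tightening Gabriel CI bounds never enlarges the strong-LD pair set", {
  p <- blocky_panel(20, seed = 151)
  g <- simulate_genotypes(p, 800, seed = 152)
  pr <- ld_pairs(g, window = 25)
  strong_070 <- pr$ci_low >= 0.70 & pr$ci_high >= 0.98
  strong_085 <- pr$ci_low >= 0.85 & pr$ci_high >= 0.98
  expect_true(all(which(strong_085) %in% which(strong_070)))
  # both parameterisations produce valid partitions
  expect_true(partition_is_valid(gabriel_blocks(g, pairs = pr)))
  expect_true(partition_is_valid(
    gabriel_blocks(g, ci_lower_min = 0.85, pairs = pr)
  ))
})

test_that("perfectly duplicated SNPs form a solid spine at D' = 1", {
  set.seed(6)
  col <- rbinom(400, 2, 0.4)
  g <- make_dataset(cbind(col, col, col))
  part <- solid_spine_blocks(g, dprime_min = 1.0, window = 5)
  expect_equal(nrow(part$blocks), 1L)
  expect_equal(part$blocks$start_index, 1L)
  expect_equal(part$blocks$end_index, 3L)
})

test_that("spine variants stay structurally valid at stricter D'", {
  p <- blocky_panel(15, seed = 161)
  g <- simulate_genotypes(p, 600, seed = 162)
  pr <- ld_pairs(g, window = 20)
  for (dmin in c(0.8, 0.95)) {
    part <- solid_spine_blocks(g, dprime_min = dmin, pairs = pr)
    expect_true(partition_is_valid(part))
  }
})

test_that("lowering the four-gamete cutoff enlarges the recombination set", {
  p <- blocky_panel(15, seed = 171)
  g <- simulate_genotypes(p, 600, seed = 172)
  pr <- ld_pairs(g, window = 20)
  n_recomb <- function(cut) sum(pr$min_hap_freq >= cut)
  expect_gte(n_recomb(0.005), n_recomb(0.01))
  expect_true(partition_is_valid(
    four_gamete_blocks(g, fourth_freq_cutoff = 0.005, pairs = pr)
  ))
})

test_that("chunked analysis with block carry-over equals the single pass", {
  p <- blocky_panel(40, block_sizes = c(2, 5, 8), seed = 181)
  g <- simulate_genotypes(p, 800, seed = 182)
  for (method in c("spine", "fourgamete")) {
    single <- switch(method,
      spine = solid_spine_blocks(g, window = 20),
      fourgamete = four_gamete_blocks(g, window = 20)
    )
    chunked <- chunked_blocks(g, method, chunk_size = 60, window = 20)
    expect_equal(chunked$blocks$start_index, single$blocks$start_index)
    expect_equal(chunked$blocks$end_index, single$blocks$end_index)
  }
})
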