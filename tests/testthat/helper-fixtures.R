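# Fixture builders shared across the suite. Everything is generated in
# code at test time; no binary fixtures.

# small hand-specifiable dataset from a dosage matrix
make_dataset <- function(dos, chrom = "1", labels = NULL) {
  dos <- as.matrix(dos)
  m <- ncol(dos)
  snps <- tibble::tibble(
    id = paste0("snp", seq_len(m)),
    chrom = rep(chrom, length.out = m),
    pos = 1000L * seq_len(m),
    allele_a = "A", allele_b = "G"
  )
  gwas_genotypes(dos, snps, labels = labels)
}

# random dataset with optional missingness, for round-trip properties
random_dataset <- function(n, m, miss = 0, seed = 1, labels = TRUE) {
  set.seed(seed)
  dos <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (miss > 0) dos[runif(n * m) < miss] <- NA
  snps <- tibble::tibble(
    id = paste0("rs", seq_len(m)),
    chrom = as.character(rep(1:2, length.out = m)),
    pos = rep(1000L * seq_len(ceiling(m / 2)), each = 2, length.out = m),
    allele_a = sample(c("A", "C"), m, replace = TRUE),
    allele_b = sample(c("G", "T"), m, replace = TRUE)
  )
  lab <- if (labels) sample(0:1, n, replace = TRUE) else NULL
  gwas_genotypes(dos, snps, labels = lab)
}

expect_equal_dataset <- function(a, b) {
  expect_equal(unname(a$dosages), unname(b$dosages))
  expect_equal(a$snps$id, b$snps$id)
  expect_equal(a$snps$chrom, b$snps$chrom)
  expect_equal(a$snps$pos, b$snps$pos)
  expect_equal(a$labels, b$labels)
}

# 3x3 joint dosage table from known haplotype frequencies (random
# mating), for EM simulation oracles
sample_pair_counts <- function(p00, p01, p10, p11, n, seed = 1) {
  set.seed(seed)
  haps <- sample(1:4, 2 * n, replace = TRUE, prob = c(p00, p01, p10, p11))
  a_allele <- c(0, 0, 1, 1)[haps]
  b_allele <- c(0, 1, 0, 1)[haps]
  a <- a_allele[seq_len(n)] + a_allele[n + seq_len(n)]
  b <- b_allele[seq_len(n)] + b_allele[n + seq_len(n)]
  tab <- matrix(0, 3, 3)
  for (i in seq_len(n)) tab[a[i] + 1, b[i] + 1] <- tab[a[i] + 1, b[i] + 1] + 1
  tab
}

# independent-SNP panel (blocks of one SNP); common alleles so every
# pairwise LD statistic is well estimated
independent_panel <- function(n_snps, seed, maf_min = 0.2) {
  simulate_panel(n_snps, block_sizes = 1, pool_size = 4,
                 maf_min = maf_min, seed = seed)
}

# blocky panel mirroring the study structure at reduced scale
blocky_panel <- function(n_blocks, block_sizes = 5, pool_size = 2:4,
                         seed = 1) {
  simulate_panel(n_blocks, block_sizes = block_sizes,
                 pool_size = pool_size, seed = seed)
}
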