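#' Simulate a block-structured haplotype panel
#'
#' Builds the population LD structure the genotype simulator draws from:
#' an ordered set of LD blocks, each carrying a small pool of haplotypes
#' (binary allele vectors over the block's SNPs) with Dirichlet-sampled
#' frequencies. Each pool is generated on a random perfect phylogeny —
#' every SNP mutates exactly once on a random binary tree over the `K`
#' haplotypes — so no within-block pair ever shows all four gametes:
#' within a block the population |D'| is 1 for every polymorphic pair,
#' which is what makes the pool a haplotype block rather than an
#' arbitrary set of sequences. Blocks are resampled until every SNP's
#' implied minor allele frequency reaches `maf_min`. Blocks are
#' independent (free recombination between blocks), giving every LD
#' block algorithm a known ground-truth partition.
#'
#' @param n_blocks Number of LD blocks.
#' @param block_sizes Integer vector of block sizes to sample from
#'   (uniformly, with replacement), or a single size used for all blocks.
#'   Size 1 blocks are singleton SNPs.
#' @param pool_size Number of distinct haplotypes per block (`K`), or a
#'   vector of sizes to sample from per block (e.g. `2:4`). Larger
#'   pools give weaker within-block LD.
#' @param maf_min Minimum implied minor allele frequency per SNP
#'   (default 0.01).
#' @param seed Integer seed; the panel is deterministic given it.
#' @return An object of class `haplotype_panel`: list of `blocks`, each
#'   with `haplotypes` (K x size 0/1 matrix), `weights` (sums to 1) and
#'   `size`; plus `n_snps` and the generating parameters.
#' @export
simulate_panel <- function(n_blocks, block_sizes = 5, pool_size = 4,
                           maf_min = 0.01, seed = 1L) {
  stopifnot(n_blocks >= 1, all(pool_size >= 1), all(block_sizes >= 1))
  if (any(pool_size == 1) && maf_min > 0) {
    stop("pool_size = 1 gives monomorphic blocks; cannot satisfy maf_min > 0",
         call. = FALSE)
  }
  if (any(pool_size == 2) && maf_min > 0.5) {
    stop("infeasible maf_min for pool_size = 2", call. = FALSE)
  }
  set.seed(seed)
  sizes <- if (length(block_sizes) == 1) {
    rep(as.integer(block_sizes), n_blocks)
  } else {
    sample(as.integer(block_sizes), n_blocks, replace = TRUE)
  }
  ks <- if (length(pool_size) == 1) {
    rep(as.integer(pool_size), n_blocks)
  } else {
    sample(as.integer(pool_size), n_blocks, replace = TRUE)
  }
  blocks <- Map(function(L, k) {
    repeat {
      hap <- phylogeny_haplotypes(k, L)
      w <- as.numeric(stats::rgamma(k, shape = 1))
      w <- w / sum(w)
      f <- as.numeric(w %*% hap)
      if (all(pmin(f, 1 - f) >= maf_min)) {
        return(list(haplotypes = hap, weights = w, size = L))
      }
    }
  }, sizes, ks)
  structure(
    list(
      blocks = blocks, n_snps = sum(sizes),
      pool_size = pool_size, maf_min = maf_min, seed = seed
    ),
    class = "haplotype_panel"
  )
}

# K haplotypes of L SNPs on a random perfect phylogeny: recursive random
# bipartitions of the haplotype set define the tree's clades; each SNP is
# assigned to one clade (its unique mutation) with a random ancestral
# allele. Guarantees at most 3 gametes for every SNP pair.
phylogeny_haplotypes <- function(k, L) {
  clades <- list()
  rec <- function(S) {
    if (length(S) <= 1) return(invisible())
    repeat {
      pick <- stats::runif(length(S)) < 0.5
      if (any(pick) && !all(pick)) break
    }
    A <- S[pick]
    B <- S[!pick]
    clades[[length(clades) + 1]] <<- A
    clades[[length(clades) + 1]] <<- B
    rec(A)
    rec(B)
  }
  rec(seq_len(k))
  hap <- matrix(0L, k, L)
  if (length(clades) == 0) return(hap) # k = 1: monomorphic pool
  edge <- sample.int(length(clades), L, replace = TRUE)
  flip <- stats::runif(L) < 0.5
  for (s in seq_len(L)) {
    hap[clades[[edge[s]]], s] <- 1L
    if (flip[s]) hap[, s] <- 1L - hap[, s]
  }
  hap
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "<haplotype_panel> %d blocks, %d SNPs, pool size %d\n",
    length(x$blocks), x$n_snps, x$pool_size
  ))
  invisible(x)
}

#' True block partition of a panel
#'
#' The ground-truth LD block partition implied by the panel's
#' construction, in the same form the block-detection algorithms return.
#' Blocks of size 1 are singletons.
#'
#' @param panel A [simulate_panel()] object.
#' @return An `ld_partition` object (see [gabriel_blocks()]).
#' @export
panel_partition <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  sizes <- vapply(panel$blocks, `[[`, 1L, "size")
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  multi <- sizes >= 2L
  new_ld_partition(
    tibble::tibble(
      chrom = "1", start_index = starts[multi], end_index = ends[multi]
    ),
    n_snps = sum(sizes), algorithm = "ground_truth", params = list()
  )
}

#' Simulate unphased genotypes from a haplotype panel
#'
#' Each sample receives two independent haplotype draws per block
#' (weights as probabilities); the dosage is their sum. Blocks are
#' drawn independently, so between-block LD is zero in the population.
#' All SNPs are placed on one chromosome at 1 kb spacing; no
#' missingness is introduced.
#'
#' @param panel A [simulate_panel()] object.
#' @param n_samples Number of diploid samples.
#' @param seed Integer seed.
#' @return A [gwas_genotypes()] object without phenotypes. SNP ids are
#'   `b<block>_s<snp>` so block membership is recoverable by eye.
#' @export
simulate_genotypes <- function(panel, n_samples, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"), n_samples >= 1)
  set.seed(seed)
  cols <- vector("list", length(panel$blocks))
  ids <- vector("list", length(panel$blocks))
  for (b in seq_along(panel$blocks)) {
    blk <- panel$blocks[[b]]
    k <- nrow(blk$haplotypes)
    h1 <- sample.int(k, n_samples, replace = TRUE, prob = blk$weights)
    h2 <- sample.int(k, n_samples, replace = TRUE, prob = blk$weights)
    cols[[b]] <- blk$haplotypes[h1, , drop = FALSE] +
      blk$haplotypes[h2, , drop = FALSE]
    ids[[b]] <- sprintf("b%04d_s%02d", b, seq_len(blk$size))
  }
  dos <- do.call(cbind, cols)
  ids <- unlist(ids)
  snps <- tibble::tibble(
    id = ids, chrom = "1", pos = 1000L * seq_along(ids),
    allele_a = "A", allele_b = "B"
  )
  gwas_genotypes(dos, snps)
}

#' Assign case/control phenotypes
#'
#' Independent Bernoulli labels per sample. Under the null model every
#' sample is a case with the same probability, independent of genotype.
#' Under the additive model the case probability is read off the
#' sample's dosage at one causal SNP: `p0`, `p1`, `p2` for dosage
#' 0, 1, 2 (missing dosage falls back to `p0`).
#'
#' @param x A [gwas_genotypes()] object.
#' @param model `"null"` or `"additive"`.
#' @param prob Case probability for the null model (default 0.5).
#' @param causal_snp SNP id (additive model).
#' @param p0,p1,p2 Per-dosage case probabilities (additive model).
#' @param seed Integer seed.
#' @return The dataset with `labels` filled in (1 = case, 0 = control).
#' @export
assign_phenotypes <- function(x, model = c("null", "additive"), prob = 0.5,
                              causal_snp = NULL, p0 = 0.5, p1 = 0.5, p2 = 0.5,
                              seed = 1L) {
  stopifnot(inherits(x, "gwas_genotypes"))
  model <- match.arg(model)
  set.seed(seed)
  n <- nrow(x$dosages)
  if (model == "null") {
    stopifnot(prob >= 0, prob <= 1)
    p <- rep(prob, n)
  } else {
    if (is.null(causal_snp) || !causal_snp %in% x$snps$id) {
      stop("additive model requires a causal_snp present in the dataset",
           call. = FALSE)
    }
    stopifnot(all(c(p0, p1, p2) >= 0), all(c(p0, p1, p2) <= 1))
    g <- x$dosages[, match(causal_snp, x$snps$id)]
    p <- c(p0, p1, p2)[ifelse(is.na(g), 0, g) + 1]
  }
  x$labels <- as.integer(stats::runif(n) < p)
  x
}
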