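#' Compare multiple-testing correction methods on one dataset
#'
#' Runs the configured corrections on a single case/control dataset and
#' gauges every candidate threshold against one shared permutation minP
#' distribution: each method's row reports its per-test significance
#' threshold at level `alpha` and the corresponding study-wide alpha
#' (the permutation ECDF at that threshold). A method whose
#' corresponding alpha exceeds `alpha` is anti-conservative.
#'
#' @param x A [gwas_genotypes()] object with phenotypes (or pass
#'   `labels`).
#' @param labels Binary phenotype vector; defaults to `x$labels`.
#' @param alpha Study-wide significance level(s); default `0.05`.
#' @param methods Character subset of `"bonferroni"`, `"permutation"`,
#'   `"simplem"`, `"mvn"`, `"gabriel"`, `"spine"`, `"fourgamete"`.
#' @param B Permutations for the minP null (default 2000).
#' @param n_iter MVN replicates (default `B`).
#' @param window MVN band width in SNPs (default 100).
#' @param ld_window Pairwise LD window in SNPs (default 250).
#' @param target_region_size simpleM region size target (default 5000).
#' @param C simpleM variance fraction (default 0.995).
#' @param seed Integer seed governing the permutation and MVN draws.
#' @param minp Optional precomputed [permute_minp()] result to reuse as
#'   the gauge (must come from the same data and labels).
#' @return A `threshold_comparison`: a tibble with columns `method`,
#'   `alpha`, `n_tests`, `threshold`, `corresponding_alpha`, sorted by
#'   threshold within each alpha, carrying the minP null and run
#'   metadata as attributes.
#' @export
compare_methods <- function(x, labels = x$labels, alpha = 0.05,
                            methods = c("bonferroni", "permutation",
                                        "simplem", "mvn", "gabriel",
                                        "spine", "fourgamete"),
                            B = 2000, n_iter = B, window = 100,
                            ld_window = 250, target_region_size = 5000,
                            C = 0.995, seed = 1L, minp = NULL) {
  stopifnot(inherits(x, "gwas_genotypes"))
  if (is.null(labels)) stop("dataset has no phenotypes", call. = FALSE)
  methods <- match.arg(methods, several.ok = TRUE)
  m <- ncol(x$dosages)

  if (is.null(minp)) {
    minp <- permute_minp(x, labels, B = B, seed = seed)
  }
  need_pairs <- any(c("gabriel", "spine", "fourgamete", "simplem") %in% methods)
  pairs <- if (need_pairs) ld_pairs(x, window = ld_window) else NULL

  rows <- list()
  add <- function(method, n_tests, threshold) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      method = method, alpha = alpha,
      n_tests = as.integer(rep(n_tests, length(alpha))),
      threshold = threshold
    )
  }
  for (meth in methods) {
    res <- tryCatch({
      switch(meth,
        bonferroni = add("bonferroni", m, bonferroni_threshold(alpha, m)),
        permutation = add("permutation", attr(minp, "n_snps_tested"),
                          vapply(alpha, function(a) null_threshold(minp, a), 0)),
        simplem = {
          spine <- solid_spine_blocks(x, window = ld_window, pairs = pairs)
          regions <- choose_regions(x, spine, target_size = target_region_size)
          meff <- simplem_meff(x, regions, C = C)
          add("simplem", meff$total, bonferroni_threshold(alpha, meff$total))
        },
        mvn = {
          corr <- band_correlation(x, window = window)
          samp <- sample_null_minp(corr, n_iter = n_iter, seed = seed + 1L)
          add("mvn", m, vapply(alpha, function(a) null_threshold(samp, a), 0))
        },
        gabriel = {
          p <- gabriel_blocks(x, window = ld_window, pairs = pairs)
          add("gabriel", block_test_count(p),
              bonferroni_threshold(alpha, block_test_count(p)))
        },
        spine = {
          p <- solid_spine_blocks(x, window = ld_window, pairs = pairs)
          add("spine", block_test_count(p),
              bonferroni_threshold(alpha, block_test_count(p)))
        },
        fourgamete = {
          p <- four_gamete_blocks(x, window = ld_window, pairs = pairs)
          add("fourgamete", block_test_count(p),
              bonferroni_threshold(alpha, block_test_count(p)))
        }
      )
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      warning(sprintf("method %s failed: %s", meth, res), call. = FALSE)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$corresponding_alpha <- corresponding_alpha(minp, out$threshold)
  out <- dplyr::arrange(out, .data$alpha, .data$threshold)
  structure(out,
    minp = minp, seed = seed, B = attr(minp, "B"), n_iter = n_iter,
    n_snps = m, n_samples = nrow(x$dosages),
    class = c("threshold_comparison", class(out))
  )
}

#' Threshold sensitivity to sample size
#'
#' Re-runs [compare_methods()] on a random case subset (all controls
#' kept) and reports the signed change in each method's threshold,
#' `delta = threshold_subset - threshold_full`. Methods whose
#' thresholds track the LD structure rather than the realised test
#' statistics (the MVN and eigenvalue corrections) should move far
#' less than the permutation threshold.
#'
#' @param x A [gwas_genotypes()] object with phenotypes.
#' @param labels Binary phenotype vector; defaults to `x$labels`.
#' @param n_cases Number of cases to retain (drawn uniformly without
#'   replacement).
#' @param seed Integer seed for the subset draw (also seeds both
#'   comparison runs).
#' @param full Optional precomputed full-data `threshold_comparison`
#'   with matching parameters, to avoid recomputation across repeated
#'   subset draws.
#' @param ... Passed to [compare_methods()].
#' @return A tibble: `method`, `alpha`, `threshold_full`,
#'   `threshold_subset`, `delta`.
#' @export
subset_delta <- function(x, labels = x$labels, n_cases, seed = 1L,
                         full = NULL, ...) {
  stopifnot(inherits(x, "gwas_genotypes"))
  if (is.null(labels)) stop("dataset has no phenotypes", call. = FALSE)
  case_idx <- which(labels == 1L)
  ctrl_idx <- which(labels == 0L)
  if (n_cases > length(case_idx)) {
    stop(sprintf("requested %d cases but only %d available",
                 n_cases, length(case_idx)), call. = FALSE)
  }
  if (is.null(full)) {
    full <- compare_methods(x, labels, seed = seed, ...)
  }
  set.seed(seed)
  keep <- sort(c(sample(case_idx, n_cases), ctrl_idx))
  xs <- subset_genotypes(x, samples = keep)
  sub <- compare_methods(xs, labels[keep], seed = seed, ...)
  dplyr::transmute(
    dplyr::inner_join(
      dplyr::select(tibble::as_tibble(full), "method", "alpha",
                    threshold_full = "threshold"),
      dplyr::select(tibble::as_tibble(sub), "method", "alpha",
                    threshold_subset = "threshold"),
      by = c("method", "alpha")
    ),
    .data$method, .data$alpha, .data$threshold_full, .data$threshold_subset,
    delta = .data$threshold_subset - .data$threshold_full
  )
}
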