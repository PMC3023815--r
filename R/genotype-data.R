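#' Construct a genotype dataset
#'
#' The universal input container of the package: a samples-by-SNPs dosage
#' matrix together with the SNP map, sample identifiers and (optionally)
#' binary case/control phenotypes. Dosages count copies of each SNP's
#' `allele_b` and take values 0, 1, 2 or `NA` (missing). Columns are kept
#' strictly sorted by (chromosome, position), the order every downstream
#' LD computation relies on.
#'
#' @param dosages Numeric matrix, rows = samples, columns = SNPs; entries
#'   in `{0, 1, 2, NA}`.
#' @param snps Data frame with columns `id`, `chrom`, `pos`, `allele_a`,
#'   `allele_b`; one row per column of `dosages`.
#' @param samples Character vector of sample ids (defaults to rownames of
#'   `dosages`, else `"S1"..."Sn"`).
#' @param labels Optional vector of case/control phenotypes: 1/`"case"` for
#'   cases, 0/`"control"` for controls, `NA` for unknown.
#'
#' @return An object of class `gwas_genotypes`: a list with elements
#'   `dosages`, `snps` (a tibble), `samples` and `labels` (0/1 integer or
#'   `NULL`).
#' @export
gwas_genotypes <- function(dosages, snps, samples = NULL, labels = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  snps <- tibble::as_tibble(snps)
  stopifnot(
    all(c("id", "chrom", "pos", "allele_a", "allele_b") %in% names(snps)),
    nrow(snps) == ncol(dosages)
  )
  if (anyDuplicated(snps$id) > 0) {
    stop("SNP ids must be unique", call. = FALSE)
  }
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    stop("dosage entries must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (any(snps$pos < 0)) stop("positions must be non-negative", call. = FALSE)

  if (is.null(samples)) {
    samples <- rownames(dosages)
    if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosages)))
  }
  stopifnot(length(samples) == nrow(dosages))

  ord <- order(chrom_rank(snps$chrom), snps$pos)
  snps <- snps[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  dimnames(dosages) <- list(samples, snps$id)

  labels <- normalise_labels(labels, nrow(dosages))

  structure(
    list(dosages = dosages, snps = snps, samples = samples, labels = labels),
    class = "gwas_genotypes"
  )
}

#' @export
print.gwas_genotypes <- function(x, ...) {
  n_case <- if (is.null(x$labels)) NA_integer_ else sum(x$labels == 1L, na.rm = TRUE)
  n_ctrl <- if (is.null(x$labels)) NA_integer_ else sum(x$labels == 0L, na.rm = TRUE)
  cat(sprintf(
    "<gwas_genotypes> %d samples x %d SNPs on %d chromosome(s)\n",
    nrow(x$dosages), ncol(x$dosages), length(unique(x$snps$chrom))
  ))
  if (!is.null(x$labels)) {
    cat(sprintf("  phenotypes: %d cases / %d controls\n", n_case, n_ctrl))
  }
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.gwas_genotypes <- function(x) dim(x$dosages)

# Chromosome sort rank: numeric chromosomes first in numeric order, then
# X, Y, MT, then anything else alphabetically.
chrom_rank <- function(chrom) {
  chrom <- as.character(chrom)
  num <- suppressWarnings(as.numeric(chrom))
  special <- match(toupper(chrom), c("X", "Y", "XY", "MT", "M"))
  rank <- ifelse(!is.na(num), num, 100 + ifelse(!is.na(special), special, 50))
  # alphabetical tie-break for non-numeric, non-special names
  rank + ifelse(is.na(num) & is.na(special),
    match(chrom, sort(unique(chrom))) / 1e6, 0
  )
}

normalise_labels <- function(labels, n) {
  if (is.null(labels)) return(NULL)
  stopifnot(length(labels) == n)
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    out <- rep(NA_integer_, n)
    out[labels %in% c("case", "1", "2")] <- 1L
    out[labels %in% c("control", "0")] <- 0L
    if (any(labels %in% "1") && any(labels %in% "2")) {
      # PLINK-coded 1=control, 2=case
      out[labels == "1"] <- 0L
      out[labels == "2"] <- 1L
    }
    return(out)
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L) | is.na(labels))) {
    stop("numeric labels must be 0 (control), 1 (case) or NA", call. = FALSE)
  }
  labels
}

#' Subset a genotype dataset
#'
#' @param x A [gwas_genotypes()] object.
#' @param samples,snps Integer or logical index vectors (missing = keep all).
#' @return A `gwas_genotypes` object.
#' @export
subset_genotypes <- function(x, samples = NULL, snps = NULL) {
  stopifnot(inherits(x, "gwas_genotypes"))
  si <- if (is.null(samples)) seq_len(nrow(x$dosages)) else samples
  ci <- if (is.null(snps)) seq_len(ncol(x$dosages)) else snps
  gwas_genotypes(
    x$dosages[si, ci, drop = FALSE],
    x$snps[ci, , drop = FALSE],
    samples = x$samples[si],
    labels = if (is.null(x$labels)) NULL else x$labels[si]
  )
}

#' Per-SNP summary statistics
#'
#' Call rate, minor allele frequency and genotype counts for every SNP,
#' computed over non-missing samples.
#'
#' @param x A [gwas_genotypes()] object.
#' @return A tibble with one row per SNP: `id`, `chrom`, `pos`, `n_called`,
#'   `call_rate`, `maf`, `n_aa`, `n_ab`, `n_bb` (counts of 0/1/2 dosage).
#' @export
snp_stats <- function(x) {
  stopifnot(inherits(x, "gwas_genotypes"))
  g <- x$dosages
  n <- nrow(g)
  n_called <- n - colSums(is.na(g))
  n_bb <- colSums(g == 2, na.rm = TRUE)
  n_ab <- colSums(g == 1, na.rm = TRUE)
  n_aa <- n_called - n_ab - n_bb
  freq_b <- ifelse(n_called > 0, (n_ab + 2 * n_bb) / (2 * n_called), NA_real_)
  tibble::tibble(
    id = x$snps$id, chrom = x$snps$chrom, pos = x$snps$pos,
    n_called = as.integer(n_called),
    call_rate = if (n > 0) n_called / n else rep(NA_real_, ncol(g)),
    maf = pmin(freq_b, 1 - freq_b),
    n_aa = as.integer(n_aa), n_ab = as.integer(n_ab), n_bb = as.integer(n_bb)
  )
}
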