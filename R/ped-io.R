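#' Read genotypes from PLINK text pedigree files
#'
#' Parses the whitespace-delimited `.ped`/`.map` pair into a
#' [gwas_genotypes()] object. The `.map` file supplies the SNP order
#' (columns re-sorted by chromosome and position on construction); the
#' `.ped` file supplies six leading columns (family, individual, father,
#' mother, sex, phenotype) followed by two allele tokens per SNP.
#'
#' The map may have 4 columns (chromosome, id, cM, position) or 6
#' columns with two trailing allele columns (`allele_a`, `allele_b`).
#' When alleles are listed, dosage counts copies of the second-listed
#' allele; otherwise `allele_a` is the first allele observed at each SNP
#' and dosage counts the second-seen allele. `"0"` tokens mark missing
#' genotypes. Phenotype column 6 is mapped 1 = control, 2 = case;
#' anything else leaves the phenotype absent.
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @return A [gwas_genotypes()] object.
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path, call. = FALSE)
  if (!file.exists(map_path)) stop("map file not found: ", map_path, call. = FALSE)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  if (length(map_tok) && !all(lengths(map_tok) %in% c(4L, 6L))) {
    bad <- which(!lengths(map_tok) %in% c(4L, 6L))[1]
    stop(sprintf("map line %d: expected 4 or 6 columns, found %d",
                 bad, lengths(map_tok)[bad]), call. = FALSE)
  }
  m <- length(map_tok)
  col <- function(k, default = NA_character_) {
    vapply(map_tok, function(t) if (length(t) >= k) t[k] else default, "")
  }
  allele_a <- col(5)
  allele_b <- col(6)
  allele_a[allele_a %in% c(".", "0")] <- NA_character_
  allele_b[allele_b %in% c(".", "0")] <- NA_character_
  snps <- tibble::tibble(
    id = col(2), chrom = col(1),
    pos = as.integer(col(4)),
    allele_a = allele_a, allele_b = allele_b
  )

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)

  dos <- matrix(NA_real_, n, m)
  samples <- character(n)
  pheno <- rep(NA_integer_, n)
  allele_a <- snps$allele_a
  allele_b <- snps$allele_b

  for (i in seq_len(n)) {
    tok <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * m) {
      stop(sprintf("ped line %d: expected %d fields, found %d",
                   i, 6 + 2 * m, length(tok)), call. = FALSE)
    }
    samples[i] <- tok[2]
    ph <- tok[6]
    pheno[i] <- if (ph == "1") 0L else if (ph == "2") 1L else NA_integer_
    if (m == 0) next
    a1 <- tok[6 + 2 * seq_len(m) - 1]
    a2 <- tok[6 + 2 * seq_len(m)]
    for (j in seq_len(m)) {
      for (al in c(a1[j], a2[j])) {
        if (al == "0") next
        if (is.na(allele_a[j])) {
          allele_a[j] <- al
        } else if (al != allele_a[j] && is.na(allele_b[j])) {
          allele_b[j] <- al
        } else if (al != allele_a[j] && !identical(al, allele_b[j])) {
          stop(sprintf("ped line %d: >2 distinct alleles at SNP %s",
                       i, snps$id[j]), call. = FALSE)
        }
      }
      if (a1[j] == "0" || a2[j] == "0") {
        dos[i, j] <- NA_real_
      } else {
        dos[i, j] <- (a1[j] != allele_a[j]) + (a2[j] != allele_a[j])
      }
    }
  }
  snps$allele_a <- ifelse(is.na(allele_a), ".", allele_a)
  snps$allele_b <- ifelse(is.na(allele_b), ".", allele_b)

  if (anyDuplicated(samples) > 0) samples <- make.unique(samples)
  labels <- if (all(is.na(pheno))) NULL else pheno
  gwas_genotypes(dos, snps, samples = samples, labels = labels)
}

#' Write genotypes as PLINK text pedigree files
#'
#' Inverse of [read_ped_map()]: the emitted pair re-reads to an equal
#' dataset. By default the map gains two allele columns so that dosage
#' orientation survives the round trip; set `map_alleles = FALSE` for a
#' strictly 4-column map (orientation then depends on first-seen allele
#' order, as in any PLINK text interchange). Missing genotypes are
#' written as `"0 0"`.
#'
#' @param x A [gwas_genotypes()] object.
#' @param ped_path,map_path Output paths.
#' @param map_alleles Write a 6-column allele-bearing map (default `TRUE`).
#' @return `invisible(x)`.
#' @export
write_ped_map <- function(x, ped_path, map_path, map_alleles = TRUE) {
  stopifnot(inherits(x, "gwas_genotypes"))
  snps <- x$snps
  a <- ifelse(is.na(snps$allele_a), ".", snps$allele_a)
  b <- ifelse(is.na(snps$allele_b), ".", snps$allele_b)
  if (map_alleles) {
    writeLines(
      sprintf("%s\t%s\t0\t%d\t%s\t%s", snps$chrom, snps$id, snps$pos, a, b),
      map_path
    )
  } else {
    writeLines(
      sprintf("%s\t%s\t0\t%d", snps$chrom, snps$id, snps$pos),
      map_path
    )
  }
  n <- nrow(x$dosages)
  m <- ncol(x$dosages)
  # placeholder letters for alleles never observed (needed only if a
  # non-missing dosage exists at such a SNP)
  aa <- ifelse(a == ".", "A", a)
  bb <- ifelse(b == ".", "B", b)
  pheno <- if (is.null(x$labels)) rep("0", n) else {
    ifelse(is.na(x$labels), "0", ifelse(x$labels == 1L, "2", "1"))
  }
  lines <- character(n)
  for (i in seq_len(n)) {
    if (m > 0) {
      g <- x$dosages[i, ]
      a1 <- ifelse(is.na(g), "0", ifelse(g == 2, bb, aa))
      a2 <- ifelse(is.na(g), "0", ifelse(g >= 1, bb, aa))
      geno <- paste(a1, a2, sep = " ", collapse = " ")
      lines[i] <- paste("FAM", x$samples[i], "0", "0", "0", pheno[i], geno)
    } else {
      lines[i] <- paste("FAM", x$samples[i], "0", "0", "0", pheno[i])
    }
  }
  writeLines(lines, ped_path)
  invisible(x)
}
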