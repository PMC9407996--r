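#' Genotype counts per SNP
#'
#' Tallies unphased diploid calls into homozygote/heterozygote counts per SNP.
#' Missing calls (`NA` or `"./."`) are excluded listwise per SNP.
#'
#' @param geno Wide genotype tibble: `animal` plus one `"X/Y"` column per SNP.
#' @param snps SNP metadata tibble with at least `snp`, `allele1`, `allele2`
#'   (orientation: `n_hom1` counts the `allele1` homozygote); a `gene` column
#'   is carried through when present.
#' @return Tibble with one row per SNP: counts `n_hom1`, `n_het`, `n_hom2`,
#'   `n_missing`, `n_typed`.
#' @export
count_genotypes <- function(geno, snps) {
  snps <- as_tibble(snps)
  missing_cols <- setdiff(snps$snp, names(geno))
  if (length(missing_cols)) {
    abort(paste0("genotype table lacks SNP column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    g <- geno[[snps$snp[i]]]
    g[g %in% c("./.", ".", "")] <- NA
    a1 <- snps$allele1[i]
    n1 <- (substr(g, 1, 1) == a1) + (substr(g, 3, 3) == a1)
    tibble(snp = snps$snp[i],
           n_hom1 = sum(n1 == 2, na.rm = TRUE),
           n_het = sum(n1 == 1, na.rm = TRUE),
           n_hom2 = sum(n1 == 0, na.rm = TRUE),
           n_missing = sum(is.na(g)))
  })
  keep_cols <- intersect(c("snp", "gene", "allele1", "allele2"), names(snps))
  snps |>
    select(all_of(keep_cols)) |>
    left_join(list_rbind(rows), by = "snp") |>
    mutate(n_typed = .data$n_hom1 + .data$n_het + .data$n_hom2)
}

#' Genotype frequencies
#'
#' Divides genotype counts by the number of typed animals. SNPs with no typed
#' animals are flagged (`typed = FALSE`) with `NA` frequencies so downstream
#' steps can exclude them.
#'
#' @param counts Tibble from [count_genotypes()] (or any tibble with columns
#'   `n_hom1`, `n_het`, `n_hom2`).
#' @return Input with columns `f_hom1`, `f_het`, `f_hom2`, `typed` appended.
#' @export
genotype_frequencies <- function(counts) {
  counts |>
    mutate(n_typed = .data$n_hom1 + .data$n_het + .data$n_hom2,
           typed = .data$n_typed > 0,
           f_hom1 = ifelse(.data$typed, .data$n_hom1 / .data$n_typed, NA_real_),
           f_het = ifelse(.data$typed, .data$n_het / .data$n_typed, NA_real_),
           f_hom2 = ifelse(.data$typed, .data$n_hom2 / .data$n_typed, NA_real_))
}

#' Allele frequencies from genotype frequencies
#'
#' `p = f_hom1 + f_het/2` (frequency of the first-listed allele), `q = 1 - p`.
#'
#' @param freqs Tibble from [genotype_frequencies()].
#' @return Input with columns `p`, `q` appended.
#' @export
allele_frequencies <- function(freqs) {
  freqs |>
    mutate(p = .data$f_hom1 + 0.5 * .data$f_het,
           q = 1 - .data$p)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Compares observed genotype counts with the expectation
#' `n * (p^2, 2pq, q^2)` under the allele frequencies observed in the same
#' sample; `df = 1` (three genotype classes, one estimated allele frequency).
#' No continuity correction is applied. A monomorphic SNP (an expected cell of
#' zero) is reported as `chisq = 0`, `hwe_pass = TRUE` with a warning.
#'
#' @param counts Tibble with columns `n_hom1`, `n_het`, `n_hom2`.
#' @param alpha Significance threshold for the pass flag (default 0.05).
#' @return Input with `hwe_chisq`, `hwe_df`, `hwe_p`, `hwe_pass` appended.
#' @export
hwe_test <- function(counts, alpha = 0.05) {
  res <- allele_frequencies(genotype_frequencies(counts))
  stat <- function(n1, nh, n2, p, q, nt) {
    if (nt == 0) return(c(NA_real_, NA_real_, NA))
    e <- nt * c(p^2, 2 * p * q, q^2)
    if (any(e == 0)) {
      warn("monomorphic SNP: Hardy-Weinberg test degenerate, reported as passing")
      return(c(0, 1, TRUE))
    }
    x2 <- sum((c(n1, nh, n2) - e)^2 / e)
    pv <- pchisq(x2, df = 1, lower.tail = FALSE)
    c(x2, pv, pv >= alpha)
  }
  vals <- t(mapply(stat, res$n_hom1, res$n_het, res$n_hom2, res$p, res$q, res$n_typed))
  counts |>
    mutate(hwe_chisq = vals[, 1], hwe_df = 1L, hwe_p = vals[, 2],
           hwe_pass = as.logical(vals[, 3]))
}

#' SNP frequency report
#'
#' One-stop per-SNP summary: genotype counts and frequencies, allele
#' frequencies, and the Hardy-Weinberg chi-square flag — the layout of a
#' standard candidate-gene frequency table.
#'
#' @inheritParams count_genotypes
#' @param alpha Hardy-Weinberg pass threshold.
#' @return Tibble with one row per SNP.
#' @export
snp_frequency_table <- function(geno, snps, alpha = 0.05) {
  count_genotypes(geno, snps) |>
    genotype_frequencies() |>
    allele_frequencies() |>
    hwe_test(alpha = alpha) |>
    select(-any_of(c("typed")))
}
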