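# genotype label column for one SNP, ordered hom1 / het / hom2
snp_factor <- function(geno, snp, allele1, allele2) {
  g <- geno[[snp]]
  g[g %in% c("./.", ".", "")] <- NA
  gg <- gsub("/", "", g)
  het <- paste0(pmin(allele1, allele2), pmax(allele1, allele2))
  levs <- c(paste0(allele1, allele1), het, paste0(allele2, allele2))
  factor(gg, levels = levs[levs %in% stats::na.omit(gg)])
}

#' Single-SNP association scan under the animal model
#'
#' For each SNP, fits the animal model with the genotype as a fixed factor
#' (one REML fit per trait x lactation x SNP), performs the Wald chi-square
#' test, computes genotype LS-means with compact significance letters,
#' applies the per-gene Bonferroni correction, and (when all three genotype
#' classes are observed) appends the additive/dominance/substitution effect
#' decomposition based on the cohort allele frequencies.
#'
#' @param pheno Phenotype tibble (`animal`, `lactation`, `hys`,
#'   `calving_age`, trait columns).
#' @param geno Wide unphased genotype tibble.
#' @param snps SNP metadata (`snp`, `gene`, `allele1`, `allele2`).
#' @param ainv A-inverse from [build_A_inverse()].
#' @param traits Trait column(s) to analyse.
#' @param lactations Lactation(s) to analyse.
#' @param correction `"per-gene"` (family = SNPs of the same gene in the
#'   scan) or `"global"` (family = all scanned SNPs).
#' @param ... Passed to [fit_animal_model()].
#' @return Tibble with one row per SNP x trait x lactation x genotype class:
#'   counts, LS-mean, SE, significance letters, plus the per-test `chisq`,
#'   `p_value`, `p_corrected`, variance components, and `a`, `d`, `alpha`.
#' @export
assoc_single_snp <- function(pheno, geno, snps, ainv, traits, lactations,
                             correction = c("per-gene", "global"), ...) {
  correction <- match.arg(correction)
  snps <- as_tibble(snps)
  fam <- if (correction == "per-gene") {
    setNames(as.integer(table(snps$gene)[snps$gene]), snps$snp)
  } else {
    setNames(rep(nrow(snps), nrow(snps)), snps$snp)
  }
  freqs <- snp_frequency_table(geno, snps)
  out <- list()
  for (lact in lactations) {
    ph <- filter(pheno, .data$lactation == lact)
    for (tr in traits) {
      for (i in seq_len(nrow(snps))) {
        s <- snps$snp[i]
        dat <- ph
        dat$genotype <- snp_factor(geno, s, snps$allele1[i], snps$allele2[i])[
          match(ph$animal, geno$animal)]
        fit <- fit_animal_model(dat, tr, ainv, factor_name = "genotype", ...)
        wt <- test_factor(fit)
        lsm <- ls_means(fit)
        let <- pairwise_letters(lsm)
        res <- lsm |>
          left_join(let, by = "level") |>
          mutate(snp = s, gene = snps$gene[i], trait = tr, lactation = lact,
                 chisq = wt$chisq, df = wt$df, p_value = wt$p_value,
                 m_family = unname(fam[s]),
                 p_corrected = unname(bonferroni(wt$p_value, fam[s])),
                 sigma_a2 = fit$sigma_a2, sigma_e2 = fit$sigma_e2)
        # effect decomposition needs all three classes, ordered hom1/het/hom2
        if (nrow(lsm) == 3) {
          pq <- freqs |> filter(.data$snp == s)
          eff <- decompose_effects(lsm$estimate[1], lsm$estimate[2],
                                   lsm$estimate[3], pq$p)
          res <- res |> mutate(a = eff$a, d = eff$d, alpha = eff$alpha)
        } else {
          res <- res |> mutate(a = NA_real_, d = NA_real_, alpha = NA_real_)
        }
        out[[length(out) + 1]] <- res
      }
    }
  }
  list_rbind(out) |>
    select("snp", "gene", "trait", "lactation", "level", "n", "estimate", "se",
           "letters_05", "letters_01", "chisq", "df", "p_value", "m_family",
           "p_corrected", "sigma_a2", "sigma_e2", "a", "d", "alpha") |>
    structure(class = c("lactsnp_assoc", "tbl_df", "tbl", "data.frame"))
}

#' Haplotype-combination association
#'
#' Runs the same animal-model machinery with the block haplotype combination
#' (diplotype) as the tested factor; combinations below `min_count` carriers
#' are excluded. Bonferroni family = number of blocks analysed.
#'
#' @param pheno Phenotype tibble.
#' @param blocks Named list of `lactsnp_block` objects from
#'   [em_block_phase()].
#' @param ainv A-inverse.
#' @param traits,lactations As in [assoc_single_snp()].
#' @param min_count Minimum carriers per combination (default 30).
#' @param ... Passed to [fit_animal_model()].
#' @return Tibble, one row per block x trait x lactation x combination.
#' @export
haplotype_association <- function(pheno, blocks, ainv, traits, lactations,
                                  min_count = 30, ...) {
  m <- length(blocks)
  if (is.null(names(blocks))) names(blocks) <- paste0("Block", seq_len(m))
  out <- list()
  for (lact in lactations) {
    ph <- filter(pheno, .data$lactation == lact)
    for (tr in traits) {
      for (bn in names(blocks)) {
        dip <- diplotype_factor(blocks[[bn]], min_count = min_count)
        dat <- ph
        dat$combination <- factor(dip$combination[match(ph$animal, dip$animal)])
        fit <- fit_animal_model(dat, tr, ainv, factor_name = "combination", ...)
        wt <- test_factor(fit)
        lsm <- ls_means(fit)
        let <- pairwise_letters(lsm)
        out[[length(out) + 1]] <- lsm |>
          left_join(let, by = "level") |>
          mutate(block = bn, trait = tr, lactation = lact,
                 chisq = wt$chisq, df = wt$df, p_value = wt$p_value,
                 m_family = m, p_corrected = bonferroni(wt$p_value, m),
                 sigma_a2 = fit$sigma_a2, sigma_e2 = fit$sigma_e2)
      }
    }
  }
  list_rbind(out) |>
    select("block", "trait", "lactation", "level", "n", "estimate", "se",
           "letters_05", "letters_01", "chisq", "df", "p_value", "m_family",
           "p_corrected", "sigma_a2", "sigma_e2") |>
    structure(class = c("lactsnp_assoc", "tbl_df", "tbl", "data.frame"))
}
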