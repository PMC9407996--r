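#' Trait specification for the cohort simulator
#'
#' Describes one milk production trait in the generative model
#' `y = mu + HYS + b * M + G + u + e`: an overall mean, i.i.d. normal
#' herd-year-season class effects, a calving-age regression, per-SNP genotype
#' values coded (+a, d, -a) for (hom1, het, hom2), a polygenic animal effect
#' with pedigree covariance `A * sigma_a2`, and residual variance `sigma_e2`.
#'
#' @param name Trait name (column name in the phenotype table).
#' @param mu Overall mean, trait units.
#' @param hys_sd Standard deviation of the herd-year-season class effects.
#' @param b Regression coefficient on calving age (trait units per month).
#' @param sigma_a2 Additive genetic variance (>= 0).
#' @param sigma_e2 Residual variance (> 0).
#' @param effects Optional tibble with columns `snp`, `a`, `d`: the additive
#'   and dominance genotype values for that SNP (effect orientation: the
#'   homozygote of the SNP's first-listed allele takes `+a`).
#' @return A `lactsnp_trait_spec` list.
#' @export
trait_spec <- function(name, mu, hys_sd, b, sigma_a2, sigma_e2, effects = NULL) {
  if (sigma_a2 < 0) abort(paste0("trait '", name, "': sigma_a2 must be >= 0"))
  if (sigma_e2 <= 0) abort(paste0("trait '", name, "': sigma_e2 must be > 0"))
  if (is.null(effects)) effects <- tibble(snp = character(), a = numeric(), d = numeric())
  structure(list(name = name, mu = mu, hys_sd = hys_sd, b = b,
                 sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
                 effects = as_tibble(effects)),
            class = "lactsnp_trait_spec")
}

#' Simulation configuration for a paternal half-sib dairy cohort
#'
#' @param n_sires Number of unrelated founder sires (each heads one paternal
#'   half-sib family).
#' @param daughters_per_sire Integer range `c(min, max)`; family sizes are
#'   drawn uniformly from this range.
#' @param n_daughters Optional total daughter count. When given, the uniform
#'   family-size draws are stochastically rebalanced (random +/-1 moves, kept
#'   within the range) until they sum to this total.
#' @param snps Tibble of SNP metadata: `snp`, `gene`, `chrom`, `position`,
#'   `allele1`, `allele2`, `freq1` (founder frequency of `allele1`; ignored
#'   for SNPs that belong to a block).
#' @param blocks List of haplotype blocks; each element is
#'   `list(snps = <character vector>, haplotypes = <named numeric>)` where the
#'   names are allele strings over the member SNPs and values are founder
#'   haplotype frequencies summing to 1.
#' @param traits List of [trait_spec()] objects.
#' @param n_farms,n_years,n_seasons Herd-year-season structure; each record is
#'   assigned a uniformly random crossed farm x year x season class.
#' @param age_range Calving-age range (months) at first lactation; second
#'   lactation ages are shifted by +12 months.
#' @param lactation2_fraction Fraction of daughters that also have a
#'   second-lactation record (the two lactation cohorts need not coincide).
#' @param seed Integer seed used by [simulate_cohort()].
#' @return A validated `lactsnp_sim_config` list.
#' @export
sim_config <- function(n_sires,
                       daughters_per_sire,
                       snps,
                       traits,
                       blocks = list(),
                       n_daughters = NULL,
                       n_farms = 10, n_years = 3, n_seasons = 4,
                       age_range = c(22, 34),
                       lactation2_fraction = 1,
                       seed = 1L) {
  if (length(n_sires) != 1 || n_sires < 1) abort("n_sires must be a single integer >= 1")
  r <- as.integer(daughters_per_sire)
  if (length(r) != 2 || any(r < 1) || r[1] > r[2]) {
    abort("daughters_per_sire must be c(min, max) with 1 <= min <= max")
  }
  snps <- as_tibble(snps)
  need <- c("snp", "gene", "chrom", "position", "allele1", "allele2", "freq1")
  if (!all(need %in% names(snps))) {
    abort(paste0("snps tibble needs columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(snps$snp)) abort("duplicate SNP names in snps")
  if (any(snps$freq1 < 0 | snps$freq1 > 1, na.rm = TRUE)) {
    abort("founder allele frequencies must lie in [0, 1]")
  }
  in_block <- unlist(lapply(blocks, `[[`, "snps"))
  if (anyDuplicated(in_block)) {
    abort(paste0("SNP listed in two blocks: ", in_block[duplicated(in_block)][1]))
  }
  if (!all(in_block %in% snps$snp)) {
    abort("block member SNPs must appear in the snps tibble")
  }
  for (b in blocks) {
    h <- b$haplotypes
    if (abs(sum(h) - 1) > 1e-9) {
      abort(paste0("haplotype frequencies for block [",
                   paste(b$snps, collapse = ","), "] must sum to 1"))
    }
    if (any(h < 0)) abort("haplotype frequencies must be non-negative")
    if (any(nchar(names(h)) != length(b$snps))) {
      abort("haplotype allele strings must have one letter per member SNP")
    }
    # marker alleles and founder frequencies of block members are implied by
    # the haplotypes; derive them and check consistency with the snps table
    for (k in seq_along(b$snps)) {
      letters_k <- substr(names(h), k, k)
      fr <- tapply(h, letters_k, sum)
      fr <- sort(fr, decreasing = TRUE)
      if (length(fr) != 2) {
        abort(paste0("block SNP ", b$snps[k], " is not biallelic across haplotypes"))
      }
      i <- match(b$snps[k], snps$snp)
      if (!setequal(c(snps$allele1[i], snps$allele2[i]), names(fr))) {
        abort(paste0("alleles of ", b$snps[k], " disagree with block haplotype letters"))
      }
      snps$freq1[i] <- unname(fr[snps$allele1[i]])
    }
  }
  if (!is.null(n_daughters)) {
    if (n_daughters < n_sires * r[1] || n_daughters > n_sires * r[2]) {
      abort("n_daughters is unattainable from the family-size range")
    }
  }
  traits <- if (is(traits, "lactsnp_trait_spec")) list(traits) else traits
  for (tr in traits) {
    if (!is(tr, "lactsnp_trait_spec")) abort("traits must be trait_spec() objects")
    bad <- setdiff(tr$effects$snp, snps$snp)
    if (length(bad)) abort(paste0("trait '", tr$name, "' has effects for unknown SNP ", bad[1]))
  }
  if (lactation2_fraction < 0 || lactation2_fraction > 1) {
    abort("lactation2_fraction must lie in [0, 1]")
  }
  structure(list(n_sires = as.integer(n_sires), daughters_per_sire = r,
                 n_daughters = if (is.null(n_daughters)) NULL else as.integer(n_daughters),
                 snps = snps, blocks = blocks, traits = traits,
                 n_farms = n_farms, n_years = n_years, n_seasons = n_seasons,
                 age_range = age_range, lactation2_fraction = lactation2_fraction,
                 seed = as.integer(seed)),
            class = "lactsnp_sim_config")
}

#' Default cohort configuration
#'
#' The study-design defaults: 44 paternal half-sib families totalling 924
#' daughters (family sizes 6-62), 10 biallelic SNPs in two candidate genes
#' of which 7 form two haplotype blocks (a 5-SNP block with six founder
#' haplotypes and a 2-SNP block dominated by two haplotypes), and five milk
#' production traits over two lactations on realistic dairy scales
#' (heritability about 1/3 for the yield traits).
#'
#' @param seed Integer seed stored in the configuration.
#' @return A `lactsnp_sim_config`.
#' @export
default_cohort_config <- function(seed = 1L) {
  snps <- tribble(
    ~snp,           ~gene,       ~chrom, ~position, ~allele1, ~allele2, ~freq1,
    "ALDH18A1_01",  "ALDH18A1",  "26",   17130318,  "A",      "C",      0.8274,
    "ALDH18A1_02",  "ALDH18A1",  "26",   17118244,  "A",      "T",      NA,
    "ALDH18A1_03",  "ALDH18A1",  "26",   17102977,  "C",      "G",      NA,
    "ALDH18A1_04",  "ALDH18A1",  "26",   17100534,  "G",      "A",      NA,
    "ALDH18A1_05",  "ALDH18A1",  "26",   17089560,  "G",      "A",      NA,
    "ALDH18A1_06",  "ALDH18A1",  "26",   17088978,  "G",      "T",      NA,
    "ALDH18A1_07",  "ALDH18A1",  "26",   17088098,  "G",      "A",      NA,
    "ALDH18A1_08",  "ALDH18A1",  "26",   17086802,  "G",      "T",      NA,
    "MAT2A_01",     "MAT2A",     "11",   49472723,  "C",      "G",      0.8003,
    "MAT2A_02",     "MAT2A",     "11",   49465032,  "C",      "T",      0.6813
  )
  # Block haplotype frequencies follow the block structure the design targets:
  # six haplotypes 0.58/0.172/0.094/0.066/0.066/0.022 for the 5-SNP block and
  # a 2-SNP block with a rare third haplotype carrying the residual mass.
  blocks <- list(
    list(snps = paste0("ALDH18A1_0", 2:6),
         haplotypes = c(ACGGG = 0.580, TGGGG = 0.172, TGAAG = 0.094,
                        TGAGG = 0.066, TGAGT = 0.066, AGGGG = 0.022)),
    list(snps = paste0("ALDH18A1_0", 7:8),
         haplotypes = c(GG = 0.874, AT = 0.124, GT = 0.002))
  )
  traits <- list(
    trait_spec("milk",          10250, 300, 15,    4e5,   8e5,
               effects = tibble(snp = c("ALDH18A1_05", "MAT2A_02"),
                                a = c(150, 80), d = c(50, -30))),
    trait_spec("fat_yield",     360,   12,  0.5,   700,   1400,
               effects = tibble(snp = "ALDH18A1_01", a = 20, d = 15)),
    trait_spec("fat_pct",       3.45,  0.08, 0.002, 0.012, 0.02),
    trait_spec("protein_yield", 312,   9,   0.4,   400,   800,
               effects = tibble(snp = "ALDH18A1_05", a = 6, d = 2)),
    trait_spec("protein_pct",   2.98,  0.05, 0.001, 0.006, 0.012)
  )
  sim_config(n_sires = 44, daughters_per_sire = c(6, 62), n_daughters = 924,
             snps = snps, blocks = blocks, traits = traits,
             n_farms = 10, n_years = 3, n_seasons = 4,
             age_range = c(22, 34), lactation2_fraction = 635 / 924,
             seed = seed)
}
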