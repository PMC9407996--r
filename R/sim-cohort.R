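#' Simulate a paternal half-sib pedigree
#'
#' Founder sires and founder dams are unrelated; every daughter has exactly
#' one sire and one (unique) dam. Family sizes are drawn uniformly from
#' `config$daughters_per_sire`; if `config$n_daughters` is set, the draws are
#' rebalanced by random within-range +/-1 moves so the total matches.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @return Pedigree tibble (`animal`, `sire`, `dam`) with a `family` column
#'   (sire id) for daughters.
#' @export
simulate_pedigree <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- config$daughters_per_sire
  ns <- config$n_sires
  sizes <- r[1] + sample.int(r[2] - r[1] + 1L, ns, replace = TRUE) - 1L
  if (!is.null(config$n_daughters)) {
    delta <- config$n_daughters - sum(sizes)
    while (delta != 0L) {
      step <- sign(delta)
      movable <- if (step > 0) which(sizes < r[2]) else which(sizes > r[1])
      k <- if (length(movable) == 1L) movable else sample(movable, 1L)
      sizes[k] <- sizes[k] + step
      delta <- delta - step
    }
  }
  sires <- sprintf("S%03d", seq_len(ns))
  nd <- sum(sizes)
  dams <- sprintf("D%04d", seq_len(nd))
  daughters <- sprintf("C%04d", seq_len(nd))
  bind_rows(
    tibble(animal = sires, sire = NA_character_, dam = NA_character_, family = NA_character_),
    tibble(animal = dams, sire = NA_character_, dam = NA_character_, family = NA_character_),
    tibble(animal = daughters, sire = rep(sires, sizes), dam = dams,
           family = rep(sires, sizes))
  )
}

# integer haplotype index per chromosome for block b, allele letters for
# independent snps; gametes: whole-block haplotype, per-locus for the rest
#' Simulate phased genotypes by gene dropping
#'
#' Founders draw block haplotypes i.i.d. from the configured frequencies and
#' independent-SNP alleles per locus; every non-founder receives one gamete
#' from each parent with no recombination within a block and free
#' recombination between blocks and loose SNPs.
#'
#' @param ped Pedigree tibble (from [simulate_pedigree()] or [read_pedigree()]).
#' @inheritParams simulate_pedigree
#' @return Phased genotype tibble: `animal`, `snp`, `hap1` (paternal allele),
#'   `hap2` (maternal allele).
#' @export
simulate_genotypes <- function(ped, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pn <- ped_normalise(ped)
  n <- nrow(pn$ped)
  si <- pn$sire; di <- pn$dam
  snps <- config$snps
  m <- nrow(snps)
  block_of <- rep(NA_integer_, m)
  for (bi in seq_along(config$blocks)) {
    block_of[match(config$blocks[[bi]]$snps, snps$snp)] <- bi
  }
  # hap[[1]] / hap[[2]] are n x m allele-character matrices (paternal, maternal)
  hap <- list(matrix(NA_character_, n, m), matrix(NA_character_, n, m))
  founder <- si == 0L & di == 0L
  nf <- sum(founder)
  # founders: blocks first, then loose SNPs
  for (bi in seq_along(config$blocks)) {
    b <- config$blocks[[bi]]
    cols <- match(b$snps, snps$snp)
    hseq <- do.call(rbind, strsplit(names(b$haplotypes), ""))
    for (side in 1:2) {
      draw <- sample.int(length(b$haplotypes), nf, replace = TRUE, prob = b$haplotypes)
      hap[[side]][founder, cols] <- hseq[draw, , drop = FALSE]
    }
  }
  loose <- which(is.na(block_of))
  for (j in loose) {
    for (side in 1:2) {
      hap[[side]][founder, j] <- ifelse(runif(nf) < snps$freq1[j],
                                        snps$allele1[j], snps$allele2[j])
    }
  }
  # gene dropping in pedigree order; a gamete keeps each block intact
  gamete <- function(p) {
    g <- character(m)
    for (bi in seq_along(config$blocks)) {
      cols <- match(config$blocks[[bi]]$snps, snps$snp)
      side <- sample.int(2L, 1L)
      g[cols] <- hap[[side]][p, cols]
    }
    if (length(loose)) {
      side <- sample.int(2L, length(loose), replace = TRUE)
      g[loose] <- ifelse(side == 1L, hap[[1]][p, loose], hap[[2]][p, loose])
    }
    g
  }
  for (i in which(!founder)) {
    hap[[1]][i, ] <- if (si[i] > 0L) gamete(si[i]) else
      vapply(seq_len(m), function(j) founder_allele(snps, config, j, block_of), "")
    hap[[2]][i, ] <- if (di[i] > 0L) gamete(di[i]) else
      vapply(seq_len(m), function(j) founder_allele(snps, config, j, block_of), "")
  }
  tibble(animal = rep(pn$ped$animal, m),
         snp = rep(snps$snp, each = n),
         hap1 = as.vector(hap[[1]]),
         hap2 = as.vector(hap[[2]]))
}

# fallback gamete from the founder population for a half-known parent pair
founder_allele <- function(snps, config, j, block_of) {
  if (!is.na(block_of[j])) {
    b <- config$blocks[[block_of[j]]]
    k <- match(snps$snp[j], b$snps)
    hseq <- substr(names(b$haplotypes), k, k)
    sample(hseq, 1L, prob = b$haplotypes)
  } else {
    if (runif(1) < snps$freq1[j]) snps$allele1[j] else snps$allele2[j]
  }
}

#' Collapse phased genotypes to unphased calls
#'
#' @param phased Tibble from [simulate_genotypes()].
#' @return Wide tibble: `animal` plus one column per SNP holding
#'   alphabetically sorted `"X/Y"` genotype strings.
#' @export
unphase_genotypes <- function(phased) {
  phased |>
    mutate(genotype = paste(pmin(.data$hap1, .data$hap2),
                            pmax(.data$hap1, .data$hap2), sep = "/")) |>
    select("animal", "snp", "genotype") |>
    pivot_wider(names_from = "snp", values_from = "genotype")
}

#' Simulate phenotypes under the animal model
#'
#' Generates `y = mu + HYS + b * M + G + u + e` per trait and lactation:
#' crossed herd-year-season classes with i.i.d. normal effects, a uniform
#' calving-age covariate, genotype values coded (+a, d, -a), a polygenic
#' effect dropped through the pedigree (founders `N(0, sigma_a2)`, offspring
#' mid-parent plus a Mendelian-sampling deviate of variance
#' `(1/2 - (F_s + F_d)/4) sigma_a2`), and i.i.d. residuals.
#'
#' @param ped Pedigree tibble.
#' @param phased Phased genotypes from [simulate_genotypes()].
#' @inheritParams simulate_pedigree
#' @return List with `phenotypes` (tibble: `animal`, `lactation`, `farm`,
#'   `year`, `season`, `hys`, `calving_age`, one column per trait) and
#'   `truth` (variance components, fixed effects, per-animal breeding values,
#'   HYS effects, and the phased haplotypes).
#' @export
simulate_phenotypes <- function(ped, phased, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pn <- ped_normalise(ped)
  n <- nrow(pn$ped)
  si <- pn$sire; di <- pn$dam
  f <- inbreeding_coefficients(pn$ped)$f
  daughters <- pn$ped$animal[si > 0L | di > 0L]
  geno <- unphase_genotypes(phased)
  stopifnot(all(daughters %in% geno$animal))

  # records: all daughters in lactation 1; a random subset gets lactation 2
  n2 <- round(config$lactation2_fraction * length(daughters))
  l2 <- sample(daughters, n2)
  rec <- bind_rows(tibble(animal = daughters, lactation = 1L),
                   tibble(animal = l2, lactation = 2L))
  nr <- nrow(rec)
  rec <- rec |>
    mutate(farm = sample.int(config$n_farms, nr, replace = TRUE),
           year = sample.int(config$n_years, nr, replace = TRUE),
           season = sample.int(config$n_seasons, nr, replace = TRUE),
           hys = paste(.data$farm, .data$year, .data$season, sep = "-"),
           calving_age = runif(nr, config$age_range[1], config$age_range[2]) +
             12 * (.data$lactation - 1L))

  snps <- config$snps
  # code +1 / 0 / -1 for hom(allele1) / het / hom(allele2)
  geno_codes <- vapply(snps$snp, function(s) {
    g <- geno[[s]][match(rec$animal, geno$animal)]
    a1 <- snps$allele1[match(s, snps$snp)]
    (substr(g, 1, 1) == a1) + (substr(g, 3, 3) == a1) - 1
  }, numeric(nr))

  truth <- list(traits = list(), u = NULL, phased = phased,
                lactation2_animals = l2)
  u_tab <- tibble(animal = pn$ped$animal)
  out <- rec
  hys_classes <- sort(unique(rec$hys))
  for (tr in config$traits) {
    hys_eff <- setNames(rnorm(length(hys_classes), 0, tr$hys_sd), hys_classes)
    u <- numeric(n)
    for (i in seq_len(n)) {
      if (si[i] == 0L && di[i] == 0L) {
        u[i] <- rnorm(1, 0, sqrt(tr$sigma_a2))
      } else {
        mp <- 0; vms <- 0
        if (si[i] > 0L && di[i] > 0L) {
          mp <- 0.5 * (u[si[i]] + u[di[i]])
          vms <- (0.5 - 0.25 * (f[si[i]] + f[di[i]])) * tr$sigma_a2
        } else {
          p <- max(si[i], di[i])
          mp <- 0.5 * u[p]
          vms <- (0.75 - 0.25 * f[p]) * tr$sigma_a2
        }
        u[i] <- mp + rnorm(1, 0, sqrt(vms))
      }
    }
    gval <- numeric(nr)
    if (nrow(tr$effects)) {
      for (k in seq_len(nrow(tr$effects))) {
        code <- geno_codes[, tr$effects$snp[k]]
        gval <- gval + ifelse(code == 0, tr$effects$d[k], code * tr$effects$a[k])
      }
    }
    y <- tr$mu + hys_eff[rec$hys] + tr$b * rec$calving_age + gval +
      u[match(rec$animal, pn$ped$animal)] + rnorm(nr, 0, sqrt(tr$sigma_e2))
    out[[tr$name]] <- unname(y)
    truth$traits[[tr$name]] <- list(mu = tr$mu, b = tr$b,
                                    sigma_a2 = tr$sigma_a2, sigma_e2 = tr$sigma_e2,
                                    effects = tr$effects,
                                    hys_effects = tibble(hys = hys_classes,
                                                         effect = unname(hys_eff)))
    u_tab[[tr$name]] <- u
  }
  truth$u <- u_tab
  list(phenotypes = out, truth = truth)
}

#' Simulate a full cohort
#'
#' Runs [simulate_pedigree()], [simulate_genotypes()] and
#' [simulate_phenotypes()] under `config$seed`, so the whole simulation is
#' reproducible from the configuration alone.
#'
#' @inheritParams simulate_pedigree
#' @return List: `config`, `pedigree`, `phased`, `genotypes` (unphased wide),
#'   `phenotypes`, `truth`.
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  ped <- simulate_pedigree(config)
  phased <- simulate_genotypes(ped, config)
  sim <- simulate_phenotypes(ped, phased, config)
  list(config = config, pedigree = ped, phased = phased,
       genotypes = unphase_genotypes(phased),
       phenotypes = sim$phenotypes, truth = sim$truth)
}
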