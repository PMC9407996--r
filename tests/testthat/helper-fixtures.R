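# Shared fixtures and independent oracles, built in code at test time.

suppressMessages({
  library(dplyr)
  library(tibble)
})

# compact cohort: 20 half-sib families, sparse HYS structure, one yield trait
# with a single tested SNP plus a small two-SNP block
small_config <- function(seed = 1L, n_sires = 20, range = c(18, 22),
                         a = 0, d = 0, sigma_a2 = 1e4, sigma_e2 = 3e4) {
  snps <- tribble(
    ~snp,   ~gene,  ~chrom, ~position, ~allele1, ~allele2, ~freq1,
    "TEST", "GENE1", "1",   1000,      "A",      "C",      0.8,
    "B1",   "GENE1", "1",   2000,      "G",      "T",      NA,
    "B2",   "GENE1", "1",   3000,      "G",      "A",      NA
  )
  blocks <- list(list(snps = c("B1", "B2"),
                      haplotypes = c(GG = 0.7, TA = 0.3)))
  traits <- list(trait_spec("yield", 5000, 100, 10, sigma_a2, sigma_e2,
                            effects = tibble(snp = "TEST", a = a, d = d)))
  sim_config(n_sires = n_sires, daughters_per_sire = range,
             snps = snps, blocks = blocks, traits = traits,
             n_farms = 4, n_years = 2, n_seasons = 2,
             age_range = c(22, 34), lactation2_fraction = 0, seed = seed)
}

# ---- gene-dropping oracle for the A matrix -------------------------------
# 2 * kinship estimated by dropping distinct founder alleles through the
# pedigree and counting identity-by-descent between random gametes
gene_drop_kinship <- function(ped, reps = 1e6, seed = 99) {
  set.seed(seed)
  pn <- lactsnp:::ped_normalise(ped)
  n <- nrow(pn$ped)
  si <- pn$sire; di <- pn$dam
  a1 <- matrix(0L, reps, n)  # allele labels, column per animal
  a2 <- matrix(0L, reps, n)
  next_allele <- 1L
  for (i in seq_len(n)) {
    if (si[i] > 0L) {
      pick <- runif(reps) < 0.5
      a1[, i] <- ifelse(pick, a1[, si[i]], a2[, si[i]])
    } else {
      a1[, i] <- next_allele; next_allele <- next_allele + 1L
    }
    if (di[i] > 0L) {
      pick <- runif(reps) < 0.5
      a2[, i] <- ifelse(pick, a1[, di[i]], a2[, di[i]])
    } else {
      a2[, i] <- next_allele; next_allele <- next_allele + 1L
    }
  }
  K <- matrix(0, n, n, dimnames = list(pn$ped$animal, pn$ped$animal))
  for (i in seq_len(n)) for (j in i:n) {
    if (i == j) {
      # kinship with self: (1 + F)/2, F = P(the two own alleles IBD)
      phi <- 0.5 * (1 + mean(a1[, i] == a2[, i]))
    } else {
      phi <- 0.25 * (mean(a1[, i] == a1[, j]) + mean(a1[, i] == a2[, j]) +
                     mean(a2[, i] == a1[, j]) + mean(a2[, i] == a2[, j]))
    }
    K[i, j] <- K[j, i] <- 2 * phi
  }
  K
}

# three-generation 8-animal pedigree with a half-sib mating
pedigree_8 <- function() {
  tribble(
    ~animal, ~sire, ~dam,
    "A", NA, NA,
    "B", NA, NA,
    "C", NA, NA,
    "D", "A", "B",
    "E", "A", "C",
    "F", "D", "C",
    "G", "D", "E",   # parents are paternal half sibs
    "H", "F", "G"
  )
}

# ---- dense GLS / REML oracles --------------------------------------------
# generalized least squares with explicit V = Z A Z' sa2 + I se2
gls_fixed_effects <- function(y, X, Z, A, sigma_a2, sigma_e2) {
  V <- Z %*% A %*% t(Z) * sigma_a2 + diag(length(y)) * sigma_e2
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  cov_b <- solve(XtVi %*% X)
  list(beta = as.vector(cov_b %*% XtVi %*% y), cov = cov_b)
}

# -2 REML log-likelihood profiled in sigma_e2, dense H = ZAZ'/lambda + I
dense_reml_m2ll <- function(lambda, y, X, Z, A) {
  n <- length(y); p <- ncol(X)
  H <- Z %*% A %*% t(Z) / lambda + diag(n)
  Hi <- solve(H)
  XtHiX <- t(X) %*% Hi %*% X
  P <- Hi - Hi %*% X %*% solve(XtHiX) %*% t(X) %*% Hi
  se2 <- as.numeric(t(y) %*% P %*% y) / (n - p)
  as.numeric((n - p) * log(se2) + determinant(H, logarithm = TRUE)$modulus[1] +
               determinant(XtHiX, logarithm = TRUE)$modulus[1])
}

# direct haplotype counting on phase-known data (oracle for the EM)
count_haplotypes <- function(phased, snp_order) {
  w <- phased |>
    filter(.data$snp %in% snp_order) |>
    group_by(.data$animal) |>
    summarise(h1 = paste(.data$hap1[match(snp_order, .data$snp)], collapse = ""),
              h2 = paste(.data$hap2[match(snp_order, .data$snp)], collapse = ""),
              .groups = "drop")
  tab <- table(c(w$h1, w$h2))
  sort(tab / sum(tab), decreasing = TRUE)
}
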