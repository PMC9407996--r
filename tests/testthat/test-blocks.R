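test_that("block detection recovers the simulated two-block structure", {
  cfg <- default_cohort_config()
  hits <- 0
  for (seed in 1:3) {
    set.seed(seed)
    ped <- simulate_pedigree(cfg)
    g <- unphase_genotypes(simulate_genotypes(ped, cfg))
    daughters <- ped$animal[!is.na(ped$sire)]
    g <- filter(g, animal %in% daughters)
    bl <- find_blocks(ld_pairwise(g, cfg$snps), cfg$snps)
    found <- lapply(bl$snps, sort)
    want1 <- sort(cfg$blocks[[1]]$snps)
    want2 <- sort(cfg$blocks[[2]]$snps)
    if (any(vapply(found, identical, TRUE, want1)) &&
        any(vapply(found, identical, TRUE, want2)) && nrow(bl) == 2) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 2)
})

test_that("mutual perfect LD yields one block and independence yields none", {
  set.seed(8)
  # three SNPs riding on two haplotypes -> all pairs in complete LD
  hp <- sample(c("AAA", "BBB"), 1200, TRUE, c(0.7, 0.3))
  split3 <- function(h, k) substr(h, k, k)
  g <- tibble(animal = sprintf("x%04d", 1:600))
  for (k in 1:3) {
    a <- split3(hp[1:600], k); b <- split3(hp[601:1200], k)
    g[[paste0("s", k)]] <- paste(pmin(a, b), pmax(a, b), sep = "/")
  }
  snps <- tibble(snp = paste0("s", 1:3), chrom = "1", position = 1:3 * 100,
                 allele1 = "A", allele2 = "B")
  bl <- find_blocks(ld_pairwise(g, snps), snps)
  expect_equal(nrow(bl), 1)
  expect_equal(sort(bl$snps[[1]]), c("s1", "s2", "s3"))
  # independent SNPs: no blocks
  g2 <- tibble(animal = sprintf("x%04d", 1:600))
  for (k in 1:3) {
    a <- sample(c("A", "B"), 600, TRUE); b <- sample(c("A", "B"), 600, TRUE)
    g2[[paste0("s", k)]] <- paste(pmin(a, b), pmax(a, b), sep = "/")
  }
  bl2 <- find_blocks(ld_pairwise(g2, snps), snps)
  expect_equal(nrow(bl2), 0)
  # fewer than two SNPs: empty result
  expect_equal(nrow(find_blocks(tibble(), snps[1, ])), 0)
})

test_that("multi-locus EM equals direct counting on phase-known data", {
  set.seed(15)
  # haplotypes chosen so every animal has at most one heterozygous site
  haps <- c("ACG", "ACT")
  h1 <- sample(haps, 80, TRUE, c(0.7, 0.3))
  h2 <- sample(haps, 80, TRUE, c(0.7, 0.3))
  g <- tibble(animal = sprintf("p%03d", 1:80))
  for (k in 1:3) {
    a <- substr(h1, k, k); b <- substr(h2, k, k)
    g[[paste0("m", k)]] <- paste(pmin(a, b), pmax(a, b), sep = "/")
  }
  snps <- tibble(snp = paste0("m", 1:3), allele1 = c("A", "C", "G"),
                 allele2 = c("C", "G", "T"))
  blk <- em_block_phase(g, paste0("m", 1:3), snps)
  direct <- sort(table(c(h1, h2)) / 160, decreasing = TRUE)
  got <- setNames(blk$haplotypes$freq, blk$haplotypes$hap)
  expect_equal(got[names(direct)], direct, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a single-SNP block reduces to allele frequencies", {
  set.seed(4)
  a <- sample(c("A", "C"), 300, TRUE, c(0.65, 0.35))
  b <- sample(c("A", "C"), 300, TRUE, c(0.65, 0.35))
  g <- tibble(animal = sprintf("q%03d", 1:300),
              s = paste(pmin(a, b), pmax(a, b), sep = "/"))
  snps <- tibble(snp = "s", allele1 = "A", allele2 = "C")
  blk <- em_block_phase(g, "s", snps)
  p_obs <- mean(c(a, b) == "A")
  expect_equal(blk$haplotypes$freq[blk$haplotypes$hap == "A"], p_obs,
               tolerance = 1e-9)
})

test_that("the frequency filter keeps a 0.066 haplotype and drops a 0.02 one", {
  cfg <- default_cohort_config()
  set.seed(3)
  ped <- simulate_pedigree(cfg)
  phased <- simulate_genotypes(ped, cfg)
  daughters <- ped$animal[!is.na(ped$sire)]
  g <- unphase_genotypes(phased) |> filter(animal %in% daughters)
  blk <- em_block_phase(g, cfg$blocks[[1]]$snps, cfg$snps)
  h <- blk$haplotypes
  expect_false(h$retained[h$hap == "AGGGG"])   # simulated at 0.022
  expect_true(h$retained[h$hap == "TGAGG"])    # simulated at 0.066
  expect_true(h$retained[h$hap == "TGAGT"])    # simulated at 0.066
  # EM recovers the realized sample frequencies closely; the configured truth
  # only within the half-sib sampling noise (88 paternal founder chromosomes)
  realized <- count_haplotypes(filter(phased, animal %in% daughters),
                               cfg$blocks[[1]]$snps)
  expect_lt(max(abs(h$freq[match(names(realized), h$hap)] - realized)), 0.01)
  truth <- cfg$blocks[[1]]$haplotypes
  expect_lt(max(abs(h$freq[match(names(truth), h$hap)] - truth)), 0.08)
  # H labels in descending frequency, H1 the major haplotype
  expect_equal(h$label[1], "H1")
  expect_equal(h$hap[1], "ACGGG")
})

test_that("diplotypes are consistent with the unphased genotypes", {
  cfg <- small_config(seed = 2)
  co <- simulate_cohort(cfg)
  blk <- em_block_phase(co$genotypes, c("B1", "B2"), cfg$snps)
  dip <- blk$diplotypes
  for (k in 1:2) {
    sn <- c("B1", "B2")[k]
    a <- substr(dip$hap1, k, k); b <- substr(dip$hap2, k, k)
    got <- paste(pmin(a, b), pmax(a, b), sep = "/")
    expect_equal(got, co$genotypes[[sn]][match(dip$animal, co$genotypes$animal)])
  }
  # EM log-likelihood trace is non-decreasing
  expect_true(all(diff(blk$loglik) > -1e-9))
})

test_that("oversized blocks are rejected", {
  g <- tibble(animal = "x")
  snps <- tibble(snp = paste0("s", 1:13), allele1 = "A", allele2 = "B")
  for (s in snps$snp) g[[s]] <- "A/B"
  expect_error(em_block_phase(g, snps$snp, snps), "12 SNPs")
})
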