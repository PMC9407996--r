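# hand-written 6-bp PFM used across tests; consensus ACGTAC
hand_pfm_text <- c(
  ">TEST1 handmade",
  "A [ 8 0 1 0 9 0 ]",
  "C [ 1 7 0 2 0 8 ]",
  "G [ 0 2 9 0 1 0 ]",
  "T [ 1 1 0 8 0 2 ]"
)

test_that("JASPAR dialects parse and weights match hand arithmetic", {
  m1 <- read_pfm(hand_pfm_text)
  expect_equal(m1$name, "TEST1 handmade")
  expect_equal(dim(m1$counts), c(4, 6))
  # same matrix without labels or brackets
  m2 <- read_pfm(c(">TEST1", "8 0 1 0 9 0", "1 7 0 2 0 8",
                   "0 2 9 0 1 0", "1 1 0 8 0 2"))
  expect_equal(m2$counts, m1$counts, ignore_attr = TRUE)
  # hand-computed log-odds: w = log2((c + 0.8*0.25) / (N + 0.8) / 0.25)
  w_a1 <- log2((8 + 0.8 * 0.25) / (10 + 0.8) / 0.25)
  expect_equal(unname(m1$pwm["A", 1]), w_a1, tolerance = 1e-12)
  w_g3 <- log2((9 + 0.2) / 10.8 / 0.25)
  expect_equal(unname(m1$pwm["G", 3]), w_g3, tolerance = 1e-12)
  # smin/smax from per-column extrema
  expect_equal(m1$smax, sum(apply(m1$pwm, 2, max)), tolerance = 1e-12)
})

test_that("malformed matrices are rejected", {
  expect_error(read_pfm(c(">X", "1 2 3", "1 2 3 4", "1 2 3 4", "1 2 3 4")),
               "ragged")
  expect_error(read_pfm(c(">X", "1 2 -3 4", "1 2 3 4", "1 2 3 4", "1 2 3 4")),
               "negative")
  # all-uniform columns: Smin = Smax is degenerate
  expect_error(read_pfm(c(">X", "1 1 1 1", "1 1 1 1", "1 1 1 1", "1 1 1 1")),
               "degenerate")
})

test_that("relative score is 1 at the consensus and 0 at the anti-consensus", {
  m <- read_pfm(hand_pfm_text)
  consensus <- paste(rownames(m$pwm)[apply(m$pwm, 2, which.max)], collapse = "")
  anti <- paste(rownames(m$pwm)[apply(m$pwm, 2, which.min)], collapse = "")
  expect_equal(relative_score(consensus, m), 1)
  expect_equal(relative_score(anti, m), 0)
  expect_error(relative_score("ACGT", m), "length")
  # spreadsheet oracle for an arbitrary 6-mer
  seq6 <- "ACGGAC"
  s <- sum(vapply(1:6, function(k) m$pwm[substr(seq6, k, k), k], 0))
  expect_equal(relative_score(seq6, m), (s - m$smin) / (m$smax - m$smin),
               tolerance = 1e-9)
})

test_that("relative scores are bounded and monotone toward the consensus", {
  m <- read_pfm(hand_pfm_text)
  set.seed(30)
  cons <- rownames(m$pwm)[apply(m$pwm, 2, which.max)]
  for (r in 1:50) {
    win <- sample(c("A", "C", "G", "T"), 6, TRUE)
    s0 <- relative_score(paste(win, collapse = ""), m)
    expect_gte(s0, 0); expect_lte(s0, 1)
    k <- sample(6, 1)
    win2 <- win; win2[k] <- cons[k]
    expect_gte(relative_score(paste(win2, collapse = ""), m), s0 - 1e-12)
  }
  # N contributes the worst-case column weight
  expect_equal(relative_score("NCGTAC", m),
               relative_score(paste0(rownames(m$pwm)[which.min(m$pwm[, 1])],
                                     "CGTAC"), m),
               tolerance = 1e-12)
})

test_that("allele scans classify gained, lost, retained and absent sites", {
  m <- read_pfm(hand_pfm_text)  # consensus ACGTAC
  # alt allele completes the consensus at the SNP position
  flank <- "TTTTTACGAACTTTTT"    # ref G at offset 9 breaks the consensus
  expect_error(scan_alleles(flank, 9, "C", "T", m), "ref allele")
  res <- scan_alleles(flank, 9, "A", "T", m, threshold = 0.999)
  expect_equal(res$classification, "gained")
  expect_equal(res$alt_score, 1)
  # ref = alt can only be retained or absent
  res2 <- scan_alleles(flank, 9, "A", "A", m, threshold = 0.5)
  expect_true(res2$classification %in% c("retained", "absent"))
  # a motif nowhere near threshold is absent
  res3 <- scan_alleles("GGGGGGGGGGGGGGG", 8, "G", "C", m, threshold = 0.95)
  expect_equal(res3$classification, "absent")
})

test_that("classifications are strand-symmetric", {
  m <- read_pfm(hand_pfm_text)
  set.seed(77)
  for (r in 1:10) {
    flank <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
    ref <- substr(flank, 11, 11)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    fwd <- scan_alleles(flank, 11, ref, alt, m, threshold = 0.8)
    rc <- lactsnp:::revcomp(flank)
    bwd <- scan_alleles(rc, 11, lactsnp:::revcomp(ref), lactsnp:::revcomp(alt),
                        m, threshold = 0.8)
    expect_equal(bwd$classification, fwd$classification)
    expect_equal(bwd$ref_score, fwd$ref_score, tolerance = 1e-12)
    expect_equal(bwd$alt_score, fwd$alt_score, tolerance = 1e-12)
  }
})

test_that("FASTA flanks load as named uppercase sequences", {
  skip_if_not_installed("Biostrings")
  tmp <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">snp1 upstream flank", "acgtACGTacgt", ">snp2", "TTTTAAAA"), tmp)
  fl <- read_flank_fasta(tmp)
  expect_equal(unname(fl["snp1"]), "ACGTACGTACGT")
  expect_equal(names(fl), c("snp1", "snp2"))
})

test_that("multi-motif JASPAR files round-trip through read_jaspar", {
  tmp <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(hand_pfm_text,
               ">TEST2", "A 1 2 3 4", "C 4 3 2 1", "G 0 0 0 9", "T 5 5 5 0"),
             tmp)
  ms <- read_jaspar(tmp)
  expect_length(ms, 2)
  expect_equal(ms[[2]]$length, 4)
})
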