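# genotype column -> copies of allele1 (0/1/2), NA for missing
geno_code <- function(g, allele1) {
  g[g %in% c("./.", ".", "")] <- NA
  (substr(g, 1, 1) == allele1) + (substr(g, 3, 3) == allele1)
}

# two-locus genotype log-likelihood given the four haplotype frequencies
# tab: 3x3 counts indexed by copies of allele1 at locus 1 (rows) and 2 (cols)
two_locus_loglik <- function(tab, h) {
  # h = c(h11, h12, h21, h22): locus1 allele (1/2) x locus2 allele (1/2)
  tbl <- two_locus_pairs_table()
  ll <- 0
  for (c1 in 0:2) for (c2 in 0:2) {
    n <- tab[c1 + 1, c2 + 1]
    if (n > 0) {
      pairs <- tbl[[c1 * 3 + c2 + 1]]
      pr <- sum(vapply(pairs, function(p) {
        (if (p[1] == p[2]) 1 else 2) * h[p[1]] * h[p[2]]
      }, 0))
      if (pr <= 0) return(-Inf)
      ll <- ll + n * log(pr)
    }
  }
  ll
}

# memoised compatible-pair table for all 9 two-locus genotype classes
two_locus_pairs_table <- local({
  tbl <- NULL
  function() {
    if (is.null(tbl)) {
      tbl <<- lapply(0:8, function(k) hap_pairs_two_locus(k %/% 3, k %% 3))
    }
    tbl
  }
})

# unordered haplotype pairs compatible with a two-locus genotype
# haplotype index: 1 = (a1,b1), 2 = (a1,b2), 3 = (a2,b1), 4 = (a2,b2)
hap_pairs_two_locus <- function(c1, c2) {
  hs <- list(c1 = c(2, 2, 1, 1)[1:4], c2 = c(2, 1, 2, 1))
  idx <- which(outer(1:4, 1:4, function(i, j) {
    (hs$c1[i] + hs$c1[j] - 2 == c1) & (hs$c2[i] + hs$c2[j] - 2 == c2)
  }), arr.ind = TRUE)
  idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
  lapply(seq_len(nrow(idx)), function(r) c(idx[r, 1], idx[r, 2]))
}

#' Two-locus EM estimate of haplotype frequencies and D'
#'
#' Standard EM over the double-heterozygote phase ambiguity, initialised at
#' linkage-equilibrium product frequencies and iterated to log-likelihood
#' convergence. Reports `D = p11 - p1 * q1`, the normalised
#' `D' = |D| / Dmax`, and `r^2`.
#'
#' @param g1,g2 Character genotype vectors (`"X/Y"`) for the two SNPs over
#'   the same animals.
#' @param allele1_1,allele1_2 The first-listed allele of each SNP (frequency
#'   orientation).
#' @param tol Log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return One-row tibble: haplotype frequencies `h11`, `h12`, `h21`, `h22`,
#'   `d`, `dprime`, `r2`, `n` (informative animals), `loglik`, `monomorphic`.
#' @export
em_two_locus <- function(g1, g2, allele1_1, allele1_2, tol = 1e-8, max_iter = 1000) {
  c1 <- geno_code(g1, allele1_1)
  c2 <- geno_code(g2, allele1_2)
  ok <- !is.na(c1) & !is.na(c2)
  c1 <- c1[ok]; c2 <- c2[ok]
  n <- length(c1)
  if (n < 2) abort("need at least 2 informative animals for two-locus EM")
  tab <- matrix(0, 3, 3)
  for (i in seq_len(n)) tab[c1[i] + 1, c2[i] + 1] <- tab[c1[i] + 1, c2[i] + 1] + 1
  p1 <- mean(c1) / 2   # freq of allele1 at locus 1
  p2 <- mean(c2) / 2
  mono <- p1 %in% c(0, 1) || p2 %in% c(0, 1)
  h <- c(p1 * p2, p1 * (1 - p2), (1 - p1) * p2, (1 - p1) * (1 - p2))
  ndh <- tab[2, 2]  # double heterozygotes
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # expected haplotype counts; all classes but the double het are unambiguous
    cnt <- numeric(4)
    for (a in 0:2) for (b in 0:2) {
      nn <- tab[a + 1, b + 1]
      if (nn == 0 || (a == 1 && b == 1)) next
      for (p in hap_pairs_two_locus(a, b)) {
        cnt[p[1]] <- cnt[p[1]] + nn
        cnt[p[2]] <- cnt[p[2]] + nn
      }
    }
    if (ndh > 0) {
      w_cis <- h[1] * h[4]; w_trans <- h[2] * h[3]
      pc <- if (w_cis + w_trans > 0) w_cis / (w_cis + w_trans) else 0.5
      cnt[c(1, 4)] <- cnt[c(1, 4)] + ndh * pc
      cnt[c(2, 3)] <- cnt[c(2, 3)] + ndh * (1 - pc)
    }
    h <- cnt / (2 * n)
    ll <- two_locus_loglik(tab, h)
    if (ll < ll_old - 1e-9) abort("EM log-likelihood decreased")
    if (ll - ll_old < tol) break
    ll_old <- ll
  }
  pA <- h[1] + h[2]; pB <- h[1] + h[3]
  d <- h[1] - pA * pB
  dmax <- if (d >= 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (mono || dmax == 0) NA_real_ else abs(d) / dmax
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- if (denom > 0) d^2 / denom else NA_real_
  tibble(h11 = h[1], h12 = h[2], h21 = h[3], h22 = h[4],
         p1 = pA, p2 = pB, d = d, dprime = dprime, r2 = r2,
         n = n, loglik = ll, monomorphic = mono)
}

#' Likelihood-based confidence interval for D'
#'
#' Evaluates the two-locus genotype likelihood on a grid of D' values in
#' `[0, 1]` (allele frequencies held at their EM estimates, sign of D fixed at
#' the point estimate), normalises it, and reads off the interval between the
#' `alpha/...` tails — the construction behind the Gabriel block definition.
#'
#' @param fit One-row tibble from [em_two_locus()].
#' @param g1,g2,allele1_1,allele1_2 Genotype data, as in [em_two_locus()].
#' @param grid_points Number of grid points on `[0, 1]` (default 101).
#' @param conf Central mass between the bounds (default 0.90).
#' @return Tibble `ci_low`, `ci_high` (one row).
#' @export
dprime_ci <- function(fit, g1, g2, allele1_1, allele1_2,
                      grid_points = 101, conf = 0.90) {
  if (is.na(fit$dprime)) {
    warn("D' undefined (monomorphic SNP); CI reported as [0, 1]")
    return(tibble(ci_low = 0, ci_high = 1))
  }
  c1 <- geno_code(g1, allele1_1)
  c2 <- geno_code(g2, allele1_2)
  ok <- !is.na(c1) & !is.na(c2)
  c1 <- c1[ok]; c2 <- c2[ok]
  tab <- matrix(0, 3, 3)
  for (i in seq_along(c1)) tab[c1[i] + 1, c2[i] + 1] <- tab[c1[i] + 1, c2[i] + 1] + 1
  pA <- fit$p1; pB <- fit$p2
  s <- if (fit$d >= 0) 1 else -1
  dmax <- if (s > 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  grid <- seq(0, 1, length.out = grid_points)
  ll <- vapply(grid, function(dp) {
    dd <- s * dp * dmax
    h <- c(pA * pB + dd, pA * (1 - pB) - dd, (1 - pA) * pB - dd, (1 - pA) * (1 - pB) + dd)
    h <- pmax(h, 0)
    sh <- sum(h)
    if (sh <= 0) return(-Inf)
    two_locus_loglik(tab, h / sh)
  }, 0)
  if (all(!is.finite(ll))) {
    warn("degenerate D' likelihood; CI reported as [0, 1]")
    return(tibble(ci_low = 0, ci_high = 1))
  }
  lik <- exp(ll - max(ll, na.rm = TRUE))
  lik[!is.finite(lik)] <- 0
  cum <- cumsum(lik) / sum(lik)
  tail <- (1 - conf) / 2
  lo <- grid[which(cum >= tail)[1]]
  hi <- grid[which(cum >= 1 - tail)[1]]
  tibble(ci_low = lo, ci_high = hi)
}

#' All pairwise LD within chromosomes
#'
#' Runs [em_two_locus()] and [dprime_ci()] for every SNP pair on the same
#' chromosome, SNPs ordered by position.
#'
#' @param geno Wide genotype tibble (`animal` + SNP columns).
#' @param snps SNP metadata (`snp`, `chrom`, `position`, `allele1`, `allele2`).
#' @param conf Confidence level for the D' interval.
#' @return Tibble with one row per pair: `snp1`, `snp2`, `chrom`, D'
#'   statistics and CI bounds.
#' @export
ld_pairwise <- function(geno, snps, conf = 0.90) {
  snps <- as_tibble(snps) |> arrange(.data$chrom, .data$position)
  out <- list()
  for (ch in unique(snps$chrom)) {
    ss <- filter(snps, .data$chrom == ch)
    if (nrow(ss) < 2) next
    for (i in seq_len(nrow(ss) - 1)) for (j in seq(i + 1, nrow(ss))) {
      fit <- em_two_locus(geno[[ss$snp[i]]], geno[[ss$snp[j]]],
                          ss$allele1[i], ss$allele1[j])
      ci <- if (is.na(fit$dprime)) tibble(ci_low = NA_real_, ci_high = NA_real_) else
        dprime_ci(fit, geno[[ss$snp[i]]], geno[[ss$snp[j]]],
                  ss$allele1[i], ss$allele1[j], conf = conf)
      out[[length(out) + 1]] <- bind_cols(
        tibble(snp1 = ss$snp[i], snp2 = ss$snp[j], chrom = ch), fit, ci)
    }
  }
  list_rbind(out)
}
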