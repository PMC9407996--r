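#' Gabriel-style haplotype block detection
#'
#' Classifies each pair by its D' confidence interval: strong LD when
#' `ci_low >= strong_low` and `ci_high >= strong_high`; strong recombination
#' when `ci_high < recomb_high`; other pairs are uninformative. A contiguous
#' span of SNPs is a candidate block when at least `frac_strong` of its
#' informative pairs are in strong LD (and it has at least one informative
#' pair); maximal non-overlapping candidates are chosen greedily longest
#' first. Blocks never span chromosomes.
#'
#' @param ld Pairwise LD tibble from [ld_pairwise()].
#' @param snps SNP metadata (`snp`, `chrom`, `position`).
#' @param strong_low,strong_high,recomb_high,frac_strong Gabriel thresholds
#'   (defaults 0.70 / 0.98 / 0.90 / 0.95, the Haploview defaults).
#' @return Tibble with one row per detected block: `block`, `chrom`,
#'   `n_snps`, and a list-column `snps` of member SNP names in position order.
#' @export
find_blocks <- function(ld, snps, strong_low = 0.70, strong_high = 0.98,
                        recomb_high = 0.90, frac_strong = 0.95) {
  snps <- as_tibble(snps) |> arrange(.data$chrom, .data$position)
  if (nrow(snps) < 2) return(tibble(block = integer(), chrom = character(),
                                    n_snps = integer(), snps = list()))
  ld <- ld |>
    mutate(strong = !is.na(.data$ci_low) & .data$ci_low >= strong_low &
             .data$ci_high >= strong_high,
           recomb = !is.na(.data$ci_high) & .data$ci_high < recomb_high,
           informative = .data$strong | .data$recomb)
  out <- list()
  for (ch in unique(snps$chrom)) {
    ss <- filter(snps, .data$chrom == ch)$snp
    k <- length(ss)
    if (k < 2) next
    pair <- function(i, j) {
      filter(ld, (.data$snp1 == ss[i] & .data$snp2 == ss[j]) |
               (.data$snp1 == ss[j] & .data$snp2 == ss[i]))
    }
    cand <- list()
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      n_inf <- 0L; n_str <- 0L
      for (a in seq(i, j - 1)) for (b in seq(a + 1, j)) {
        pr <- pair(a, b)
        if (nrow(pr) && pr$informative[1]) {
          n_inf <- n_inf + 1L
          if (pr$strong[1]) n_str <- n_str + 1L
        }
      }
      if (n_inf > 0 && n_str / n_inf >= frac_strong) {
        cand[[length(cand) + 1]] <- list(i = i, j = j, len = j - i + 1)
      }
    }
    if (!length(cand)) next
    lens <- vapply(cand, `[[`, 0, "len")
    starts <- vapply(cand, `[[`, 0, "i")
    ordc <- order(-lens, starts)
    taken <- rep(FALSE, k)
    for (ci in ordc) {
      span <- seq(cand[[ci]]$i, cand[[ci]]$j)
      if (!any(taken[span])) {
        taken[span] <- TRUE
        out[[length(out) + 1]] <- tibble(chrom = ch,
                                         n_snps = length(span),
                                         snps = list(ss[span]),
                                         .start = cand[[ci]]$i)
      }
    }
  }
  if (!length(out)) return(tibble(block = integer(), chrom = character(),
                                  n_snps = integer(), snps = list()))
  list_rbind(out) |>
    arrange(.data$chrom, .data$.start) |>
    mutate(block = row_number()) |>
    select("block", "chrom", "n_snps", "snps")
}

#' Multi-locus EM haplotype phasing of a block
#'
#' Estimates block haplotype frequencies by EM over all haplotype pairs
#' consistent with each animal's multilocus genotype (initialised at
#' linkage-equilibrium product frequencies; frequencies below `prune` are
#' dropped between iterations). Haplotypes with final frequency above
#' `retain` are labelled `H1..Hk` by descending frequency, and each animal is
#' assigned its maximum-posterior consistent pair (ties broken toward the
#' pair containing the globally more frequent haplotype).
#'
#' @param geno Wide genotype tibble.
#' @param block_snps Member SNP names, in map order.
#' @param snps SNP metadata (`snp`, `allele1`, `allele2`).
#' @param retain Frequency threshold above which a haplotype is retained
#'   (default 0.05).
#' @param prune In-iteration pruning threshold (default 1e-4).
#' @param tol,max_iter EM convergence controls.
#' @return A `lactsnp_block` object: `$haplotypes` (tibble `hap`, `freq`,
#'   `retained`, `label`), `$diplotypes` (tibble `animal`, `hap1`, `hap2`,
#'   `combination`, `posterior`), `$snps`, `$loglik`.
#' @export
em_block_phase <- function(geno, block_snps, snps, retain = 0.05,
                           prune = 1e-4, tol = 1e-8, max_iter = 1000) {
  L <- length(block_snps)
  if (L > 12) abort("block exceeds 12 SNPs; phase it in windows instead")
  snps <- as_tibble(snps)
  meta <- snps[match(block_snps, snps$snp), ]
  if (anyNA(meta$snp)) abort("block member SNP missing from metadata")
  n_all <- nrow(geno)
  codes <- vapply(seq_len(L), function(k) geno_code(geno[[block_snps[k]]], meta$allele1[k]),
                  numeric(n_all))
  codes <- matrix(codes, nrow = n_all)
  ok <- stats::complete.cases(codes)
  animals <- geno$animal[ok]
  codes <- codes[ok, , drop = FALSE]
  n <- nrow(codes)
  if (n == 0) abort("no animal fully typed on the block")

  hap_str <- function(bits) {
    # bits: 1 = allele1, 0 = allele2 per position
    paste(ifelse(bits == 1, meta$allele1, meta$allele2), collapse = "")
  }
  # enumerate compatible unordered haplotype pairs per distinct genotype pattern
  pat_key <- apply(codes, 1, paste, collapse = "")
  pats <- unique(pat_key)
  pat_n <- as.vector(table(factor(pat_key, levels = pats)))
  pat_pairs <- lapply(pats, function(p) {
    cs <- as.integer(strsplit(p, "")[[1]])
    het <- which(cs == 1)
    base1 <- ifelse(cs == 2, 1L, 0L)  # homozygous positions fixed
    if (!length(het)) {
      return(list(h1 = hap_str(base1), h2 = hap_str(base1)))
    }
    combos <- expand.grid(rep(list(0:1), length(het)))
    h1s <- character(0); h2s <- character(0)
    for (r in seq_len(nrow(combos))) {
      b1 <- base1; b2 <- base1
      b1[het] <- as.integer(combos[r, ])
      b2[het] <- 1L - as.integer(combos[r, ])
      s1 <- hap_str(b1); s2 <- hap_str(b2)
      key <- paste(pmin(s1, s2), pmax(s1, s2))
      if (!key %in% paste(pmin(h1s, h2s), pmax(h1s, h2s))) {
        h1s <- c(h1s, s1); h2s <- c(h2s, s2)
      }
    }
    list(h1 = h1s, h2 = h2s)
  })
  haps <- unique(unlist(lapply(pat_pairs, function(p) c(p$h1, p$h2))))
  # linkage-equilibrium initial frequencies
  pfreq1 <- colMeans(codes) / 2
  init <- vapply(haps, function(h) {
    bits <- strsplit(h, "")[[1]] == meta$allele1
    prod(ifelse(bits, pfreq1, 1 - pfreq1))
  }, 0)
  f <- init / sum(init)
  names(f) <- haps
  i1 <- lapply(pat_pairs, function(p) match(p$h1, haps))
  i2 <- lapply(pat_pairs, function(p) match(p$h2, haps))
  ll_old <- -Inf
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    cnt <- numeric(length(haps))
    ll <- 0
    for (pi in seq_along(pats)) {
      a <- i1[[pi]]; b <- i2[[pi]]
      w <- f[a] * f[b] * ifelse(a == b, 1, 2)
      sw <- sum(w)
      if (sw <= 0) next
      post <- w / sw
      np <- pat_n[pi]
      for (r in seq_along(a)) {
        cnt[a[r]] <- cnt[a[r]] + np * post[r]
        cnt[b[r]] <- cnt[b[r]] + np * post[r]
      }
      ll <- ll + np * log(sw)
    }
    f_new <- setNames(cnt / (2 * n), haps)
    f_new[f_new < prune] <- 0
    f_new <- f_new / sum(f_new)
    if (ll < ll_old - 1e-9 && it > 1) abort("block EM log-likelihood decreased")
    ll_trace <- c(ll_trace, ll)
    conv <- is.finite(ll_old) && (ll - ll_old < tol)
    f <- f_new
    if (conv) break
    ll_old <- ll
  }
  ord <- order(-f)
  htab <- tibble(hap = haps[ord], freq = unname(f[ord])) |>
    filter(.data$freq > 0) |>
    mutate(retained = .data$freq > retain,
           label = ifelse(.data$retained, paste0("H", cumsum(.data$retained)), NA_character_))
  # maximum-posterior diplotype per animal
  best <- lapply(seq_along(pats), function(pi) {
    a <- i1[[pi]]; b <- i2[[pi]]
    w <- f[a] * f[b] * ifelse(a == b, 1, 2)
    sw <- sum(w)
    if (sw <= 0) return(list(h1 = NA_character_, h2 = NA_character_, post = NA_real_))
    post <- w / sw
    top <- which(post == max(post))
    if (length(top) > 1) {
      # prefer the pair containing the globally most frequent haplotype
      bestf <- vapply(top, function(r) max(f[a[r]], f[b[r]]), 0)
      top <- top[which.max(bestf)]
    } else top <- top[1]
    # order pair by descending frequency
    hh <- c(haps[a[top]], haps[b[top]])
    hh <- hh[order(-f[hh])]
    list(h1 = hh[1], h2 = hh[2], post = max(post))
  })
  pi_of <- match(pat_key, pats)
  lab <- setNames(htab$label, htab$hap)
  dip <- tibble(animal = animals,
                hap1 = vapply(best, `[[`, "", "h1")[pi_of],
                hap2 = vapply(best, `[[`, "", "h2")[pi_of],
                posterior = vapply(best, `[[`, 0, "post")[pi_of]) |>
    mutate(label1 = unname(lab[.data$hap1]), label2 = unname(lab[.data$hap2]),
           combination = ifelse(is.na(.data$label1) | is.na(.data$label2),
                                NA_character_,
                                paste0(.data$label1, .data$label2)))
  structure(list(snps = meta, haplotypes = htab, diplotypes = dip,
                 loglik = ll_trace, n = n),
            class = "lactsnp_block")
}

#' @export
print.lactsnp_block <- function(x, ...) {
  cat("Haplotype block over", nrow(x$snps), "SNPs (", x$n, "animals )\n")
  print(x$haplotypes)
  invisible(x)
}

#' Haplotype-combination factor for association
#'
#' Extracts per-animal haplotype combinations from a phased block, keeping
#' only combinations carried by at least `min_count` animals (the rest are
#' dropped as `NA`).
#'
#' @param block A `lactsnp_block` from [em_block_phase()].
#' @param min_count Minimum carriers for a combination to be analysed
#'   (default 30).
#' @return Tibble `animal`, `combination` (NA for dropped/unassigned).
#' @export
diplotype_factor <- function(block, min_count = 30) {
  dip <- block$diplotypes |> select("animal", "combination")
  keep <- dip |> count(.data$combination) |>
    filter(!is.na(.data$combination), .data$n >= min_count) |>
    pull(.data$combination)
  dip |> mutate(combination = ifelse(.data$combination %in% keep,
                                     .data$combination, NA_character_))
}
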