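#' Read a genotype TSV
#'
#' Tab-separated table with an `animal` column and one column per SNP holding
#' diploid calls (`A/C`, `AC`, or `A C`); calls are normalised to sorted
#' `"X/Y"` strings, with `./.`, `.`, `NA` or empty as missing.
#'
#' @param path TSV path.
#' @return Wide genotype tibble.
#' @export
read_genotypes_tsv <- function(path) {
  g <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (!"animal" %in% names(g)) abort("genotype TSV needs an 'animal' column")
  for (s in setdiff(names(g), "animal")) {
    x <- gsub("[ /|]", "", g[[s]])
    x[x %in% c("", "..", ".", "NA")] <- NA
    a1 <- substr(x, 1, 1); a2 <- substr(x, 2, 2)
    g[[s]] <- ifelse(is.na(x), NA_character_,
                     paste(pmin(a1, a2), pmax(a1, a2), sep = "/"))
  }
  g
}

#' Write a genotype TSV
#'
#' @param geno Wide genotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(geno, path) {
  readr::write_tsv(geno, path, na = "./.")
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Reads diploid `GT` calls (phased or unphased accepted; phase is not
#' retained) and converts allele indices to bases.
#'
#' @param path VCF path (plain text or gzipped).
#' @return List with `geno` (wide genotype tibble, animals x SNPs) and `snps`
#'   (metadata tibble: `snp`, `chrom`, `position`, `allele1` = REF,
#'   `allele2` = first ALT).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID)
  gt <- vcfR::extract.gt(v, element = "GT")
  rownames(gt) <- ids
  conv <- function(cell, ref, alt) {
    if (is.na(cell)) return(NA_character_)
    al <- strsplit(cell, "[/|]")[[1]]
    if (length(al) != 2 || any(al == ".")) return(NA_character_)
    b <- c(ref, strsplit(alt, ",")[[1]])[as.integer(al) + 1]
    paste(pmin(b[1], b[2]), pmax(b[1], b[2]), sep = "/")
  }
  geno <- tibble(animal = colnames(gt))
  for (i in seq_along(ids)) {
    geno[[ids[i]]] <- vapply(gt[i, ], conv, "", ref = fix$REF[i], alt = fix$ALT[i],
                             USE.NAMES = FALSE)
  }
  snps <- tibble(snp = ids, chrom = fix$CHROM, position = as.numeric(fix$POS),
                 allele1 = fix$REF,
                 allele2 = vapply(strsplit(fix$ALT, ","), `[`, "", 1))
  list(geno = geno, snps = snps)
}

#' Write genotypes as a minimal VCF
#'
#' Unphased diploid `GT`-only records; `allele1` is written as REF and
#' `allele2` as ALT.
#'
#' @param geno Wide genotype tibble.
#' @param snps SNP metadata (`snp`, `chrom`, `position`, `allele1`, `allele2`).
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, snps, path) {
  snps <- as_tibble(snps)
  animals <- geno$animal
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", animals), collapse = "\t"))
  body <- vapply(seq_len(nrow(snps)), function(i) {
    g <- geno[[snps$snp[i]]]
    code <- function(x) {
      if (is.na(x)) return("./.")
      a <- strsplit(x, "/")[[1]]
      idx <- match(a, c(snps$allele1[i], snps$allele2[i])) - 1
      paste(sort(idx), collapse = "/")
    }
    paste(c(snps$chrom[i], format(snps$position[i], scientific = FALSE),
            snps$snp[i], snps$allele1[i], snps$allele2[i], ".", "PASS", ".",
            "GT", vapply(g, code, "", USE.NAMES = FALSE)), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}
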