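#' Run the full candidate-gene analysis pipeline
#'
#' Executes the stages in dependency order — frequency/HWE summary, pairwise
#' LD, block detection, block phasing, single-SNP association, haplotype
#' association, and (when motifs and flanks are supplied) the
#' allele-differential TFBS scan — writing one TSV per stage plus a JSON run
#' manifest recording seed, thresholds, versions and timings.
#'
#' @param out_dir Output directory (created if needed).
#' @param cohort A cohort list (as from [simulate_cohort()], or assembled
#'   from files: `pedigree`, `genotypes`, `phenotypes`, and a `config` whose
#'   `snps` tibble describes the markers). If `NULL`, a synthetic cohort is
#'   generated from `config`.
#' @param config Simulation configuration used when `cohort` is `NULL`
#'   (default [default_cohort_config()] with `seed`).
#' @param traits,lactations Subsets to analyse (default: all configured
#'   traits, both lactations).
#' @param correction Bonferroni family mode for the single-SNP scan.
#' @param min_count Carrier threshold for haplotype combinations.
#' @param tfbs_threshold Relative-score binding threshold.
#' @param motifs Optional named list of `lactsnp_pwm` for the TFBS stage.
#' @param tfbs_sites Optional tibble for the TFBS stage: `snp`, `flank`,
#'   `offset`, `ref`, `alt`.
#' @param seed Seed used when generating the synthetic cohort.
#' @return Invisibly, a named list of the stage result tibbles and the
#'   manifest.
#' @export
run_pipeline <- function(out_dir, cohort = NULL, config = NULL,
                         traits = NULL, lactations = c(1L, 2L),
                         correction = "per-gene", min_count = 30,
                         tfbs_threshold = 0.8, motifs = NULL,
                         tfbs_sites = NULL, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    s <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), s, units = "secs")), 3)
    res
  }

  if (is.null(cohort)) {
    if (is.null(config)) config <- default_cohort_config(seed = seed)
    cohort <- stage("simulate", simulate_cohort(config))
    write_pedigree(cohort$pedigree |> select("animal", "sire", "dam"),
                   file.path(out_dir, "pedigree.csv"))
    write_genotypes_tsv(cohort$genotypes, file.path(out_dir, "genotypes.tsv"))
    write_genotypes_vcf(cohort$genotypes, config$snps,
                        file.path(out_dir, "genotypes.vcf"))
    readr::write_csv(cohort$phenotypes, file.path(out_dir, "phenotypes.csv"))
  }
  config <- cohort$config %||% config
  snps <- config$snps
  if (is.null(traits)) traits <- vapply(config$traits, `[[`, "", "name")

  freq <- stage("frequencies", snp_frequency_table(cohort$genotypes, snps))
  readr::write_tsv(freq, file.path(out_dir, "snp_frequencies.tsv"))

  ld <- stage("ld", ld_pairwise(cohort$genotypes, snps))
  readr::write_tsv(ld |> select(-"loglik"), file.path(out_dir, "ld_pairwise.tsv"))

  blocks_tab <- stage("blocks", find_blocks(ld, snps))
  readr::write_tsv(blocks_tab |>
                     mutate(snps = vapply(.data$snps, paste, "", collapse = ",")),
                   file.path(out_dir, "blocks.tsv"))

  phased_blocks <- stage("phase", {
    bl <- list()
    for (i in seq_len(nrow(blocks_tab))) {
      bl[[paste0("Block", i)]] <- em_block_phase(cohort$genotypes,
                                                 blocks_tab$snps[[i]], snps)
    }
    bl
  })
  if (length(phased_blocks)) {
    hap_tab <- imap(phased_blocks, \(b, nm) mutate(b$haplotypes, block = nm)) |>
      list_rbind()
    readr::write_tsv(hap_tab, file.path(out_dir, "block_haplotypes.tsv"))
    dip_tab <- imap(phased_blocks, \(b, nm) mutate(b$diplotypes, block = nm)) |>
      list_rbind()
    readr::write_tsv(dip_tab, file.path(out_dir, "diplotypes.tsv"))
  }

  ainv <- stage("kinship", build_A_inverse(cohort$pedigree |>
                                             select("animal", "sire", "dam")))

  assoc <- stage("association",
                 assoc_single_snp(cohort$phenotypes, cohort$genotypes, snps,
                                  ainv, traits, lactations,
                                  correction = correction))
  readr::write_tsv(assoc, file.path(out_dir, "association_snp.tsv"))

  hap_assoc <- NULL
  if (length(phased_blocks)) {
    hap_assoc <- stage("haplotype_association",
                       haplotype_association(cohort$phenotypes, phased_blocks,
                                             ainv, traits, lactations,
                                             min_count = min_count))
    readr::write_tsv(hap_assoc, file.path(out_dir, "association_haplotype.tsv"))
  }

  tfbs <- NULL
  if (!is.null(motifs) && !is.null(tfbs_sites)) {
    tfbs <- stage("tfbs", {
      rows <- lapply(seq_len(nrow(tfbs_sites)), function(i) {
        scan_alleles(tfbs_sites$flank[i], tfbs_sites$offset[i],
                     tfbs_sites$ref[i], tfbs_sites$alt[i], motifs,
                     threshold = tfbs_threshold) |>
          mutate(snp = tfbs_sites$snp[i], .before = 1)
      })
      list_rbind(rows)
    })
    readr::write_tsv(tfbs, file.path(out_dir, "tfbs_scan.tsv"))
  }

  manifest <- list(
    package = "lactsnp",
    version = as.character(utils::packageVersion("lactsnp")),
    seed = if (!is.null(cohort$config)) cohort$config$seed else seed,
    traits = traits, lactations = lactations,
    thresholds = list(correction = correction, min_count = min_count,
                      tfbs_threshold = tfbs_threshold,
                      block_strong_low = 0.70, block_strong_high = 0.98,
                      block_recomb_high = 0.90, block_frac_strong = 0.95,
                      haplotype_retain = 0.05, hwe_alpha = 0.05),
    timings_sec = timings,
    total_sec = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(frequencies = freq, ld = ld, blocks = blocks_tab,
                 phased_blocks = phased_blocks, association = assoc,
                 haplotype_association = hap_assoc, tfbs = tfbs,
                 manifest = manifest))
}
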