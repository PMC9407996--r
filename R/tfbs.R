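#' Parse a JASPAR position frequency matrix
#'
#' Accepts the common JASPAR `.jaspar` / `.pfm` dialects: a `>` header line
#' (motif id and name) followed by four count rows, with or without `A/C/G/T`
#' row labels and square brackets. Builds the log-odds weight matrix with the
#' JASPAR pseudocount convention (pseudocount 0.8 split by background):
#' `w = log2((c + 0.8 * bg) / (N + 0.8) / bg)`.
#'
#' @param text Character vector of lines (or a single string with newlines).
#' @param background Nucleotide background frequencies in A, C, G, T order
#'   (default uniform 0.25).
#' @param pseudocount Total pseudocount (default 0.8).
#' @return A `lactsnp_pwm`: counts, weight matrix, background, `smin`, `smax`.
#' @export
read_pfm <- function(text, background = rep(0.25, 4), pseudocount = 0.8) {
  if (length(text) == 1 && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]
  lines <- text[nzchar(trimws(text))]
  name <- "motif"
  if (grepl("^>", lines[1])) {
    name <- trimws(sub("^>\\s*", "", lines[1]))
    lines <- lines[-1]
  }
  if (length(lines) < 4) abort("PFM needs 4 count rows")
  bases <- c("A", "C", "G", "T")
  rows <- vector("list", 4)
  labels <- character(4)
  for (r in 1:4) {
    ln <- lines[r]
    lab <- toupper(sub("^\\s*([ACGTacgt])[\\s\\[|:].*$", "\\1", ln, perl = TRUE))
    if (lab %in% bases && nchar(lab) == 1) {
      labels[r] <- lab
      ln <- sub("^\\s*[ACGTacgt]", "", ln, perl = TRUE)
    }
    ln <- gsub("[\\[\\]|:]", " ", ln, perl = TRUE)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    if (anyNA(vals)) abort(paste0("PFM format error at row ", r, ": non-numeric count"))
    if (any(vals < 0)) abort(paste0("PFM format error at row ", r, ": negative count"))
    rows[[r]] <- vals
  }
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) {
    abort(paste0("PFM format error: ragged rows (lengths ",
                 paste(lens, collapse = "/"), ")"))
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- if (all(labels %in% bases) && !anyDuplicated(labels)) labels else bases
  counts <- counts[bases, , drop = FALSE]
  L <- ncol(counts)
  if (L < 4) abort("PFM must have at least 4 positions")
  if (any(colSums(counts) <= 0)) abort("PFM has a column with zero total count")
  names(background) <- bases
  N <- colSums(counts)
  w <- log2(sweep(counts + pseudocount * background, 2, N + pseudocount, "/") / background)
  smin <- sum(apply(w, 2, min))
  smax <- sum(apply(w, 2, max))
  if (smax - smin <= 0) abort("degenerate PFM: all columns uniform (Smin = Smax)")
  structure(list(name = name, counts = counts, background = background,
                 pwm = w, smin = smin, smax = smax, length = L),
            class = "lactsnp_pwm")
}

#' Read all JASPAR motifs in a file or directory
#'
#' @param path A `.jaspar`/`.pfm` file (possibly holding several motifs) or a
#'   directory of such files.
#' @inheritParams read_pfm
#' @return Named list of `lactsnp_pwm` objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4)) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.(jaspar|pfm|txt)$", full.names = TRUE)
  } else path
  motifs <- list()
  for (f in files) {
    lines <- readLines(f, warn = FALSE)
    starts <- grep("^>", lines)
    if (!length(starts)) starts <- 1
    ends <- c(starts[-1] - 1, length(lines))
    for (k in seq_along(starts)) {
      m <- read_pfm(lines[starts[k]:ends[k]], background = background)
      motifs[[m$name]] <- m
    }
  }
  motifs
}

#' @export
print.lactsnp_pwm <- function(x, ...) {
  cat("PWM", x$name, "(", x$length, "bp; score range",
      sprintf("%.3f .. %.3f", x$smin, x$smax), ")\n")
  invisible(x)
}

#' Relative PWM score of a sequence window
#'
#' `(S - Smin) / (Smax - Smin)`, scaled to `[0, 1]` between the worst and
#' best achievable match. Ambiguous bases (`N`) contribute their position's
#' worst-case (minimum) weight.
#'
#' @param window Character string of length equal to the motif width.
#' @param motif A `lactsnp_pwm`.
#' @return Relative score in `[0, 1]`.
#' @export
relative_score <- function(window, motif) {
  b <- strsplit(toupper(window), "")[[1]]
  if (length(b) != motif$length) {
    abort(paste0("window length ", length(b), " != motif length ", motif$length))
  }
  s <- 0
  for (k in seq_along(b)) {
    s <- s + if (b[k] %in% rownames(motif$pwm)) motif$pwm[b[k], k] else min(motif$pwm[, k])
  }
  as.numeric((s - motif$smin) / (motif$smax - motif$smin))
}

#' Read flanking sequences from a FASTA file
#'
#' @param path FASTA path; each record is one flank, named by its SNP.
#' @return Named character vector of uppercase sequences.
#' @export
read_flank_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(seqs)), sub("\\s.*$", "", names(seqs)))
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# best relative score over all windows covering position `offset`, both strands
best_hit <- function(seqstr, offset, motif) {
  L <- motif$length
  n <- nchar(seqstr)
  starts <- seq(max(1, offset - L + 1), min(offset, n - L + 1))
  best <- tibble(score = -Inf, start = NA_integer_, strand = NA_character_)
  for (s in starts) {
    win <- substr(seqstr, s, s + L - 1)
    for (strand in c("+", "-")) {
      sc <- relative_score(if (strand == "+") win else revcomp(win), motif)
      if (sc > best$score) best <- tibble(score = sc, start = s, strand = strand)
    }
  }
  best
}

#' Allele-differential TFBS scan
#'
#' Scans every motif window overlapping a SNP, on both strands, against the
#' reference- and alternate-allele versions of the flanking sequence, and
#' classifies each transcription factor by its best hit relative to the score
#' threshold: `gained` (alt above, ref below), `lost` (ref above, alt below),
#' `retained` (both above), `absent` (both below).
#'
#' @param flank Flanking sequence (string, A/C/G/T) containing the SNP.
#' @param snp_offset 1-based position of the SNP within `flank`.
#' @param ref,alt Reference and alternate alleles (single bases); `flank`
#'   must carry `ref` at `snp_offset`.
#' @param motifs A `lactsnp_pwm` or list of them.
#' @param threshold Relative-score binding threshold (default 0.8).
#' @return Tibble per motif: `tf`, best ref/alt scores with window start and
#'   strand, and `classification`.
#' @export
scan_alleles <- function(flank, snp_offset, ref, alt, motifs, threshold = 0.8) {
  flank <- toupper(flank)
  if (substr(flank, snp_offset, snp_offset) != toupper(ref)) {
    abort(paste0("flank has '", substr(flank, snp_offset, snp_offset),
                 "' at offset ", snp_offset, ", expected ref allele '", ref, "'"))
  }
  if (is(motifs, "lactsnp_pwm")) motifs <- list(motifs)
  alt_seq <- flank
  substr(alt_seq, snp_offset, snp_offset) <- toupper(alt)
  rows <- lapply(motifs, function(m) {
    rb <- best_hit(flank, snp_offset, m)
    ab <- best_hit(alt_seq, snp_offset, m)
    cls <- if (rb$score >= threshold && ab$score >= threshold) "retained"
    else if (rb$score >= threshold) "lost"
    else if (ab$score >= threshold) "gained"
    else "absent"
    tibble(tf = m$name,
           ref_score = rb$score, ref_start = rb$start, ref_strand = rb$strand,
           alt_score = ab$score, alt_start = ab$start, alt_strand = ab$strand,
           classification = cls)
  })
  list_rbind(rows)
}
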