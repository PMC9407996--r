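#' Read a pedigree file
#'
#' Reads a three-column pedigree (`animal,sire,dam`) CSV. Unknown parents may
#' be coded as an empty field, `0`, or `NA`; all three dialects are accepted
#' and normalised to `NA`.
#'
#' @param path Path to a CSV file with header `animal,sire,dam`.
#' @return A tibble with character columns `animal`, `sire`, `dam`.
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(ped))) {
    abort(paste0("pedigree file must have columns animal,sire,dam; found: ",
                 paste(names(ped), collapse = ",")))
  }
  ped |>
    select(all_of(need)) |>
    mutate(across(c("sire", "dam"), \(x) ifelse(is.na(x) | x %in% c("", "0", "NA"), NA_character_, x)))
}

#' Write a pedigree file
#'
#' @param ped Pedigree tibble (`animal`, `sire`, `dam`).
#' @param path Output CSV path; unknown parents written as empty fields.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  readr::write_csv(ped, path, na = "")
  invisible(path)
}

# Normalise a pedigree: character ids, parents appearing only as sire/dam
# added as founder rows, then topological sort (parents before offspring).
# Errors with the offending id if the pedigree contains a cycle.
ped_normalise <- function(ped) {
  ped <- as_tibble(ped) |>
    mutate(animal = as.character(.data$animal),
           sire = as.character(.data$sire),
           dam = as.character(.data$dam))
  if (anyDuplicated(ped$animal)) {
    abort(paste0("duplicate animal id in pedigree: ",
                 ped$animal[duplicated(ped$animal)][1]))
  }
  parents <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$animal)
  if (length(parents)) {
    ped <- bind_rows(tibble(animal = parents, sire = NA_character_, dam = NA_character_), ped)
  }
  idx <- setNames(seq_len(nrow(ped)), ped$animal)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  # Kahn's algorithm
  n <- nrow(ped)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    bad <- ped$animal[setdiff(seq_len(n), ord)][1]
    abort(paste0("pedigree contains a cycle involving animal '", bad, "'"))
  }
  ped <- ped[ord, ]
  idx <- setNames(seq_len(n), ped$animal)
  list(ped = ped,
       sire = ifelse(is.na(ped$sire), 0L, unname(idx[ped$sire])),
       dam  = ifelse(is.na(ped$dam), 0L, unname(idx[ped$dam])))
}

#' Additive (numerator) relationship matrix
#'
#' Builds the pedigree-based additive relationship matrix A by the tabular
#' method: `a_ii = 1 + a(sire,dam)/2` and, for j preceding i,
#' `a_ij = (a(j,sire) + a(j,dam))/2`, with unknown parents contributing 0
#' (treated as unrelated, non-inbred founders).
#'
#' @param ped Pedigree tibble (`animal`, `sire`, `dam`); parents referenced
#'   but not listed are added as founders.
#' @return A dense symmetric numeric matrix with animal ids as dimnames,
#'   ordered so parents precede offspring.
#' @export
build_A <- function(ped) {
  pn <- ped_normalise(ped)
  n <- nrow(pn$ped)
  si <- pn$sire; di <- pn$dam
  A <- matrix(0, n, n, dimnames = list(pn$ped$animal, pn$ped$animal))
  for (i in seq_len(n)) {
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (si[i] > 0L) row <- row + A[si[i], j]
      if (di[i] > 0L) row <- row + A[di[i], j]
      row <- row / 2
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (si[i] > 0L && di[i] > 0L) 0.5 * A[si[i], di[i]] else 0
  }
  A
}

#' Pedigree inbreeding coefficients
#'
#' `F_i = a(sire_i, dam_i) / 2`; founders and animals with an unknown parent
#' have `F = 0`.
#'
#' @inheritParams build_A
#' @return Tibble with columns `animal`, `f`.
#' @export
inbreeding_coefficients <- function(ped) {
  A <- build_A(ped)
  tibble(animal = rownames(A), f = unname(diag(A)) - 1)
}

#' Inverse of the additive relationship matrix
#'
#' Assembles A-inverse directly from the pedigree by Henderson's rules,
#' accounting for inbreeding: the Mendelian-sampling variance of animal i is
#' `d_i = 1/2 - (F_s + F_d)/4` with both parents known, `3/4 - F_p/4` with one
#' parent known, and 1 for founders.
#'
#' @inheritParams build_A
#' @return A sparse symmetric `Matrix` with animal ids as dimnames, in the
#'   same order as [build_A()].
#' @export
build_A_inverse <- function(ped) {
  pn <- ped_normalise(ped)
  n <- nrow(pn$ped)
  si <- pn$sire; di <- pn$dam
  f <- inbreeding_coefficients(pn$ped)$f
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    dm <- if (s > 0L && d > 0L) 0.5 - 0.25 * (f[s] + f[d])
          else if (s > 0L) 0.75 - 0.25 * f[s]
          else if (d > 0L) 0.75 - 0.25 * f[d]
          else 1
    a <- 1 / dm
    add(i, i, a)
    for (p in c(s, d)[c(s, d) > 0L]) {
      add(i, p, -a / 2); add(p, i, -a / 2)
    }
    if (s > 0L && d > 0L) {
      add(s, s, a / 4); add(d, d, a / 4)
      add(s, d, a / 4); add(d, s, a / 4)
    } else if (s > 0L) {
      add(s, s, a / 4)
    } else if (d > 0L) {
      add(d, d, a / 4)
    }
  }
  Ainv <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                       dimnames = list(pn$ped$animal, pn$ped$animal))
  methods::as(Ainv, "symmetricMatrix")
}
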