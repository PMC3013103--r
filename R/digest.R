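#' Digestion parameters
#'
#' Settings for the in-silico digestion that defines the observable-peptide
#' universe: the cleavage rule, missed-cleavage allowance, the instrument's
#' acquisition mass window, and the post-translational modifications searched.
#' A peptide is *observable* when its mass in at least one admissible
#' modification state falls inside `[min_mass, max_mass]`.
#'
#' @param enzyme Cleavage rule identifier; only `"trypsin"` (cleave C-terminal
#'   of K/R except before P) is built in.
#' @param max_missed_cleavages Maximum internal uncut K/R sites per peptide.
#' @param min_mass,max_mass Observable mass window in Da. The defaults cover a
#'   typical MALDI-TOF/TOF acquisition range.
#' @param searched_ptms Tibble with columns `residues` (string of target
#'   letters), `delta_mass` (Da), `max_per_peptide`; or `NULL` for none.
#' @return An object of class `digest_params`.
#' @export
digest_params <- function(enzyme = "trypsin", max_missed_cleavages = 2L,
                          min_mass = 600, max_mass = 4000,
                          searched_ptms = NULL) {
  stopifnot(identical(enzyme, "trypsin"), max_missed_cleavages >= 0,
            min_mass < max_mass)
  if (is.null(searched_ptms)) {
    searched_ptms <- tibble::tibble(residues = character(),
                                    delta_mass = numeric(),
                                    max_per_peptide = integer())
  }
  structure(list(enzyme = enzyme,
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_mass = min_mass, max_mass = max_mass,
                 searched_ptms = searched_ptms),
            class = "digest_params")
}

#' @export
print.digest_params <- function(x, ...) {
  cat("Digestion parameters: ", x$enzyme,
      ", <=", x$max_missed_cleavages, " missed cleavages",
      ", mass window [", x$min_mass, ", ", x$max_mass, "] Da, ",
      nrow(x$searched_ptms), " searched PTM(s)\n", sep = "")
  invisible(x)
}

# 0-based positions after which trypsin cuts: after K/R unless followed by P.
tryptic_cut_sites <- function(sequence) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  if (n < 2) return(integer())
  which(res[-n] %in% c("K", "R") & res[-1] != "P")
}

#' In-silico tryptic digestion of one protein
#'
#' Enumerates all fully tryptic peptides with up to
#' `params$max_missed_cleavages` internal missed sites. The protein N- and
#' C-termini count as valid tryptic boundaries; a protein with no cleavage
#' site yields itself as a single peptide. No mass filtering is applied here
#' (see [build_digest_index()] for observability).
#'
#' @param sequence Protein sequence (single string).
#' @param params A [digest_params()] object.
#' @return A tibble with `peptide`, `start` (1-based), `missed_cleavages`,
#'   `ntt` (always 2: fully tryptic), `neutral_mass` (`NA` for peptides
#'   containing `X`).
#' @examples
#' digest_protein("MKAAAARGGGK", digest_params(max_missed_cleavages = 0))
#' @export
digest_protein <- function(sequence, params = digest_params()) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  cuts <- tryptic_cut_sites(sequence)
  bounds <- c(0L, cuts, nchar(sequence))   # fragment boundaries
  nfrag <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(nfrag)) {
    for (j in i:min(nfrag, i + params$max_missed_cleavages)) {
      rows[[length(rows) + 1L]] <- c(bounds[i] + 1L, bounds[j + 1L], j - i)
    }
  }
  m <- do.call(rbind, rows)
  pep <- substring(sequence, m[, 1], m[, 2])
  mass <- rep(NA_real_, length(pep))
  clean <- !grepl("X", pep, fixed = TRUE)
  if (any(clean)) mass[clean] <- peptide_mass(pep[clean])
  tibble::tibble(peptide = pep, start = as.integer(m[, 1]),
                 missed_cleavages = as.integer(m[, 3]), ntt = 2L,
                 neutral_mass = mass)
}

#' Count tryptic termini of a peptide in its protein context
#'
#' A peptide terminus is tryptic when it coincides with the protein terminus
#' or with a tryptic cleavage site: the N-terminus if the preceding residue is
#' K/R and the peptide does not start with P; the C-terminus if the last
#' residue is K/R (or ends the protein). Fully tryptic peptides score 2,
#' semi-tryptic 1, non-tryptic 0.
#'
#' @param peptide Peptide sequence.
#' @param protein Protein sequence containing it.
#' @param start 1-based start position of the peptide in the protein.
#' @return Integer in `{0, 1, 2}`.
#' @export
count_tryptic_termini <- function(peptide, protein, start) {
  end <- start + nchar(peptide) - 1L
  if (substring(protein, start, end) != peptide) {
    stop("count_tryptic_termini(): peptide is not the protein substring at position ",
         start)
  }
  n_ok <- start == 1L ||
    (substring(protein, start - 1L, start - 1L) %in% c("K", "R") &&
       substring(peptide, 1L, 1L) != "P")
  c_ok <- end == nchar(protein) ||
    substring(peptide, nchar(peptide), nchar(peptide)) %in% c("K", "R")
  as.integer(n_ok) + as.integer(c_ok)
}

# All reachable modified-mass deltas for a peptide under the searched PTMs,
# including 0 (unmodified). Enumeration capped at `cap` simultaneous mods.
ptm_mass_deltas <- function(peptide, searched_ptms, cap = 3L) {
  if (!nrow(searched_ptms)) return(0)
  counts <- integer(nrow(searched_ptms))
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(searched_ptms))) {
    targets <- strsplit(searched_ptms$residues[i], "", fixed = TRUE)[[1]]
    counts[i] <- min(sum(res %in% targets), searched_ptms$max_per_peptide[i])
  }
  grids <- purrr::map(counts, function(k) 0:k)
  combos <- do.call(expand.grid, grids)
  combos <- combos[rowSums(combos) <= cap, , drop = FALSE]
  unique(as.numeric(as.matrix(combos) %*% searched_ptms$delta_mass))
}

#' Build the observable-peptide index of a database
#'
#' Digests every protein and keeps the *observable* peptides: unique tryptic
#' sequences (per protein) whose mass in at least one admissible modification
#' state lies within the acquisition window. The index carries the quantities
#' that drive the protein-level features: `n` per protein (observable-peptide
#' count) and the database total `D`. A sequence shared by two proteins
#' contributes to both proteins' `n` and twice to `D`, because every
#' peptide-spectrum match is attributable to one specific parent protein.
#'
#' @param database Tibble with `accession` and `sequence` (see [read_fasta()]).
#' @param params A [digest_params()] object.
#' @return An object of class `digest_index`: list with `peptides` (tibble of
#'   `accession`, `peptide`, `start`, `length`, `missed_cleavages`,
#'   `neutral_mass`), `n_per_protein` (tibble `accession`, `n`), `total_d`,
#'   and `params`.
#' @export
build_digest_index <- function(database, params = digest_params()) {
  stopifnot(nrow(database) > 0)
  per_protein <- purrr::map2(database$accession, database$sequence,
    function(acc, seq) {
      d <- digest_protein(seq, params)
      # one entry per unique sequence within the protein (first occurrence)
      d <- d[!duplicated(d$peptide), , drop = FALSE]
      d <- d[!is.na(d$neutral_mass), , drop = FALSE]   # X-containing excluded
      if (!nrow(d)) return(NULL)
      deltas <- purrr::map(d$peptide, ptm_mass_deltas,
                           searched_ptms = params$searched_ptms)
      obs <- purrr::map2_lgl(d$neutral_mass, deltas, function(m, dl) {
        any(m + dl >= params$min_mass & m + dl <= params$max_mass)
      })
      d <- d[obs, , drop = FALSE]
      if (!nrow(d)) return(NULL)
      tibble::tibble(accession = acc, peptide = d$peptide, start = d$start,
                     length = nchar(d$peptide),
                     missed_cleavages = d$missed_cleavages,
                     neutral_mass = d$neutral_mass)
    })
  peptides <- dplyr::bind_rows(per_protein)
  if (!nrow(peptides)) {
    peptides <- tibble::tibble(accession = character(), peptide = character(),
                               start = integer(), length = integer(),
                               missed_cleavages = integer(),
                               neutral_mass = numeric())
  }
  n_per_protein <- database |>
    dplyr::distinct(.data$accession) |>
    dplyr::left_join(
      dplyr::count(peptides, .data$accession, name = "n"),
      by = "accession") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  structure(list(peptides = peptides, n_per_protein = n_per_protein,
                 total_d = nrow(peptides), params = params),
            class = "digest_index")
}

#' @export
print.digest_index <- function(x, ...) {
  cat("Observable-peptide index: D =", x$total_d, "peptides over",
      nrow(x$n_per_protein), "protein(s)\n")
  invisible(x)
}

# n (observable-peptide count) for one accession; 0 if the protein is absent.
index_n <- function(index, accession) {
  i <- match(accession, index$n_per_protein$accession)
  ifelse(is.na(i), 0L, index$n_per_protein$n[i])
}
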