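#' Protein Hit Count (PHC) feature
#'
#' Tail probability, in negative log10 space, of the number of
#' peptide-spectrum matches observed for one parent protein under random
#' sampling from the observable-peptide database. With `D` observable
#' peptides database-wide, `n` of them from the protein, and `P` sampled
#' instances in the search result, the hit count is modelled as Poisson with
#' rate `lambda = P * n / D` (the Poisson estimate of the binomial sampling
#' model). The default `"upper"` tail returns `-log10 P(X >= k)`, so a large
#' PHC means more hits than random sampling explains — evidence that the
#' protein is present. The `"lower"` tail (`-log10 P(X <= k)`) preserves the
#' literal "k or fewer" formulation. All arithmetic is in log space, so no
#' underflow occurs even for extreme counts.
#'
#' @param k Observed hit count(s) for the parent protein (vectorised).
#' @param n Observable peptides of that protein.
#' @param d Observable peptides in the whole database.
#' @param p Number of sampled instances in the search result.
#' @param tail `"upper"` (default) or `"lower"`.
#' @return Non-negative numeric vector of `-log10` tail probabilities.
#' @examples
#' phc(k = 5, n = 10, d = 1000, p = 100)  # lambda = 1 -> about 2.44
#' @export
phc <- function(k, n, d, p, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  stopifnot(d > 0, p > 0, all(n >= 0), all(n <= d), all(k >= 0), all(k <= p))
  if (any(n == 0 & k > 0)) {
    stop("phc(): hits observed from a protein with no observable peptides")
  }
  lambda <- p * n / d
  out <- numeric(length(k))
  lk <- pmax(k, rep_len(0, length(out)))
  if (tail == "upper") {
    # P(X >= k) = P(X > k - 1); k = 0 gives probability 1, PHC 0
    lp <- stats::ppois(lk - 1, lambda, lower.tail = FALSE, log.p = TRUE)
  } else {
    lp <- stats::ppois(lk, lambda, lower.tail = TRUE, log.p = TRUE)
  }
  out <- -lp / log(10)
  out[n == 0 & k == 0] <- 0
  out
}

#' Potential Coverage Ratio (PCR) feature
#'
#' Fraction of a protein's residues that belong to observable peptides and
#' are covered by the peptides actually observed in the search result.
#' Both numerator and denominator are residue unions on protein coordinates,
#' so overlapping peptides are never double counted. A matched peptide absent
#' from the observable set (semi-tryptic or out-of-window) is excluded from
#' the numerator with a warning.
#'
#' @param accession Protein accession.
#' @param matched_peptides Character vector of observed peptide sequences for
#'   this protein.
#' @param index A [build_digest_index()] object.
#' @return A single value in `[0, 1]` (0 when the protein has no observable
#'   peptides).
#' @export
pcr <- function(accession, matched_peptides, index) {
  obs <- index$peptides[index$peptides$accession == accession, , drop = FALSE]
  if (!nrow(obs)) return(0)
  len <- max(obs$start + obs$length) - 1L
  denom_cov <- logical(len)
  for (i in seq_len(nrow(obs))) {
    denom_cov[obs$start[i]:(obs$start[i] + obs$length[i] - 1L)] <- TRUE
  }
  matched_peptides <- unique(matched_peptides)
  unknown <- setdiff(matched_peptides, obs$peptide)
  if (length(unknown)) {
    warning("pcr(): ", length(unknown), " matched peptide(s) of ", accession,
            " not in the observable set (semi-tryptic or out-of-window); excluded")
    matched_peptides <- setdiff(matched_peptides, unknown)
  }
  num_cov <- logical(len)
  hit <- obs[obs$peptide %in% matched_peptides, , drop = FALSE]
  for (i in seq_len(nrow(hit))) {
    num_cov[hit$start[i]:(hit$start[i] + hit$length[i] - 1L)] <- TRUE
  }
  sum(num_cov) / sum(denom_cov)
}

#' PTM percentage feature
#'
#' Percentage of a peptide's modifiable residues (residues targeted by any
#' searched PTM) that the search engine actually modified to achieve the
#' match. A match that needs most of its possible modifications is suspect.
#' Returns 0 when the peptide has no modifiable residue.
#'
#' @param peptide Peptide sequence.
#' @param modifications Tibble with `position` (1-based residue index) and
#'   `delta_mass`, as carried by the PSM table.
#' @param searched_ptms Tibble of searched PTMs (see [digest_params()]).
#' @return A value in `[0, 100]`.
#' @export
ptm_percentage <- function(peptide, modifications, searched_ptms) {
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  targets <- unique(unlist(strsplit(searched_ptms$residues, "", fixed = TRUE)))
  modifiable <- which(res %in% targets)
  n_mod <- 0L
  if (!is.null(modifications) && nrow(modifications)) {
    pos <- unique(modifications$position)
    if (any(pos < 1 | pos > length(res))) {
      stop("ptm_percentage(): modification position outside the peptide")
    }
    if (any(!pos %in% modifiable)) {
      stop("ptm_percentage(): modification on residue(s) not targeted by any ",
           "searched PTM (inconsistent search output)")
    }
    n_mod <- length(pos)
  }
  if (!length(modifiable)) return(0)
  100 * n_mod / length(modifiable)
}

#' Spectral-quality features of one spectrum
#'
#' Summary statistics of the peak intensities: their sum, mean, population
#' standard deviation, the peak count, and the distribution of intensities in
#' five 20%-bins after normalising by the spectrum's maximum intensity
#' (bins `[0,0.2), [0.2,0.4), [0.4,0.6), [0.6,0.8), [0.8,1]`; fractions sum
#' to 1).
#'
#' @param peaks Tibble with `mz` and `intensity` (at least one peak).
#' @return A one-row tibble: `summed_intensity`, `intensity_mean`,
#'   `intensity_std`, `peak_count`, `intensity_bin1` .. `intensity_bin5`.
#' @export
spectral_quality_features <- function(peaks) {
  ints <- peaks$intensity
  if (!length(ints)) stop("spectral_quality_features(): empty peak list")
  rel <- ints / max(ints)
  bin <- pmin(findInterval(rel, c(0, 0.2, 0.4, 0.6, 0.8)), 5L)
  frac <- tabulate(bin, nbins = 5L) / length(ints)
  tibble::tibble(
    summed_intensity = sum(ints),
    intensity_mean = mean(ints),
    intensity_std = sqrt(mean((ints - mean(ints))^2)),
    peak_count = length(ints),
    intensity_bin1 = frac[1], intensity_bin2 = frac[2],
    intensity_bin3 = frac[3], intensity_bin4 = frac[4],
    intensity_bin5 = frac[5]
  )
}

# Mobile-proton class of a precursor: 1 = mobile (charge exceeds all basic
# residues), 3 = non-mobile (charge covered by arginines alone), 2 = partial.
mobile_proton_factor <- function(peptide, charge) {
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  n_r <- sum(res == "R")
  n_rkh <- sum(res %in% c("R", "K", "H"))
  dplyr::case_when(charge > n_rkh ~ 1L, charge <= n_r ~ 3L, TRUE ~ 2L)
}

c_terminal_code <- function(peptide) {
  last <- substring(peptide, nchar(peptide), nchar(peptide))
  dplyr::case_when(last == "R" ~ 1L, last == "K" ~ 2L, TRUE ~ 3L)
}

#' Assemble the full feature matrix for a set of PSM candidates
#'
#' Joins candidates with their spectra and the observable-peptide index and
#' computes every feature group:
#'
#' * Sequest pass-throughs: `xcorr`, `delta_mh` (precursor MH+ minus the
#'   candidate's theoretical MH+), `deltacn`, `sp`, `sprank`, `ion_fraction`;
#' * Published: `ntt`, `peptide_length`, `summed_intensity`, `mpf`,
#'   `c_terminal_code`, `mass_window_peptides` (observable database peptides
#'   within `mass_window` Da of the candidate peptide's neutral mass),
#'   `proline_count`, `arginine_count`;
#' * Novel: `intensity_mean`, `intensity_std`, `peak_count`,
#'   `intensity_bin1..5`, `phc`, `pcr`, `ptm_percentage`.
#'
#' The protein hit count `k` behind PHC counts all PSM instances of the
#' protein across all ranks of the dataset being featurised, and `P` is the
#' total instance count, so PHC and PCR are global dataset features: all
#' candidates of one protein share them, and all candidates of one spectrum
#' share the spectral-quality columns. Output rows are sorted by
#' `(spectrum_id, rank)` and the result is reproducible bit-exactly.
#'
#' @param candidates PSM tibble as from [read_psm_table()].
#' @param spectra Spectrum tibble as from [read_mgf()].
#' @param database Protein tibble as from [read_fasta()].
#' @param index A [build_digest_index()] of `database`.
#' @param mass_window Half-width (Da) for the mass-window peptide count.
#' @param phc_tail Tail convention passed to [phc()].
#' @param hit_count_ranks `"all"` (default) counts every instance of a
#'   protein toward `k`; `"rank1"` counts rank-1 instances only.
#' @return A tibble with `spectrum_id`, `rank`, the feature columns in the
#'   documented order, and `label`.
#' @export
build_feature_matrix <- function(candidates, spectra, database, index,
                                 mass_window = 3.0,
                                 phc_tail = c("upper", "lower"),
                                 hit_count_ranks = c("all", "rank1")) {
  phc_tail <- match.arg(phc_tail)
  hit_count_ranks <- match.arg(hit_count_ranks)
  missing_spec <- setdiff(unique(candidates$spectrum_id), spectra$spectrum_id)
  if (length(missing_spec)) {
    stop("build_feature_matrix(): unresolvable spectrum_id(s): ",
         paste(utils::head(missing_spec, 5), collapse = ", "))
  }
  missing_prot <- setdiff(unique(candidates$protein), database$accession)
  if (length(missing_prot)) {
    stop("build_feature_matrix(): unresolvable protein accession(s): ",
         paste(utils::head(missing_prot, 5), collapse = ", "))
  }
  if (any(candidates$total_ions <= 0)) {
    stop("build_feature_matrix(): total_ions must be positive")
  }
  required <- c("xcorr", "deltacn", "sp", "sprank", "matched_ions", "total_ions")
  bad <- !stats::complete.cases(candidates[required])
  if (any(bad)) {
    stop("build_feature_matrix(): ", sum(bad), " candidate(s) with missing ",
         "Sequest fields; instances are rejected, never imputed")
  }

  cand <- dplyr::arrange(candidates, .data$spectrum_id, .data$rank)

  # per-spectrum quality features and precursor context
  spec_feats <- spectra |>
    dplyr::mutate(quality = purrr::map(.data$peaks, spectral_quality_features)) |>
    tidyr::unnest("quality") |>
    dplyr::select(-"peaks")

  # per-protein global features
  hits <- if (hit_count_ranks == "rank1") dplyr::filter(cand, .data$rank == 1L) else cand
  k_tbl <- dplyr::count(hits, protein = .data$protein, name = "k")
  p_total <- nrow(cand)
  ptms <- index$params$searched_ptms
  prot_tbl <- k_tbl |>
    dplyr::mutate(
      n_obs = index_n(index, .data$protein),
      phc = phc(.data$k, .data$n_obs, d = index$total_d, p = p_total,
                tail = phc_tail),
      pcr = purrr::map_dbl(.data$protein, function(acc) {
        suppressWarnings(
          pcr(acc, unique(hits$peptide[hits$protein == acc]), index))
      })
    )

  seqs <- stats::setNames(database$sequence, database$accession)
  mass_sorted <- sort(index$peptides$neutral_mass)

  theo_mass <- peptide_mass(cand$peptide,
                            purrr::map(cand$modifications, "delta_mass"))
  ntt <- purrr::pmap_int(list(cand$peptide, cand$protein), function(pep, acc) {
    prot <- seqs[[acc]]
    st <- as.integer(regexpr(pep, prot, fixed = TRUE))
    if (st < 1L) return(0L)   # peptide not in protein verbatim: no tryptic termini
    count_tryptic_termini(pep, prot, st)
  })

  out <- cand |>
    dplyr::left_join(spec_feats, by = "spectrum_id") |>
    dplyr::left_join(prot_tbl, by = "protein") |>
    dplyr::mutate(
      theo_mh = theo_mass + PROTON_MASS,
      delta_mh = .data$precursor_mh - .data$theo_mh,
      ion_fraction = .data$matched_ions / .data$total_ions,
      ntt = ntt,
      peptide_length = nchar(.data$peptide),
      mpf = purrr::map2_int(.data$peptide, .data$charge, mobile_proton_factor),
      c_terminal_code = c_terminal_code(.data$peptide),
      mass_window_peptides = {
        lo <- findInterval(theo_mass - mass_window - 1e-9, mass_sorted)
        hi <- findInterval(theo_mass + mass_window, mass_sorted)
        as.integer(hi - lo)
      },
      proline_count = stringr::str_count(.data$peptide, stringr::fixed("P")),
      arginine_count = stringr::str_count(.data$peptide, stringr::fixed("R")),
      ptm_percentage = purrr::map2_dbl(.data$peptide, .data$modifications,
                                       ptm_percentage, searched_ptms = ptms)
    )

  dplyr::select(out, "spectrum_id", "rank", dplyr::all_of(psm_feature_names()),
                "label")
}

#' Documented feature order of the feature matrix
#'
#' @return Character vector of the feature column names in their fixed order.
#' @export
psm_feature_names <- function() {
  c("xcorr", "delta_mh", "deltacn", "sp", "sprank", "ion_fraction",
    "ntt", "peptide_length", "summed_intensity", "mpf", "c_terminal_code",
    "mass_window_peptides", "proline_count", "arginine_count",
    "intensity_mean", "intensity_std", "peak_count",
    paste0("intensity_bin", 1:5), "phc", "pcr", "ptm_percentage")
}

#' Write a feature matrix as TSV
#'
#' Header row follows the documented feature order; the label column is last.
#'
#' @param features Tibble from [build_feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  readr::write_tsv(features, path, na = "", progress = FALSE)
  invisible(path)
}
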