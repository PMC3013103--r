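#' Simulation configuration
#'
#' Settings for the synthetic Sequest-like search generator. The defaults
#' emulate the structure of a MALDI reference search: each spectrum carries
#' its 10 top-ranked candidates, roughly 5% of instances are true matches
#' (about half of the spectra contain a true candidate, and 34% of true
#' candidates are not ranked first), and true hits cluster on a small set of
#' "present" proteins — the clustering that gives the protein-level features
#' their signal.
#'
#' @param n_proteins Number of database proteins.
#' @param protein_length_range Integer min/max protein length (residues).
#' @param present_fraction Fraction of proteins present in the sample.
#' @param n_spectra Number of simulated spectra.
#' @param candidates_per_spectrum Ranked candidates per spectrum (at most 10).
#' @param true_spectrum_fraction Fraction of spectra containing a true
#'   candidate. With 10 candidates per spectrum, 0.47 gives about 4.7%
#'   positive instances.
#' @param rank1_fraction Probability that a true candidate is ranked first
#'   (0.66: a third of true matches sit below rank 1).
#' @param cluster_hits If `TRUE` (default) true spectra are drawn from the
#'   present-protein subset with per-protein loads, concentrating true hits;
#'   if `FALSE` true peptides come from proteins drawn uniformly, which
#'   removes the protein-level clustering signal.
#' @param xcorr_true,xcorr_decoy Mean/sd pairs of the Normal XCorr
#'   distributions (truncated at 0) for true and decoy candidates.
#' @param ion_fraction_shape_true,ion_fraction_shape_decoy Beta shape pairs
#'   for the matched-ion fraction.
#' @param delta_mh_sd_true Spread (Da) of the precursor mass error for true
#'   candidates. Decoys inherit the mass mismatch between the precursor and
#'   their own peptide mass within the `decoy_mass_window`.
#' @param decoy_mass_window Half-width (Da) of the neighbourhood from which
#'   decoy peptides are drawn around the precursor mass — the search engine's
#'   precursor tolerance: every reported candidate, true or not, lies within
#'   it. When a neighbourhood holds too few peptides, the nearest peptides by
#'   mass are used instead.
#' @param mean_peaks Mean peak count per spectrum (Poisson).
#' @param seed Integer seed; identical configurations and seeds reproduce
#'   the dataset bit-exactly.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 120L,
                       protein_length_range = c(200L, 400L),
                       present_fraction = 0.25,
                       n_spectra = 1000L,
                       candidates_per_spectrum = 10L,
                       true_spectrum_fraction = 0.47,
                       rank1_fraction = 0.66,
                       cluster_hits = TRUE,
                       xcorr_true = c(3.0, 0.7),
                       xcorr_decoy = c(1.5, 0.5),
                       ion_fraction_shape_true = c(8, 12),
                       ion_fraction_shape_decoy = c(6, 14),
                       delta_mh_sd_true = 0.05,
                       decoy_mass_window = 2.0,
                       mean_peaks = 40,
                       seed = 1L) {
  stopifnot(n_proteins >= 2, candidates_per_spectrum <= 10L,
            present_fraction > 0, present_fraction < 1,
            true_spectrum_fraction >= 0, true_spectrum_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# Random protein sequence with K/R frequency tuned so tryptic fragments
# average 8-15 residues.
random_protein <- function(len) {
  other <- setdiff(AA_ALPHABET, c("K", "R", "P"))
  prob <- c(rep(0.855 / length(other), length(other)), 0.045, 0.045, 0.055)
  paste(sample(c(other, "K", "R", "P"), len, replace = TRUE, prob = prob),
        collapse = "")
}

#' Simulate a protein database
#'
#' Random sequences over the 20-letter alphabet; deterministic given the
#' configuration seed.
#'
#' @param config A [sim_config()].
#' @return A tibble in the [read_fasta()] shape.
#' @export
simulate_database <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    lens <- sample(config$protein_length_range[1]:config$protein_length_range[2],
                   config$n_proteins, replace = TRUE)
    tibble::tibble(
      accession = sprintf("SIMPROT%04d", seq_len(config$n_proteins)),
      description = "synthetic protein",
      sequence = vapply(lens, random_protein, character(1))
    )
  })
}

rtruncnorm0 <- function(n, mean, sd) pmax(stats::rnorm(n, mean, sd), 0.01)

#' Simulate a Sequest-like search result
#'
#' Selects a "present" protein subset, then emits one spectrum at a time:
#' a true spectrum carries one correct candidate — an observable tryptic
#' peptide of a present protein, with scores drawn from the true-class
#' distributions and placed at rank 1 with probability `rank1_fraction` —
#' plus decoy candidates (random database peptides near the precursor mass,
#' scores from the decoy distributions); a non-true spectrum carries decoys
#' only. Ranks follow descending XCorr, the rank-1 deltaCn is 0 and lower
#' ranks get the relative XCorr gap to rank 1, and every spectrum has at
#' most one true candidate. Peak lists are Poisson-count peaks with
#' lognormal intensities, present only to exercise the spectral-quality
#' features.
#'
#' @param database Tibble from [simulate_database()] (or any protein table).
#' @param config A [sim_config()].
#' @param params [digest_params()] used to pick candidate peptides.
#' @return A list with `spectra` (as [read_mgf()]), `candidates` (as
#'   [read_psm_table()], with labels), and `present` (tibble of present
#'   accessions).
#' @export
simulate_search <- function(database, config, params = digest_params()) {
  stopifnot(inherits(config, "sim_config"))
  index <- build_digest_index(database, params)
  pool <- index$peptides
  if (!nrow(pool)) stop("simulate_search(): no observable peptides in database")
  withr::with_seed(config$seed + 1L, {
    n_present <- max(1L, round(config$present_fraction * nrow(database)))
    present <- sample(database$accession, n_present)
    present_pool <- pool[pool$accession %in% present, , drop = FALSE]
    if (!nrow(present_pool)) stop("simulate_search(): present subset is empty")

    n_spec <- config$n_spectra
    m <- config$candidates_per_spectrum
    is_true <- stats::runif(n_spec) < config$true_spectrum_fraction

    # per-protein load weights concentrate true hits on few proteins
    load <- stats::rexp(n_present) + 0.2
    prot_weight <- load[match(present_pool$accession, present)]

    spectra <- vector("list", n_spec)
    cands <- vector("list", n_spec)
    for (si in seq_len(n_spec)) {
      sid <- sprintf("SIMSPEC%05d", si)
      if (is_true[si]) {
        row <- if (config$cluster_hits) {
          present_pool[sample.int(nrow(present_pool), 1, prob = prot_weight), ]
        } else {
          pool[sample.int(nrow(pool), 1), ]
        }
        true_mass <- row$neutral_mass
      } else {
        row <- NULL
        true_mass <- pool$neutral_mass[sample.int(nrow(pool), 1)]
      }
      precursor_mh <- true_mass + PROTON_MASS +
        stats::rnorm(1, 0, config$delta_mh_sd_true)

      n_decoy <- m - as.integer(is_true[si])
      # decoys: database peptides near the precursor mass when possible
      dist <- abs(pool$neutral_mass - true_mass)
      near <- which(dist < config$decoy_mass_window)
      if (length(near) < n_decoy) {
        near <- order(dist)[seq_len(min(nrow(pool), 3L * n_decoy))]
      }
      pick <- near[sample.int(length(near), n_decoy,
                              replace = length(near) < n_decoy)]
      decoys <- pool[pick, , drop = FALSE]

      xc_d <- rtruncnorm0(n_decoy, config$xcorr_decoy[1], config$xcorr_decoy[2])
      ion_d <- stats::rbeta(n_decoy, config$ion_fraction_shape_decoy[1],
                            config$ion_fraction_shape_decoy[2])
      tab <- tibble::tibble(
        peptide = decoys$peptide,
        protein = decoys$accession,
        xcorr = xc_d,
        ion_fraction = ion_d,
        label = 0L
      )
      if (is_true[si]) {
        xc_t <- rtruncnorm0(1, config$xcorr_true[1], config$xcorr_true[2])
        if (stats::runif(1) < config$rank1_fraction) {
          xc_t <- max(xc_t, max(tab$xcorr) + abs(stats::rnorm(1, 0.3, 0.2)))
        } else if (xc_t > max(tab$xcorr)) {
          # push the true hit below at least one decoy
          xc_t <- stats::runif(1, min(tab$xcorr), max(tab$xcorr))
        }
        tab <- dplyr::bind_rows(tab, tibble::tibble(
          peptide = row$peptide, protein = row$accession, xcorr = xc_t,
          ion_fraction = stats::rbeta(1, config$ion_fraction_shape_true[1],
                                      config$ion_fraction_shape_true[2]),
          label = 1L
        ))
      }
      tab <- dplyr::arrange(tab, dplyr::desc(.data$xcorr))
      tab$rank <- seq_len(nrow(tab))
      tab$deltacn <- (tab$xcorr[1] - tab$xcorr) / tab$xcorr[1]
      total_ions <- 2L * (nchar(tab$peptide) - 1L)
      tab$spectrum_id <- sid
      tab$modifications <- rep(list(tibble::tibble(position = integer(),
                                                   delta_mass = numeric())),
                               nrow(tab))
      tab$sp <- 100 * tab$xcorr + stats::rnorm(nrow(tab), 0, 30)
      tab$sprank <- as.integer(rank(-tab$sp, ties.method = "first"))
      tab$matched_ions <- pmax(1L, as.integer(round(tab$ion_fraction * total_ions)))
      tab$total_ions <- total_ions

      n_peaks <- max(3L, stats::rpois(1, config$mean_peaks))
      spectra[[si]] <- tibble::tibble(
        spectrum_id = sid,
        precursor_mh = precursor_mh,
        charge = 1L,
        peaks = list(tibble::tibble(
          mz = sort(stats::runif(n_peaks, 100, max(300, precursor_mh))),
          intensity = stats::rlnorm(n_peaks, 4, 1)
        ))
      )
      cands[[si]] <- tab
    }
    candidates <- dplyr::bind_rows(cands)
    candidates <- candidates[, c("spectrum_id", "rank", "peptide",
                                 "modifications", "protein", "xcorr",
                                 "deltacn", "sp", "sprank", "matched_ions",
                                 "total_ions", "label")]
    list(spectra = dplyr::bind_rows(spectra),
         candidates = candidates,
         present = tibble::tibble(accession = sort(present)),
         index = index)
  })
}

#' Simulate a complete labelled dataset
#'
#' Convenience wrapper: database, observable-peptide index, spectra and
#' ranked candidates in one call.
#'
#' @param config A [sim_config()].
#' @param params [digest_params()] for the observable index.
#' @return A list with `database`, `index`, `spectra`, `candidates`,
#'   `present`.
#' @export
simulate_dataset <- function(config = sim_config(), params = digest_params()) {
  database <- simulate_database(config)
  res <- simulate_search(database, config, params)
  list(database = database, index = res$index, spectra = res$spectra,
       candidates = res$candidates, present = res$present)
}
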