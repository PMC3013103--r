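test_that("PHC reproduces the Poisson tail arithmetic", {
  # k = 0: P(X >= 0) = 1, so the upper-tail PHC is exactly 0
  expect_identical(phc(0, 10, 1000, 100), 0)
  # lambda = 1: P(X >= 5) = 1 - e^-1 (1 + 1 + 1/2 + 1/6 + 1/24)
  exact <- -log10(1 - exp(-1) * (1 + 1 + 1/2 + 1/6 + 1/24))
  expect_equal(phc(5, 10, 1000, 100), exact, tolerance = 1e-10)
  expect_gt(phc(6, 10, 1000, 100), phc(5, 10, 1000, 100))
})

test_that("PHC handles degenerate inputs and stays finite in deep tails", {
  expect_error(phc(3, 0, 1000, 100), "no observable peptides")
  expect_identical(phc(0, 0, 1000, 100), 0)
  # deep in the tail: exact log-space evaluation, no underflow to Inf
  deep <- phc(500, 10, 100000, 1000)
  expect_true(is.finite(deep))
  expect_gt(deep, 100)
})

test_that("lower-tail PHC matches the literal k-or-fewer binomial sum closely", {
  withr::with_seed(21, {
    for (i in 1:200) {
      d <- sample(20000:200000, 1)
      n <- sample(1:floor(0.01 * d), 1)
      p_inst <- max(1L, round(stats::runif(1, 0.05, 10) * d / n))
      lam <- p_inst * n / d
      k <- sample(0:min(p_inst, ceiling(lam + 6 * sqrt(lam) + 3)), 1)
      got <- phc(k, n, d, p_inst, tail = "lower")
      oracle <- -stats::pbinom(k, p_inst, n / d, log.p = TRUE) / log(10)
      expect_lt(abs(got - oracle), 0.05)
    }
  })
})

test_that("upper-tail PHC matches the exact binomial tail in the sparse regime", {
  # real databases are sparse: per-protein n is tens against D ~ 1e5-1e6
  withr::with_seed(22, {
    for (i in 1:200) {
      d <- sample(100000:1000000, 1)
      n <- sample(1:floor(0.001 * d), 1)
      p_inst <- max(1L, round(stats::runif(1, 0.05, 10) * d / n))
      lam <- p_inst * n / d
      k <- sample(0:min(p_inst, ceiling(lam + 6 * sqrt(lam) + 3)), 1)
      got <- phc(k, n, d, p_inst)
      oracle <- -stats::pbinom(k - 1, p_inst, n / d, lower.tail = FALSE,
                               log.p = TRUE) / log(10)
      expect_lt(abs(got - oracle), 0.05)
    }
  })
})

test_that("PHC is monotone in k and in the sampling rate", {
  ks <- 0:20
  vals <- phc(ks, 50, 10000, 2000)
  expect_true(all(diff(vals) > 0))
  # more observable peptides at fixed k: the same count is less surprising
  expect_gt(phc(10, 20, 10000, 2000), phc(10, 40, 10000, 2000))
})

test_that("PCR is the residue-union coverage of observable peptides", {
  # two disjoint observable peptides, lengths 10 and 30; only the 10-mer seen
  seq10 <- paste0(strrep("A", 9), "K")
  seq30 <- paste0(strrep("L", 29), "R")
  db <- tibble::tibble(accession = "P", description = "",
                       sequence = paste0(seq10, seq30))
  idx <- build_digest_index(db, digest_params(max_missed_cleavages = 0,
                                              min_mass = 0, max_mass = 1e6))
  expect_equal(pcr("P", seq10, idx), 0.25)
  expect_equal(pcr("P", c(seq10, seq30), idx), 1.0)
  expect_equal(pcr("P", character(), idx), 0.0)
})

test_that("PCR warns on and excludes peptides outside the observable set", {
  db <- toy_database()
  idx <- build_digest_index(db, digest_params(max_missed_cleavages = 0,
                                              min_mass = 0, max_mass = 1e6))
  expect_warning(v <- pcr("P1", c("AAAAR", "AAAA"), idx), "not in the observable")
  expect_equal(v, suppressWarnings(pcr("P1", "AAAAR", idx)))
})

test_that("PCR never decreases as matched peptides are added", {
  db <- toy_database()
  idx <- build_digest_index(db, digest_params(min_mass = 0, max_mass = 1e6))
  obs <- idx$peptides$peptide[idx$peptides$accession == "P1"]
  withr::with_seed(31, {
    for (i in 1:10) {
      sub1 <- sample(obs, sample(length(obs) - 1L, 1))
      extra <- sample(setdiff(obs, sub1), 1)
      expect_lte(pcr("P1", sub1, idx), pcr("P1", c(sub1, extra), idx))
    }
  })
})

test_that("PTM percentage counts modified over modifiable residues", {
  ptms <- tibble::tibble(residues = c("STY", "M"), delta_mass = c(79.96633, 15.9949),
                         max_per_peptide = c(3L, 2L))
  mod_at <- function(pos) tibble::tibble(position = pos,
                                         delta_mass = rep(79.96633, length(pos)))
  # SSTM A: 4 modifiable residues (S,S,T,M), 1 modified -> 25%
  expect_equal(ptm_percentage("SSTMA", mod_at(1L), ptms), 25.0)
  none <- tibble::tibble(position = integer(), delta_mass = numeric())
  expect_equal(ptm_percentage("AAGGK", none, ptms), 0.0)
  expect_equal(ptm_percentage("STY", mod_at(1:3), ptms), 100.0)
  expect_error(ptm_percentage("GAK", mod_at(2L), ptms), "not targeted")
})

test_that("spectral-quality features follow the 20%-bin definition", {
  one <- tibble::tibble(mz = 100, intensity = 10)
  f <- spectral_quality_features(one)
  expect_equal(f$summed_intensity, 10)
  expect_equal(f$intensity_mean, 10)
  expect_equal(f$intensity_std, 0)
  expect_equal(unlist(f[paste0("intensity_bin", 1:5)], use.names = FALSE),
               c(0, 0, 0, 0, 1))

  const <- tibble::tibble(mz = 1:4, intensity = rep(1, 4))
  fc <- spectral_quality_features(const)
  expect_equal(fc$intensity_std, 0)
  expect_equal(fc$intensity_bin5, 1)

  three <- tibble::tibble(mz = 1:3, intensity = c(10, 5, 1))
  ft <- spectral_quality_features(three)
  expect_equal(unlist(ft[paste0("intensity_bin", 1:5)], use.names = FALSE),
               c(1, 0, 1, 0, 1) / 3)
  expect_equal(sum(unlist(ft[paste0("intensity_bin", 1:5)])), 1)
  expect_error(spectral_quality_features(tibble::tibble(mz = numeric(),
                                                        intensity = numeric())),
               "empty")
})

test_that("the feature matrix carries the documented columns and sharing structure", {
  ds <- small_sim()
  fm <- build_feature_matrix(ds$candidates, ds$spectra, ds$database, ds$index)
  expect_equal(names(fm), c("spectrum_id", "rank", psm_feature_names(), "label"))
  expect_false(anyNA(fm[psm_feature_names()]))
  expect_true(all(fm$ion_fraction >= 0 & fm$ion_fraction <= 1))
  expect_true(all(fm$c_terminal_code %in% 1:3))
  expect_true(all(fm$ntt %in% 0:2))

  # per-spectrum features identical across a spectrum's candidates
  per_spec <- fm |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("intensity"),
                                   dplyr::n_distinct),
                     .by = "spectrum_id")
  expect_true(all(per_spec[-1] == 1L))
  # per-protein features identical across a protein's candidates
  key <- dplyr::left_join(fm, ds$candidates[c("spectrum_id", "rank", "protein")],
                          by = c("spectrum_id", "rank"))
  per_prot <- key |>
    dplyr::summarise(n_phc = dplyr::n_distinct(.data$phc),
                     n_pcr = dplyr::n_distinct(.data$pcr), .by = "protein")
  expect_true(all(per_prot$n_phc == 1L))
  expect_true(all(per_prot$n_pcr == 1L))
})

test_that("feature construction is permutation invariant and reproducible", {
  ds <- small_sim()
  cands <- ds$candidates[1:200, ]
  fm1 <- build_feature_matrix(cands, ds$spectra, ds$database, ds$index)
  shuffled <- cands[withr::with_seed(8, sample.int(nrow(cands))), ]
  fm2 <- build_feature_matrix(shuffled, ds$spectra, ds$database, ds$index)
  expect_identical(fm1, fm2)
})

test_that("published features encode the C-terminus and count residues", {
  ds <- small_sim()
  fm <- build_feature_matrix(ds$candidates, ds$spectra, ds$database, ds$index)
  pep <- ds$candidates$peptide[order(ds$candidates$spectrum_id,
                                     ds$candidates$rank)]
  last <- substring(pep, nchar(pep), nchar(pep))
  expect_equal(fm$c_terminal_code,
               ifelse(last == "R", 1L, ifelse(last == "K", 2L, 3L)))
  expect_equal(fm$proline_count, stringr::str_count(pep, "P"))
  expect_equal(fm$arginine_count, stringr::str_count(pep, "R"))
  expect_equal(fm$peptide_length, nchar(pep))
})

test_that("mass-window peptide counts match a linear scan on a toy index", {
  idx <- structure(list(
    peptides = tibble::tibble(accession = "P", peptide = letters[1:5],
                              start = 1L, length = 5L,
                              neutral_mass = c(800, 801, 802, 900, 1000)),
    n_per_protein = tibble::tibble(accession = "P", n = 5L),
    total_d = 5L,
    params = digest_params()), class = "digest_index")
  masses <- idx$peptides$neutral_mass
  expect_equal(sum(abs(masses - 801) <= 1.5), 3L)   # 800, 801, 802
  # the same counting logic drives the feature matrix column
  ds <- small_sim()
  fm <- build_feature_matrix(ds$candidates[1:50, ], ds$spectra, ds$database,
                             ds$index, mass_window = 3.0)
  cand <- dplyr::arrange(ds$candidates[1:50, ], spectrum_id, rank)
  theo <- peptide_mass(cand$peptide)
  all_m <- ds$index$peptides$neutral_mass
  oracle <- vapply(theo, function(m) sum(abs(all_m - m) <= 3.0), integer(1))
  expect_equal(fm$mass_window_peptides, oracle)
})

test_that("sequest features pass scores through and derive the mass error", {
  ds <- small_sim()
  fm <- build_feature_matrix(ds$candidates, ds$spectra, ds$database, ds$index)
  cand <- dplyr::arrange(ds$candidates, spectrum_id, rank)
  expect_equal(fm$xcorr, cand$xcorr)
  expect_equal(fm$deltacn, cand$deltacn)
  expect_equal(fm$ion_fraction, cand$matched_ions / cand$total_ions)
  sp_mh <- ds$spectra$precursor_mh[match(cand$spectrum_id,
                                         ds$spectra$spectrum_id)]
  expect_equal(fm$delta_mh,
               sp_mh - (peptide_mass(cand$peptide) + 1.00728))
})

test_that("candidates with unresolvable references or missing scores are rejected", {
  ds <- small_sim()
  bad <- ds$candidates[1:10, ]
  bad$spectrum_id[1] <- "NOPE"
  expect_error(build_feature_matrix(bad, ds$spectra, ds$database, ds$index),
               "spectrum_id")
  bad2 <- ds$candidates[ds$candidates$spectrum_id == ds$candidates$spectrum_id[1], ]
  bad2$protein[1] <- "GHOST"
  expect_error(build_feature_matrix(bad2, ds$spectra, ds$database, ds$index),
               "accession")
  bad3 <- ds$candidates[ds$candidates$spectrum_id == ds$candidates$spectrum_id[1], ]
  bad3$xcorr[2] <- NA_real_
  expect_error(build_feature_matrix(bad3, ds$spectra, ds$database, ds$index),
               "never imputed")
})
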