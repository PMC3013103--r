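#' Spectrum-level train/test split
#'
#' Splits a candidate table by *spectrum*, never by instance, so a spectrum's
#' ranked candidates always land on the same side — otherwise shared
#' per-spectrum features would leak between training and test data.
#'
#' @param candidates PSM candidate tibble.
#' @param fraction Fraction of spectra assigned to the training side.
#' @param seed Integer seed for the assignment.
#' @return A list with `train` and `test` candidate tibbles.
#' @export
split_spectra <- function(candidates, fraction = 0.5, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  ids <- unique(candidates$spectrum_id)
  train_ids <- withr::with_seed(seed,
    sample(ids, size = max(1L, round(fraction * length(ids)))))
  list(train = dplyr::filter(candidates, .data$spectrum_id %in% train_ids),
       test = dplyr::filter(candidates, !.data$spectrum_id %in% train_ids))
}

#' Run the full validation pipeline on one dataset
#'
#' Features are computed per dataset side (protein hit counts and coverage
#' are global dataset features, so each side is featurised against its own
#' search result). The tree is trained on half of the training spectra, the
#' calibration is fitted on the held-out other half (training-set margins
#' are optimistically large), and metrics are reported on the test side.
#'
#' @param dataset A [simulate_dataset()]-shaped list (`database`, `index`,
#'   `spectra`, `candidates`), or any equivalent assembled from real files.
#' @param iterations,epsilon ADTree training settings.
#' @param split_fraction Fraction of spectra used for the training side.
#' @param calibration_fraction Fraction of training spectra held out for
#'   calibration.
#' @param feature_subset Optional character vector restricting the feature
#'   columns used by the tree (default: all features).
#' @param seed Integer seed for the splits.
#' @return A list with `model` (calibrated `adtree`), `evaluation` (from
#'   [evaluate_psm()] on the test side), `scored_test` (test candidates with
#'   `margin` and `probability`), and `proteins` (test-side
#'   [protein_rollup()]).
#' @export
run_pipeline <- function(dataset, iterations = 9L, epsilon = 1.0,
                         split_fraction = 0.5, calibration_fraction = 0.5,
                         feature_subset = NULL, seed = 1L) {
  halves <- split_spectra(dataset$candidates, split_fraction, seed = seed)
  inner <- split_spectra(halves$train, 1 - calibration_fraction,
                         seed = seed + 1L)

  featurise <- function(cands) {
    build_feature_matrix(cands,
                         dplyr::filter(dataset$spectra,
                                       .data$spectrum_id %in% cands$spectrum_id),
                         dataset$database, dataset$index)
  }
  train_feat <- featurise(inner$train)
  calib_feat <- featurise(inner$test)
  test_feat <- featurise(halves$test)

  if (!is.null(feature_subset)) {
    keep <- c("spectrum_id", "rank", feature_subset, "label")
    train_feat <- train_feat[keep]
    calib_feat <- calib_feat[keep]
    test_feat <- test_feat[keep]
  }

  model <- adtree(train_feat, iterations = iterations, epsilon = epsilon)
  model$calibration <- fit_calibration(predict_margin(model, calib_feat),
                                       calib_feat$label)

  scored <- test_feat |>
    dplyr::mutate(margin = predict_margin(model, test_feat),
                  probability = calibrate(model$calibration, .data$margin)) |>
    dplyr::left_join(
      dplyr::select(halves$test, "spectrum_id", "rank", "peptide", "protein"),
      by = c("spectrum_id", "rank"))

  list(model = model,
       evaluation = evaluate_psm(scored, score = "margin"),
       scored_test = scored,
       proteins = protein_rollup(scored))
}
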