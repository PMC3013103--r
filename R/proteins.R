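#' Protein presence probability from peptide probabilities
#'
#' A conservative estimate of the probability that a protein is present —
#' i.e. that at least one of its matched peptides is a correct
#' identification:
#' `P = 1 - prod_i (1 - max_j p_ij)`,
#' where `i` runs over the protein's distinct peptides and `j` over the
#' repeated identifications of peptide `i`. Repeated identifications of the
#' same peptide are not independent samplings of the protein, so only the
#' best probability per peptide enters the product. The product is evaluated
#' in `log1p` space for numerical stability with many peptides.
#'
#' @param peptide_probs Named list (or list) of numeric probability vectors,
#'   one element per distinct peptide.
#' @return Probability in `[0, 1]`.
#' @examples
#' protein_probability(list(A = 0.5, B = 0.5))        # 0.75
#' protein_probability(list(A = c(0.4, 0.7)))         # 0.7 (max, not noisy-OR)
#' @export
protein_probability <- function(peptide_probs) {
  if (!length(peptide_probs)) {
    stop("protein_probability(): a protein with no matched peptide has no score")
  }
  best <- vapply(peptide_probs, function(p) {
    p <- as.numeric(p)
    stopifnot(all(p >= 0), all(p <= 1))
    max(p)
  }, numeric(1))
  -expm1(sum(log1p(-best)))
}

#' Roll calibrated PSM probabilities up to protein presence probabilities
#'
#' Groups scored candidates by protein accession, then by distinct peptide,
#' takes the best probability within each peptide, and combines peptides by
#' the presence-probability product. A peptide sequence matched under two
#' accessions contributes to both proteins. By default the distinct-peptide
#' key is the bare amino-acid sequence, so modified and unmodified forms of
#' one sequence count as the same peptide and take the max;
#' `distinct_key = "sequence_mods"` separates modification states.
#'
#' @param scored Tibble with at least `protein`, `peptide`, `probability`
#'   (and `spectrum_id`, `rank`, `modifications` when available).
#' @param distinct_key `"sequence"` (default) or `"sequence_mods"`.
#' @return A tibble sorted by descending probability (ties by accession):
#'   `accession`, `probability`, `n_distinct_peptides`, `n_psms`,
#'   `top_peptide`, `top_probability`.
#' @export
protein_rollup <- function(scored, distinct_key = c("sequence", "sequence_mods")) {
  distinct_key <- match.arg(distinct_key)
  stopifnot(all(c("protein", "peptide", "probability") %in% names(scored)))
  stopifnot(all(scored$probability >= 0 & scored$probability <= 1))
  key <- if (distinct_key == "sequence_mods" && "modifications" %in% names(scored)) {
    paste(scored$peptide, format_modifications(scored$modifications), sep = "|")
  } else {
    scored$peptide
  }
  scored |>
    dplyr::mutate(.pep_key = key) |>
    dplyr::summarise(best = max(.data$probability),
                     peptide = .data$peptide[which.max(.data$probability)][1],
                     n_psms = dplyr::n(),
                     .by = c("protein", ".pep_key")) |>
    dplyr::summarise(
      probability = -expm1(sum(log1p(-.data$best))),
      n_distinct_peptides = dplyr::n(),
      n_psms = sum(.data$n_psms),
      top_peptide = .data$peptide[which.max(.data$best)][1],
      top_probability = max(.data$best),
      .by = "protein") |>
    dplyr::rename(accession = "protein") |>
    dplyr::arrange(dplyr::desc(.data$probability), .data$accession)
}

#' Write the protein report TSV
#'
#' @param results Tibble from [protein_rollup()].
#' @param path Output path.
#' @param header Optional `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_protein_report <- function(results, path, header = NULL) {
  if (!is.null(header)) {
    readr::write_lines(paste0("# ", header), path)
    readr::write_tsv(results, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_tsv(results, path, progress = FALSE)
  }
  invisible(path)
}
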