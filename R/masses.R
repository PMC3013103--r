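# Monoisotopic residue masses (Da) for the 20 canonical amino acids.
# Residue mass = amino acid minus water; peptide neutral mass adds one water.
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

WATER_MASS <- 18.01056
PROTON_MASS <- 1.00728

AA_ALPHABET <- names(RESIDUE_MASS)

#' Monoisotopic neutral mass of a peptide
#'
#' Sums the monoisotopic residue masses, adds one water (18.01056 Da) for the
#' peptide termini, and adds any modification delta masses.
#'
#' @param sequence Character vector of peptide sequences over the 20-letter
#'   amino-acid alphabet.
#' @param modifications Numeric vector of modification delta masses (Da) to
#'   add, or a list of such vectors (one per sequence).
#' @return Numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' peptide_mass("AG")                 # 146.06913
#' peptide_mass("STY", c(79.96633))   # phosphorylated
#' @export
peptide_mass <- function(sequence, modifications = NULL) {
  stopifnot(is.character(sequence))
  if (any(!nzchar(sequence))) {
    stop("peptide_mass(): empty peptide sequence has no defined mass")
  }
  mass <- vapply(sequence, function(s) {
    res <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- setdiff(res, AA_ALPHABET)
    if (length(bad)) {
      stop("peptide_mass(): unknown residue(s) ", paste(unique(bad), collapse = ", "),
           " in peptide ", s)
    }
    sum(RESIDUE_MASS[res]) + WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
  if (!is.null(modifications)) {
    if (is.list(modifications)) {
      stopifnot(length(modifications) == length(sequence))
      mass <- mass + vapply(modifications, function(m) sum(as.numeric(m)), numeric(1))
    } else {
      mass <- mass + sum(as.numeric(modifications))
    }
  }
  mass
}
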