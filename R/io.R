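#' Read a FASTA protein database
#'
#' Parses a FASTA file into a protein table. The accession is the first
#' whitespace-delimited token of the header line; the remainder of the header
#' becomes the description. Sequences are uppercased and may wrap over any
#' number of lines. The letter `X` (unknown residue) is accepted; any other
#' character outside the 20-letter alphabet is an error naming the record.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `accession`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("read_fasta(): no records in ", path)
  if (!startsWith(lines[[1]], ">")) {
    stop("read_fasta(): not FASTA-formatted (first non-blank line is not '>'): ", path)
  }
  # validate the alphabet up front so offending records are named precisely
  is_header <- startsWith(lines, ">")
  rec_of <- cumsum(is_header)
  rec_names <- sub("\\s.*$", "", sub("^>", "", lines[is_header]))
  seq_ok <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "X]*$"),
                  toupper(gsub("\\s", "", lines[!is_header])))
  if (any(!seq_ok)) {
    stop("read_fasta(): sequence characters outside the accepted alphabet in record(s): ",
         paste(unique(rec_names[rec_of[!is_header][!seq_ok]]), collapse = ", "))
  }
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop("read_fasta(): no records in ", path)
  headers <- names(aa)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  sequence <- unname(toupper(as.character(aa)))
  if (anyDuplicated(accession)) {
    stop("read_fasta(): duplicate accession(s): ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "))
  }
  if (any(!nzchar(sequence))) {
    stop("read_fasta(): empty sequence in record(s): ",
         paste(accession[!nzchar(sequence)], collapse = ", "))
  }
  tibble::tibble(accession = accession, description = description,
                 sequence = sequence)
}

#' Write a protein table as FASTA
#'
#' @param proteins Tibble with `accession`, `description`, `sequence`.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60) {
  header <- ifelse(nzchar(proteins$description),
                   paste(proteins$accession, proteins$description),
                   proteins$accession)
  chunks <- purrr::map2(header, proteins$sequence, function(h, s) {
    starts <- seq(1, nchar(s), by = width)
    c(paste0(">", h), substring(s, starts, pmin(starts + width - 1, nchar(s))))
  })
  readr::write_lines(unlist(chunks), path)
  invisible(path)
}

#' Read an MGF peak-list file
#'
#' Parses Mascot Generic Format `BEGIN IONS`/`END IONS` blocks. `TITLE` is
#' used as the spectrum identifier, `PEPMASS` as the precursor m/z, and
#' `CHARGE` (defaulting to 1+, the MALDI convention) converts it to the
#' singly-protonated parent mass: MH+ = z * (m/z) - (z - 1) * 1.00728.
#' Peaks are sorted ascending by m/z.
#'
#' @param path Path to an MGF file.
#' @return A tibble with columns `spectrum_id`, `precursor_mh`, `charge`, and
#'   a `peaks` list-column of tibbles with `mz` and `intensity`.
#' @export
read_mgf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) != length(end) || any(end < begin)) {
    stop("read_mgf(): unbalanced BEGIN IONS/END IONS blocks in ", path)
  }
  spectra <- purrr::map2(begin, end, function(b, e) {
    block <- lines[(b + 1):(e - 1)]
    block <- block[nzchar(trimws(block))]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- toupper(sub("=.*$", "", block[kv]))
    vals <- sub("^[^=]*=", "", block[kv])
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else paste0("index=", b)
    if (!"PEPMASS" %in% keys) {
      stop("read_mgf(): block starting at line ", b, " has no PEPMASS")
    }
    pepmass <- as.numeric(strsplit(vals[match("PEPMASS", keys)], "\\s+")[[1]][1])
    charge <- 1L
    if ("CHARGE" %in% keys) {
      charge <- as.integer(sub("\\+$", "", vals[match("CHARGE", keys)]))
    }
    peak_lines <- block[!kv]
    fields <- strsplit(trimws(peak_lines), "\\s+")
    mz <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1)))
    intensity <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
    if (length(peak_lines) && (anyNA(mz) || anyNA(intensity))) {
      off <- which(is.na(mz) | is.na(intensity))[1]
      stop("read_mgf(): non-numeric peak line at file line ",
           b + match(peak_lines[off], block))
    }
    ord <- order(mz)
    tibble::tibble(
      spectrum_id = title,
      precursor_mh = charge * pepmass - (charge - 1) * PROTON_MASS,
      charge = charge,
      peaks = list(tibble::tibble(mz = mz[ord], intensity = intensity[ord]))
    )
  })
  dplyr::bind_rows(spectra)
}

#' Write spectra as MGF
#'
#' @param spectra Tibble as returned by [read_mgf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- purrr::pmap(spectra, function(spectrum_id, precursor_mh, charge, peaks, ...) {
    pepmass <- (precursor_mh + (charge - 1) * PROTON_MASS) / charge
    c("BEGIN IONS",
      paste0("TITLE=", spectrum_id),
      paste0("PEPMASS=", format(pepmass, digits = 12)),
      paste0("CHARGE=", charge, "+"),
      paste(format(peaks$mz, digits = 12, trim = TRUE),
            format(peaks$intensity, digits = 12, trim = TRUE)),
      "END IONS", "")
  })
  readr::write_lines(unlist(blocks), path)
  invisible(path)
}

psm_table_columns <- c("spectrum_id", "rank", "peptide", "modifications",
                       "protein", "xcorr", "deltacn", "sp", "sprank",
                       "matched_ions", "total_ions", "label")

parse_modifications <- function(x) {
  purrr::map(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(tibble::tibble(position = integer(), delta_mass = numeric()))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    tibble::tibble(
      position = as.integer(vapply(parts, `[`, "", 1)),
      delta_mass = as.numeric(vapply(parts, `[`, "", 2))
    )
  })
}

format_modifications <- function(mods) {
  vapply(mods, function(m) {
    if (!nrow(m)) return("")
    paste(paste0(m$position, ":", vapply(m$delta_mass, as.character, "")),
          collapse = ";")
  }, "")
}

#' Read a Sequest-style PSM table
#'
#' Reads the documented tab-separated dialect: one row per ranked candidate,
#' with columns `spectrum_id`, `rank`, `peptide`, `modifications`
#' (semicolon-separated `position:deltaMass` pairs), `protein`, `xcorr`,
#' `deltacn`, `sp`, `sprank`, `matched_ions`, `total_ions`, `label` (may be
#' empty). All ten top-ranked candidates per spectrum may be present; ranks
#' within a spectrum must be 1..m without gaps, and ranks above 10 are
#' rejected. By Sequest convention the rank-1 candidate has deltaCn 0; a
#' violation is a warning, not an error.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the dialect's columns, `modifications` parsed into a
#'   list-column of tibbles with `position` and `delta_mass`.
#' @export
read_psm_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    spectrum_id = readr::col_character(),
    rank = readr::col_integer(),
    peptide = readr::col_character(),
    modifications = readr::col_character(),
    protein = readr::col_character(),
    xcorr = readr::col_double(),
    deltacn = readr::col_double(),
    sp = readr::col_double(),
    sprank = readr::col_integer(),
    matched_ions = readr::col_integer(),
    total_ions = readr::col_integer(),
    label = readr::col_integer()
  ), progress = FALSE)
  missing_cols <- setdiff(psm_table_columns, names(raw))
  if (length(missing_cols)) {
    stop("read_psm_table(): missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(raw[c("spectrum_id", "rank")])) {
    dup <- raw[duplicated(raw[c("spectrum_id", "rank")]), ]
    stop("read_psm_table(): duplicate (spectrum_id, rank): ",
         paste(unique(dup$spectrum_id), collapse = ", "))
  }
  if (any(raw$rank > 10L)) {
    stop("read_psm_table(): rank above 10 found; the table carries at most ",
         "the 10 top-ranked tentative peptide matches per spectrum")
  }
  if (any(raw$rank < 1L)) stop("read_psm_table(): rank below 1")
  gap <- raw |>
    dplyr::summarise(ok = all(sort(.data$rank) == seq_along(.data$rank)),
                     .by = "spectrum_id") |>
    dplyr::filter(!.data$ok)
  if (nrow(gap)) {
    stop("read_psm_table(): ranks not contiguous from 1 for spectrum(s): ",
         paste(gap$spectrum_id, collapse = ", "))
  }
  bad_dcn <- raw$rank == 1L & !is.na(raw$deltacn) & raw$deltacn != 0
  if (any(bad_dcn)) {
    warning("read_psm_table(): ", sum(bad_dcn),
            " rank-1 candidate(s) with nonzero deltaCn (Sequest convention is 0)")
  }
  raw$modifications <- parse_modifications(raw$modifications)
  raw
}

#' Write a PSM table in the documented TSV dialect
#'
#' Inverse of [read_psm_table()]: field values round-trip exactly.
#'
#' @param psms Tibble of PSM candidates.
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed comment lines to
#'   place before the column header.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path, header = NULL) {
  out <- psms[intersect(psm_table_columns, names(psms))]
  out$modifications <- format_modifications(out$modifications)
  if (!is.null(header)) {
    readr::write_lines(paste0("# ", header), path)
    readr::write_tsv(out, path, append = TRUE, col_names = TRUE, na = "",
                     progress = FALSE)
  } else {
    readr::write_tsv(out, path, na = "", progress = FALSE)
  }
  invisible(path)
}

#' Read search hits from a pepXML file (tolerant convenience reader)
#'
#' Extracts `search_hit` elements with their `xcorr`, `deltacn`, `sp`,
#' `sprank` search scores and ion counts into the same shape as
#' [read_psm_table()]. Requires the xml2 package.
#'
#' @param path Path to a pepXML file.
#' @return A tibble in the PSM-table shape (label all `NA`).
#' @export
read_pepxml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("read_pepxml() requires the xml2 package")
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  queries <- xml2::xml_find_all(doc, ".//spectrum_query")
  rows <- purrr::map(queries, function(q) {
    sid <- xml2::xml_attr(q, "spectrum")
    hits <- xml2::xml_find_all(q, ".//search_hit")
    if (!length(hits)) return(NULL)
    score_of <- function(h, name) {
      node <- xml2::xml_find_first(h, sprintf(".//search_score[@name='%s']", name))
      as.numeric(xml2::xml_attr(node, "value"))
    }
    tibble::tibble(
      spectrum_id = sid,
      rank = as.integer(xml2::xml_attr(hits, "hit_rank")),
      peptide = xml2::xml_attr(hits, "peptide"),
      modifications = list(tibble::tibble(position = integer(),
                                          delta_mass = numeric())),
      protein = xml2::xml_attr(hits, "protein"),
      xcorr = vapply(hits, score_of, numeric(1), name = "xcorr"),
      deltacn = vapply(hits, score_of, numeric(1), name = "deltacn"),
      sp = vapply(hits, score_of, numeric(1), name = "sp"),
      sprank = as.integer(vapply(hits, score_of, numeric(1), name = "sprank")),
      matched_ions = as.integer(xml2::xml_attr(hits, "num_matched_ions")),
      total_ions = as.integer(xml2::xml_attr(hits, "tot_num_ions")),
      label = NA_integer_
    )
  })
  dplyr::bind_rows(rows)
}
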