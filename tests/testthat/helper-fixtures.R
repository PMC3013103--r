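# Shared fixtures, all generated in code.

write_temp_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

toy_database <- function() {
  tibble::tibble(
    accession = c("P1", "P2"),
    description = c("first toy protein", "second toy protein"),
    sequence = c("MKAAAARGGGK", "AAAAKPRLLLK")
  )
}

# Elemental monoisotopic masses: an oracle for peptide masses that is
# independent of the package's residue-mass table.
elemental_peptide_mass <- function(sequence) {
  elem <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
            O = 15.9949146221, S = 31.97207069)
  # residue formulas (amino acid minus water): C, H, N, O, S counts
  f <- list(
    G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0), Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0), M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0)
  )
  res <- strsplit(sequence, "")[[1]]
  counts <- Reduce(`+`, f[res])
  unname(sum(counts * elem[c("C", "H", "N", "O", "S")]) +
           2 * elem[["H"]] + elem[["O"]])
}

# Brute-force digestion oracle: every substring whose termini are tryptic
# boundaries and whose internal missed-cleavage count is admissible.
brute_force_digest <- function(sequence, max_missed = 2L) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cut_after <- function(p) p >= 1 && p < n && res[p] %in% c("K", "R") && res[p + 1] != "P"
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      n_ok <- i == 1 || cut_after(i - 1)
      c_ok <- j == n || cut_after(j)
      if (!n_ok || !c_ok) next
      internal <- if (j > i) sum(vapply(i:(j - 1), cut_after, logical(1))) else 0L
      if (internal > max_missed) next
      out[[length(out) + 1L]] <- data.frame(peptide = paste(res[i:j], collapse = ""),
                                            start = i, missed_cleavages = internal)
    }
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$missed_cleavages), , drop = FALSE]
}

random_aa_sequence <- function(len, letters = c("A", "G", "K", "R", "P", "L", "S", "E")) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# Pairwise rank-sum AUC oracle (half credit for ties), brute force.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Random ADTree models for the path-enumeration oracle.
random_adtree_model <- function(n_rules, n_features, seed) {
  withr::with_seed(seed, {
    rules <- tibble::tibble(
      id = seq_len(n_rules),
      precondition_node = vapply(seq_len(n_rules), function(r) {
        sample(0:(2L * (r - 1L)), 1)
      }, integer(1)),
      feature = paste0("f", sample.int(n_features, n_rules, replace = TRUE)),
      threshold = round(stats::runif(n_rules, -2, 2), 3),
      left_value = round(stats::rnorm(n_rules), 3),
      right_value = round(stats::rnorm(n_rules), 3)
    )
    structure(list(root_value = round(stats::rnorm(1), 3), rules = rules,
                   feature_names = paste0("f", seq_len(n_features)),
                   meta = list(iterations = n_rules, epsilon = 1, seed = seed)),
              class = "adtree")
  })
}

# Independent margin oracle: recursive walk over the rule graph, structurally
# unlike the iterative reached-mask logic of predict_margin().
oracle_margin <- function(model, x) {
  rules <- model$rules
  children <- split(seq_len(nrow(rules)), rules$precondition_node)
  walk <- function(node_id) {
    total <- 0
    for (r in children[[as.character(node_id)]]) {
      if (x[[rules$feature[r]]] <= rules$threshold[r]) {
        total <- total + rules$left_value[r] + walk(2L * r - 1L)
      } else {
        total <- total + rules$right_value[r] + walk(2L * r)
      }
    }
    total
  }
  model$root_value + walk(0L)
}

# Small simulated dataset shared across tests (computed once per test run).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- psmval::simulate_dataset(
        psmval::sim_config(n_proteins = 60L, n_spectra = 200L, seed = 99L))
    }
    cache
  }
})
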