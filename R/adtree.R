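#' Train an Alternating Decision Tree
#'
#' Boosted additive rule model: the classifier is a conjunction of base rules
#' that each contribute real-valued evidence, and an instance's *margin* is
#' the sum of the prediction values on every path it reaches — not a single
#' root-to-leaf path. Training follows the boosting rule search:
#'
#' 1. instance weights start uniform; the root prediction value is the prior
#'    log-odds `0.5 * ln(W+ / W-)` and instances are reweighted by it;
#' 2. each iteration scans every (existing prediction node `c`, feature,
#'    threshold) triple — thresholds are midpoints between consecutive
#'    distinct feature values observed under `c` — and picks the minimiser of
#'    `Z = 2 * (sqrt(W+(c & s) W-(c & s)) + sqrt(W+(c & !s) W-(c & !s))) + W(!c)`;
#' 3. the winning splitter gets smoothed prediction values
#'    `0.5 * ln((W+ + eps) / (W- + eps))` on each branch and weights are
#'    updated by `w <- w * exp(-y * r(x))`.
#'
#' Ties in `Z` break deterministically: earliest precondition node, then
#' lowest feature index, then lowest threshold. Every iteration adds one
#' splitter and two prediction nodes, so `iterations = 9` yields at most 19
#' prediction nodes — small enough to read as a tree.
#'
#' @param data Data frame whose columns are numeric features plus a label
#'   column in `{0, 1}` (at least one instance of each class).
#' @param label Name of the label column.
#' @param iterations Number of boosting iterations (base rules). 0 gives the
#'   root-only prior classifier.
#' @param epsilon Smoothing constant inside the prediction-value logs.
#' @param class_weighted If `TRUE`, initial positive weights are scaled so
#'   both classes carry equal total weight (for heavily skewed data).
#' @param exclude Character vector of non-feature columns to ignore (defaults
#'   to the instance keys of [build_feature_matrix()]).
#' @return An object of class `adtree`: list with `root_value`, `rules`
#'   (tibble: `id`, `precondition_node`, `feature`, `threshold`,
#'   `left_value`, `right_value`), `feature_names`, and `meta`.
#' @export
adtree <- function(data, label = "label", iterations = 9L, epsilon = 1.0,
                   class_weighted = FALSE,
                   exclude = c("spectrum_id", "rank")) {
  stopifnot(label %in% names(data), iterations >= 0)
  feature_names <- setdiff(names(data), c(label, exclude))
  x <- as.matrix(data[feature_names])
  storage.mode(x) <- "double"
  y01 <- data[[label]]
  if (anyNA(y01) || !all(y01 %in% c(0, 1))) {
    stop("adtree(): labels must be 0/1 with no missing values")
  }
  if (length(unique(y01)) < 2) {
    stop("adtree(): both classes must be present in the training data")
  }
  y <- ifelse(y01 == 1, 1, -1)
  n <- length(y)

  w <- rep(1, n)
  if (class_weighted) {
    w[y > 0] <- sum(y < 0) / sum(y > 0)
  }
  root_value <- 0.5 * log(sum(w[y > 0]) / sum(w[y < 0]))
  w <- w * exp(-y * root_value)

  # prediction-node membership masks; node 0 is the root (all instances)
  node_mask <- list(rep(TRUE, n))
  node_ids <- 0L
  rules <- vector("list", iterations)

  for (iter in seq_len(iterations)) {
    wp <- w * (y > 0)
    wm <- w * (y < 0)
    w_total <- sum(w)
    best <- NULL
    for (ni in seq_along(node_mask)) {
      mask <- node_mask[[ni]]
      if (!any(mask)) next
      w_outside <- w_total - sum(w[mask])
      for (fi in seq_along(feature_names)) {
        cand <- best_split_for_feature(x[mask, fi], wp[mask], wm[mask],
                                       w_outside)
        if (is.null(cand)) next
        if (is.null(best) || cand$z < best$z - 1e-12) {
          best <- c(cand, node = ni, feature = fi)
        }
      }
    }
    if (is.null(best)) {
      rules <- rules[seq_len(iter - 1L)]
      break
    }
    mask <- node_mask[[best$node]]
    s <- mask & (x[, best$feature] <= best$threshold)
    ns <- mask & !s
    a_left <- 0.5 * log((sum(w[s & y > 0]) + epsilon) /
                          (sum(w[s & y < 0]) + epsilon))
    a_right <- 0.5 * log((sum(w[ns & y > 0]) + epsilon) /
                           (sum(w[ns & y < 0]) + epsilon))
    w[s] <- w[s] * exp(-y[s] * a_left)
    w[ns] <- w[ns] * exp(-y[ns] * a_right)
    rules[[iter]] <- tibble::tibble(
      id = iter,
      precondition_node = node_ids[best$node],
      feature = feature_names[best$feature],
      threshold = best$threshold,
      left_value = a_left,
      right_value = a_right
    )
    node_mask <- c(node_mask, list(s), list(ns))
    node_ids <- c(node_ids, 2L * iter - 1L, 2L * iter)
  }

  structure(list(
    root_value = root_value,
    rules = dplyr::bind_rows(rules),
    feature_names = feature_names,
    meta = list(iterations = as.integer(iterations), epsilon = epsilon,
                class_weighted = class_weighted, n_train = n)
  ), class = "adtree")
}

# Vectorised best split of one feature under one precondition.
# xs/wps/wms are restricted to the precondition's instances.
best_split_for_feature <- function(xs, wps, wms, w_outside) {
  ord <- order(xs)
  xs <- xs[ord]
  cp <- cumsum(wps[ord])
  cm <- cumsum(wms[ord])
  m <- length(xs)
  bnd <- which(xs[-m] != xs[-1])   # boundaries between distinct values
  if (!length(bnd)) return(NULL)
  wp_tot <- cp[m]
  wm_tot <- cm[m]
  z <- 2 * (sqrt(cp[bnd] * cm[bnd]) +
              sqrt((wp_tot - cp[bnd]) * (wm_tot - cm[bnd]))) + w_outside
  i <- which.min(z)   # lowest threshold wins ties (first minimum)
  list(z = z[i], threshold = (xs[bnd[i]] + xs[bnd[i] + 1]) / 2)
}

#' Margin score of instances under an ADTree
#'
#' The margin is `root_value` plus, for every rule whose precondition node
#' the instance reaches, the left value if `x[feature] <= threshold` and the
#' right value otherwise. An instance that goes right at a rule never
#' accumulates values from rules nested under that rule's left prediction
#' node.
#'
#' @param model An [adtree()] model.
#' @param newdata Data frame containing the model's feature columns.
#' @return Numeric vector of margin scores.
#' @export
predict_margin <- function(model, newdata) {
  missing_f <- setdiff(model$feature_names, names(newdata))
  if (length(missing_f)) {
    stop("predict_margin(): newdata lacks feature(s): ",
         paste(missing_f, collapse = ", "))
  }
  x <- as.matrix(newdata[model$feature_names])
  storage.mode(x) <- "double"
  n <- nrow(x)
  margin <- rep(model$root_value, n)
  rules <- model$rules
  if (is.null(rules) || !nrow(rules)) return(margin)
  # reached[, j] = does each instance reach prediction node with id j-1
  reached <- matrix(FALSE, n, 2L * nrow(rules) + 1L)
  reached[, 1L] <- TRUE
  for (r in seq_len(nrow(rules))) {
    pre <- reached[, rules$precondition_node[r] + 1L]
    go_left <- x[, rules$feature[r]] <= rules$threshold[r]
    left <- pre & go_left
    right <- pre & !go_left
    margin <- margin + ifelse(left, rules$left_value[r],
                              ifelse(right, rules$right_value[r], 0))
    reached[, 2L * r] <- left        # node id 2r - 1
    reached[, 2L * r + 1L] <- right  # node id 2r
  }
  unname(margin)
}

#' Classify instances with an ADTree
#'
#' An instance is classified positive exactly when its margin is greater
#' than zero (a margin of exactly zero is negative).
#'
#' @inheritParams predict_margin
#' @return Integer vector in `{0, 1}`.
#' @export
adtree_classify <- function(model, newdata) {
  as.integer(predict_margin(model, newdata) > 0)
}

#' Predict method for ADTree models
#'
#' @param object An `adtree` model.
#' @param newdata Data frame of instances.
#' @param type `"margin"` (additive score), `"class"` (0/1 at margin > 0),
#'   or `"probability"` (requires a calibration fitted with
#'   [fit_calibration()] attached as `object$calibration`).
#' @param ... Unused.
#' @return Numeric margins, 0/1 classes, or probabilities.
#' @export
predict.adtree <- function(object, newdata, type = c("margin", "class", "probability"),
                           ...) {
  type <- match.arg(type)
  m <- predict_margin(object, newdata)
  switch(type,
         margin = m,
         class = as.integer(m > 0),
         probability = {
           if (is.null(object$calibration)) {
             stop("predict.adtree(): no calibration attached to the model")
           }
           calibrate(object$calibration, m)
         })
}

#' @export
print.adtree <- function(x, ...) {
  cat("Alternating decision tree: root value ",
      format(x$root_value, digits = 4), ", ", nrow(x$rules),
      " base rule(s), ", 2L * nrow(x$rules) + 1L, " prediction node(s)\n",
      sep = "")
  invisible(x)
}

#' Render an ADTree as text, DOT, or JSON
#'
#' The text and DOT renderings follow the conventional drawing: elliptical
#' prediction nodes, rectangular splitter nodes, and the rule's discovery
#' index in parentheses after the feature name (discovery order is a rough
#' guide to rule importance). JSON serialisation is lossless and round-trips
#' through [read_adtree()].
#'
#' @param model An [adtree()] model.
#' @param format `"text"`, `"dot"`, or `"json"`.
#' @return A character scalar with the rendering.
#' @export
export_tree <- function(model, format = c("text", "dot", "json")) {
  format <- match.arg(format)
  rules <- model$rules
  if (format == "json") {
    obj <- list(
      root_value = model$root_value,
      feature_names = model$feature_names,
      rules = if (nrow(rules)) {
        purrr::pmap(rules, function(id, precondition_node, feature, threshold,
                                    left_value, right_value) {
          list(id = id, precondition_node = precondition_node,
               feature = feature, threshold = threshold,
               left_value = left_value, right_value = right_value)
        })
      } else list(),
      meta = model$meta
    )
    if (!is.null(model$calibration)) {
      obj$calibration <- list(slope = model$calibration$slope,
                              intercept = model$calibration$intercept)
    }
    # digits = I(17): IEEE doubles round-trip bit-exactly through the JSON
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                            null = "null"))
  }
  if (format == "dot") {
    lines <- c("digraph adtree {",
               sprintf("  p0 [shape=ellipse, label=\"%+.3f\"];",
                       model$root_value))
    for (r in seq_len(nrow(rules))) {
      lines <- c(lines,
        sprintf("  s%d [shape=box, label=\"%s (%d)\\n<= %.4g\"];",
                r, rules$feature[r], rules$id[r], rules$threshold[r]),
        sprintf("  p%d [shape=ellipse, label=\"%+.3f\"];",
                2L * r - 1L, rules$left_value[r]),
        sprintf("  p%d [shape=ellipse, label=\"%+.3f\"];",
                2L * r, rules$right_value[r]),
        sprintf("  p%d -> s%d [style=dashed];", rules$precondition_node[r], r),
        sprintf("  s%d -> p%d [label=\"y\"];", r, 2L * r - 1L),
        sprintf("  s%d -> p%d [label=\"n\"];", r, 2L * r))
    }
    return(paste(c(lines, "}"), collapse = "\n"))
  }
  # text: indented by nesting under prediction nodes
  lines <- sprintf("[root] %+.4f", model$root_value)
  depth_of <- c(`0` = 0L)
  for (r in seq_len(nrow(rules))) {
    d <- depth_of[[as.character(rules$precondition_node[r])]] + 1L
    pad <- strrep("  ", d)
    lines <- c(lines,
      sprintf("%s%s (%d) <= %.6g ? %+.4f : %+.4f  [under node %d]",
              pad, rules$feature[r], rules$id[r], rules$threshold[r],
              rules$left_value[r], rules$right_value[r],
              rules$precondition_node[r]))
    depth_of[[as.character(2L * r - 1L)]] <- d
    depth_of[[as.character(2L * r)]] <- d
  }
  paste(lines, collapse = "\n")
}

#' Write / read an ADTree model as JSON
#'
#' @param model An [adtree()] model.
#' @param path File path.
#' @return `write_adtree()` returns `path` invisibly; `read_adtree()` returns
#'   the reconstructed `adtree` model (with any stored calibration).
#' @export
write_adtree <- function(model, path) {
  readr::write_lines(export_tree(model, "json"), path)
  invisible(path)
}

#' @rdname write_adtree
#' @export
read_adtree <- function(path) {
  obj <- jsonlite::fromJSON(readr::read_lines(path), simplifyVector = TRUE)
  rules <- if (length(obj$rules)) {
    tibble::as_tibble(obj$rules)
  } else {
    tibble::tibble(id = integer(), precondition_node = integer(),
                   feature = character(), threshold = numeric(),
                   left_value = numeric(), right_value = numeric())
  }
  model <- structure(list(
    root_value = obj$root_value,
    rules = rules,
    feature_names = obj$feature_names,
    meta = obj$meta
  ), class = "adtree")
  if (!is.null(obj$calibration)) {
    model$calibration <- new_psm_calibration(obj$calibration$slope,
                                             obj$calibration$intercept)
  }
  model
}

#' @export
tidy.adtree <- function(x, ...) {
  x$rules
}

#' @export
glance.adtree <- function(x, ...) {
  tibble::tibble(
    root_value = x$root_value,
    n_rules = nrow(x$rules),
    n_prediction_nodes = 2L * nrow(x$rules) + 1L,
    iterations = x$meta$iterations,
    epsilon = x$meta$epsilon,
    n_train = x$meta$n_train %||% NA_integer_
  )
}
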