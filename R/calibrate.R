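new_psm_calibration <- function(slope, intercept, converged = TRUE) {
  structure(list(slope = slope, intercept = intercept, converged = converged),
            class = "psm_calibration")
}

#' Logistic calibration of margin scores
#'
#' Fits the sigmoid `p(+ | m) = 1 / (1 + exp(-(A m + B)))` to margin scores
#' by maximum Bernoulli likelihood, giving a strictly monotone one-to-one
#' mapping from margin to probability (so ranking metrics such as AUC are
#' unchanged by calibration). Fit the calibration on held-out data, not on
#' the instances the tree was trained on, whose margins are optimistically
#' large.
#'
#' @param margins Numeric vector of finite margin scores.
#' @param labels 0/1 vector of the same length, both classes present.
#' @param method `"mle"` (plain maximum likelihood on 0/1 targets) or
#'   `"platt"` (Platt's smoothed targets `(N+ + 1)/(N+ + 2)` and
#'   `1/(N- + 2)`, which bound the fit away from 0/1 under separation).
#' @param max_iterations Cap on the IRLS iteration count.
#' @return A `psm_calibration` object with `slope` (A) and `intercept` (B).
#' @export
fit_calibration <- function(margins, labels, method = c("mle", "platt"),
                            max_iterations = 10000L) {
  method <- match.arg(method)
  stopifnot(length(margins) == length(labels))
  if (any(!is.finite(margins))) stop("fit_calibration(): non-finite margins")
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop("fit_calibration(): labels must be 0/1")
  }
  if (length(unique(labels)) < 2) {
    stop("fit_calibration(): both classes must be present")
  }
  target <- as.numeric(labels)
  if (method == "platt") {
    n_pos <- sum(labels == 1)
    n_neg <- sum(labels == 0)
    target <- ifelse(labels == 1, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  }
  fit <- suppressWarnings(stats::glm(
    target ~ margins, family = stats::binomial(),
    control = stats::glm.control(maxit = max_iterations)
  ))
  new_psm_calibration(slope = unname(stats::coef(fit)[2]),
                      intercept = unname(stats::coef(fit)[1]),
                      converged = fit$converged)
}

#' Map margin scores to calibrated probabilities
#'
#' @param model A `psm_calibration` object.
#' @param margin Numeric vector of finite margin scores.
#' @return Probabilities in `(0, 1)`, strictly increasing in `margin` when
#'   the fitted slope is positive.
#' @export
calibrate <- function(model, margin) {
  stopifnot(inherits(model, "psm_calibration"))
  if (any(!is.finite(margin))) stop("calibrate(): non-finite margin")
  stats::plogis(model$slope * margin + model$intercept)
}

#' @export
print.psm_calibration <- function(x, ...) {
  cat("Logistic calibration: p = sigmoid(", format(x$slope, digits = 4),
      " * margin + ", format(x$intercept, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.psm_calibration <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept"),
                 estimate = c(x$slope, x$intercept))
}

#' @export
glance.psm_calibration <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 converged = x$converged)
}
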