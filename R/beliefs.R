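#' Numerically safe elementwise logarithm of probabilities
#'
#' Returns `log(pmax(p, eps))`. Every belief update in the package takes logs
#' of probability arrays that legitimately contain exact zeros (identity
#' transition mappings, near-deterministic likelihoods, lesioned priors), so a
#' floor is applied before the logarithm rather than propagating `-Inf`.
#'
#' @param p Numeric vector or array with non-negative entries.
#' @param eps Probability floor applied before the logarithm. Default `1e-16`.
#' @return Object of the same shape as `p` with `log(pmax(p, eps))`.
#' @examples
#' log_stable(c(1, 0))
#' log_stable(c(0.25, 0.75))
#' @export
log_stable <- function(p, eps = 1e-16) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("log_stable() requires finite, non-negative entries", call. = FALSE)
  }
  log(pmax(p, eps))
}

#' Softmax (normalized exponential)
#'
#' @param x Numeric vector of log-weights.
#' @return Probability vector proportional to `exp(x)`; invariant to adding a
#'   constant to `x`.
#' @examples
#' softmax(c(0, log(9)))
#' @export
softmax <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

#' Categorical belief over a labelled discrete support
#'
#' A normalized probability vector with fixed, unique support labels. Houses
#' state posteriors, policy posteriors, outcome beliefs, outcome priors and
#' initial-state priors throughout the package.
#'
#' @param probs Non-negative numeric vector summing to 1 (within `1e-8`).
#' @param labels Character vector of unique support labels; defaults to names
#'   of `probs` or `V1..Vn`.
#' @return A `cat_belief` object (named probability vector).
#' @examples
#' categorical_belief(c(white = 0.5, green = 0.25, blue = 0.25))
#' @export
categorical_belief <- function(probs, labels = NULL) {
  if (is.null(labels)) {
    labels <- names(probs) %||% paste0("V", seq_along(probs))
  }
  probs <- as.numeric(probs)
  if (anyDuplicated(labels) > 0) {
    stop("categorical_belief(): support labels must be unique", call. = FALSE)
  }
  if (length(labels) != length(probs)) {
    stop("categorical_belief(): labels and probs lengths differ", call. = FALSE)
  }
  if (any(probs < 0)) {
    stop("categorical_belief(): negative probabilities", call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-8) {
    stop("categorical_belief(): probabilities sum to ", format(sum(probs)),
         ", not 1", call. = FALSE)
  }
  structure(stats::setNames(probs, labels), class = "cat_belief")
}

#' @export
print.cat_belief <- function(x, ...) {
  cat("<categorical belief over {", paste(names(x), collapse = ", "), "}>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

is_prob_vector <- function(p, tol = 1e-8) {
  is.numeric(p) && all(is.finite(p)) && all(p >= -tol) && abs(sum(p) - 1) <= tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a non-negative vector to sum to one
#' @param x Non-negative numeric vector with positive sum.
#' @return Probability vector.
#' @keywords internal
normalize <- function(x) {
  s <- sum(x)
  if (s <= 0 || !is.finite(s)) {
    stop("normalize(): vector sums to ", s, call. = FALSE)
  }
  x / s
}
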