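#' Likelihood mapping from hidden states to outcomes
#'
#' Conditional outcome distributions for one sensory modality. `A` is an array
#' whose first dimension runs over the modality's outcomes and whose remaining
#' dimensions run over the levels of the parent state factors; every "column"
#' (the outcome distribution for one combination of parent levels) must be a
#' probability vector.
#'
#' @param name Modality name.
#' @param A Numeric array, dim = c(n_outcomes, parent level counts...).
#' @param outcomes Character labels for the outcome dimension.
#' @param parents Integer indices of the parent state factors (into the
#'   factor list of the generative model).
#' @param modulated Logical; is this modality's likelihood sharpened or
#'   flattened by the inferred sensory precision? (Visual: yes;
#'   proprioceptive: no.)
#' @param precision_parent Position *within* `parents` of the factor whose
#'   level selects which precision component applies (the fixation location),
#'   or `NULL` when a single shared precision applies.
#' @return A `likelihood_mapping` object.
#' @export
likelihood_mapping <- function(name, A, outcomes = NULL, parents,
                               modulated = FALSE, precision_parent = NULL) {
  A <- as.array(A)
  storage.mode(A) <- "double"
  n_out <- dim(A)[1]
  outcomes <- outcomes %||% paste0("o", seq_len(n_out))
  if (length(outcomes) != n_out) {
    stop("likelihood_mapping('", name, "'): outcome labels do not match dim 1",
         call. = FALSE)
  }
  obj <- structure(
    list(name = name, A = A, outcomes = outcomes,
         parents = as.integer(parents), modulated = isTRUE(modulated),
         precision_parent = precision_parent),
    class = "likelihood_mapping"
  )
  validate_stochastic_array(A, margin = 1,
                            what = paste0("likelihood mapping '", name, "'"))
  obj
}

#' Transition mapping for one hidden-state factor
#'
#' Per-action conditional distributions over the next state level given the
#' previous one. Stored as an array of dim
#' `c(n_levels, n_levels, n_actions)`; columns (`B[, j, u]`) are
#' distributions over the next state. Uncontrollable factors use
#' `n_actions = 1`.
#'
#' @param name Factor name.
#' @param B Numeric matrix (promoted to a 1-action array) or 3-d array.
#' @return A `transition_mapping` object.
#' @export
transition_mapping <- function(name, B) {
  if (length(dim(B)) == 2) B <- array(B, dim = c(dim(B), 1))
  B <- as.array(B)
  storage.mode(B) <- "double"
  if (dim(B)[1] != dim(B)[2]) {
    stop("transition_mapping('", name, "'): B must be square per action",
         call. = FALSE)
  }
  for (u in seq_len(dim(B)[3])) {
    validate_stochastic_array(B[, , u, drop = FALSE], margin = 1,
                              what = paste0("transition mapping '", name,
                                            "', action ", u))
  }
  structure(list(name = name, B = B), class = "transition_mapping")
}

#' Gamma beliefs about sensory precision
#'
#' Prior and posterior beliefs about the likelihood precision (gain) `zeta`
#' for each visual location, parameterized as `Gamma(1, beta)` so that the
#' posterior expectation is `zeta = 1 / beta_posterior` exactly.
#'
#' @param beta_prior Positive rate(s) of the prior Gamma(1, beta) belief, one
#'   per location (recycled).
#' @param beta_posterior Positive rate(s) of the posterior belief; defaults to
#'   the prior.
#' @param labels Location labels.
#' @return A `precision_belief` object with fields `beta_prior`,
#'   `beta_posterior`, `labels`.
#' @examples
#' pb <- precision_belief(1, labels = c("LL", "LR", "UL", "UR"))
#' expected_precision(pb)
#' @export
precision_belief <- function(beta_prior = 1, beta_posterior = beta_prior,
                             labels = NULL) {
  n <- max(length(beta_prior), length(beta_posterior),
           length(labels %||% character()))
  beta_prior <- rep_len(as.numeric(beta_prior), n)
  beta_posterior <- rep_len(as.numeric(beta_posterior), n)
  labels <- labels %||% paste0("loc", seq_len(n))
  if (any(beta_prior <= 0) || any(beta_posterior <= 0)) {
    stop("precision_belief(): beta rates must be positive", call. = FALSE)
  }
  structure(list(beta_prior = stats::setNames(beta_prior, labels),
                 beta_posterior = stats::setNames(beta_posterior, labels),
                 labels = labels),
            class = "precision_belief")
}

#' Posterior expectation of sensory precision
#'
#' @param pb A `precision_belief`.
#' @return Named vector `1 / beta_posterior`.
#' @export
expected_precision <- function(pb) {
  stopifnot(inherits(pb, "precision_belief"))
  1 / pb$beta_posterior
}

#' @export
print.precision_belief <- function(x, ...) {
  cat("<precision belief (Gamma(1, beta))>\n")
  print(rbind(beta_prior = x$beta_prior, beta_posterior = x$beta_posterior,
              zeta = 1 / x$beta_posterior))
  invisible(x)
}

# every conditional distribution along `margin` must be a probability vector
validate_stochastic_array <- function(A, margin = 1, what = "array",
                                      tol = 1e-8) {
  if (any(A < 0)) {
    stop(what, ": negative entries", call. = FALSE)
  }
  sums <- apply(A, seq_along(dim(A))[-margin], sum)
  bad <- abs(sums - 1) > tol
  if (any(bad)) {
    stop(what, ": ", sum(bad), " conditional distribution(s) do not sum to 1 ",
         "(first offending sum = ", format(sums[bad][1]), ")", call. = FALSE)
  }
  invisible(TRUE)
}
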