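# Online inference of sensory precision (gain).
#
# One Gamma(1, beta) belief per visual location; the posterior expectation is
# zeta = 1/beta. After each observation, beta for the fixated location takes a
# few gradient steps on the variational free energy assembled from that
# observation: the likelihood term -sum_j s_j ln Abar(zeta)_{o j} plus the
# KL[Gamma(1, beta) || Gamma(1, beta_prior)] penalty, evaluated at
# zeta = 1/beta. Observations that the (confident) state belief predicts well
# push zeta up; contradicted predictions push it down sharply. State
# inference then reweights ALL stored observations at that location with the
# updated zeta, so a collapse in precision retrospectively discounts the
# conflicting evidence.

#' Analytic free-energy gradient with respect to sensory precision
#'
#' `dF/dzeta = sum_j s_j (sum_i Abar_ij ln A_ij) - sum_i o_i sum_j s_j ln A_ij
#' + beta_prior - 1/zeta`, where `Abar = softmax(zeta ln A)` column-wise, `s`
#' the joint state belief over the likelihood columns, and `o` the (one-hot
#' or soft) outcome. The last two terms are the derivative of the Gamma KL
#' penalty expressed in `zeta = 1/beta`. Matches central-difference numerical
#' differentiation of [free_energy()] (see the package tests).
#'
#' @param A_cols Likelihood matrix (outcomes x state combinations), raw
#'   (unmodulated).
#' @param s Probability vector over the state combinations (columns).
#' @param o Observed outcome index, or a probability vector over outcomes.
#' @param zeta Positive precision at which to evaluate.
#' @param beta_prior Prior Gamma rate.
#' @param eps Probability floor.
#' @return Scalar `dF/dzeta`.
#' @export
precision_gradient <- function(A_cols, s, o, zeta, beta_prior = 1,
                               eps = 1e-16) {
  A_cols <- as.matrix(A_cols)
  lnA <- log_stable(A_cols, eps)
  Abar <- modulate_likelihood(A_cols, zeta, eps = eps)
  if (length(o) == 1) {
    o_vec <- numeric(nrow(A_cols))
    o_vec[o] <- 1
  } else {
    o_vec <- as.numeric(o)
  }
  term1 <- sum(s * colSums(Abar * lnA))
  term2 <- sum(o_vec * (lnA %*% s))
  g <- term1 - term2 + beta_prior - 1 / zeta
  if (!is.finite(g)) {
    stop("precision_gradient(): non-finite gradient", call. = FALSE)
  }
  g
}

#' Update the precision belief for the fixated location
#'
#' Runs `config$precision_steps` gradient steps
#' `beta <- beta + kappa * dF/dzeta` (a descent of F in `zeta`, since
#' `zeta = 1/beta`), re-evaluating the gradient at the updated `zeta` each
#' step and clipping `beta` at `config$beta_min`. Only the fixated location's
#' belief changes.
#'
#' @param model A `gen_model` (supplies the visual likelihood and priors).
#' @param observation Observed visual outcome index.
#' @param state_beliefs List of posterior marginals (one probability vector
#'   per parent factor of the modulated modality) at the fixated timestep.
#' @param location Integer index of the fixated location (precision
#'   component).
#' @param precision A [precision_belief()]; defaults to the model's.
#' @param config An [av_config()].
#' @return Updated `precision_belief`.
#' @export
update_precision <- function(model, observation, state_beliefs, location,
                             precision = NULL, config = av_config()) {
  precision <- precision %||% model$precision
  mod_idx <- which(vapply(model$modalities, function(m) m$modulated,
                          logical(1)))[1]
  if (is.na(mod_idx)) {
    stop("update_precision(): model has no precision-modulated modality",
         call. = FALSE)
  }
  m <- model$modalities[[mod_idx]]
  # collapse the likelihood onto the fixated location's columns:
  # fix the precision-parent dimension at `location`, flatten the rest
  A <- m$A
  pd <- dim(A)[-1]
  if (!is.null(m$precision_parent)) {
    A <- slice_parent(A, m$precision_parent, location)
    s_list <- state_beliefs[-m$precision_parent]
  } else {
    s_list <- state_beliefs
  }
  A_cols <- matrix(A, nrow = dim(m$A)[1])
  s <- if (length(s_list) > 0) as.numeric(outer_list(lapply(s_list, as.numeric))) else 1
  beta <- precision$beta_posterior[location]
  b0 <- precision$beta_prior[location]
  for (k in seq_len(config$precision_steps)) {
    g <- precision_gradient(A_cols, s, observation, zeta = 1 / beta,
                            beta_prior = b0, eps = config$eps)
    beta <- max(beta + config$kappa * g, config$beta_min)
  }
  precision$beta_posterior[location] <- beta
  precision
}

# fix parent dimension `p` (1-based among parents) of likelihood array A at
# level `lev`; returns array over outcomes x remaining parents
slice_parent <- function(A, p, lev) {
  dims <- dim(A)
  idx <- rep(list(quote(expr = )), length(dims))
  idx[[p + 1]] <- lev
  out <- do.call(`[`, c(list(A), idx, list(drop = FALSE)))
  array(out, dim = dims[-(p + 1)])
}
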