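#' Enumerate the policy space
#'
#' All action sequences of length `depth` over the controllable factor's
#' levels (saccade targets), re-evaluated each step (receding horizon).
#'
#' @param model A `gen_model`.
#' @param depth Lookahead depth; defaults to the model's `policy_depth`.
#' @return Integer matrix, one row per policy, one column per future step.
#' @export
policy_space <- function(model, depth = NULL) {
  depth <- depth %||% model$policy_depth
  acts <- seq_len(model$n_actions)
  as.matrix(expand.grid(rep(list(acts), depth), KEEP.OUT.ATTRS = FALSE))
}

#' Expected free energy of a policy
#'
#' Scores an action sequence by the free energy of its anticipated futures:
#' for each future step,
#' `G += o . (ln o - ln C) - H . s`, where `o` is the predicted outcome
#' distribution under the precision-modulated likelihood, `C` the outcome
#' prior, and `-H . s >= 0` the expected ambiguity ([ambiguity()]). With
#' uniform `C` the first (risk) term is the negative outcome entropy, so low
#' `G` marks saccades with high epistemic value: locations whose features are
#' unresolved but whose outcomes are expected to be informative.
#'
#' @param model A `gen_model`.
#' @param policy Integer vector of future actions.
#' @param marginals Current per-factor posterior marginals (list of
#'   probability vectors at the latest timestep).
#' @param zeta Expected sensory precision (scalar or per-location vector).
#' @param config An [av_config()].
#' @return Scalar `G`.
#' @export
expected_free_energy <- function(model, policy, marginals, zeta = NULL,
                                 config = av_config()) {
  zeta <- zeta %||% expected_precision(model$precision)
  eps <- config$eps
  Abar_list <- lapply(model$modalities, function(m) {
    if (m$modulated) {
      if (!is.null(m$precision_parent) && length(zeta) > 1) {
        modulate_likelihood(m$A, zeta, along = m$precision_parent, eps = eps)
      } else {
        modulate_likelihood(m$A, zeta[1], eps = eps)
      }
    } else {
      m$A
    }
  })
  H_list <- lapply(Abar_list, ambiguity, eps = eps)
  q <- lapply(marginals, as.numeric)
  G <- 0
  for (step in seq_along(policy)) {
    u <- policy[step]
    q <- lapply(seq_along(model$factors), function(f) {
      fac <- model$factors[[f]]
      B <- if (fac$controllable) fac$B$B[, , u] else fac$B$B[, , 1]
      as.numeric(B %*% q[[f]])
    })
    for (g in seq_along(model$modalities)) {
      m <- model$modalities[[g]]
      vs <- q[m$parents]
      o <- predicted_outcomes(Abar_list[[g]], vs)
      risk <- sum(o * (log_stable(o, eps) - log_stable(as.numeric(model$C[[g]]), eps)))
      amb <- -ttv_all(as.array(H_list[[g]]), vs)
      G <- G + risk + amb
    }
  }
  G
}

#' Posterior over policies
#'
#' `pi = softmax(-gamma * G)`: policies expected to resolve the most
#' uncertainty (lowest expected free energy) are the most probable. Invariant
#' to adding a constant to all `G`.
#'
#' @param G Numeric vector of expected free energies.
#' @param gamma Policy precision (inverse temperature); default 1.
#' @return A [categorical_belief()] over policies.
#' @export
policy_posterior <- function(G, gamma = 1) {
  if (any(!is.finite(G))) {
    stop("policy_posterior(): non-finite expected free energy", call. = FALSE)
  }
  categorical_belief(softmax(-gamma * G), paste0("pi", seq_along(G)))
}

#' Select the next saccade from the policy posterior
#'
#' Marginalizes the policy posterior over the policies' first actions and
#' returns the action with the largest marginal probability; ties (within
#' `tie_tol`) break deterministically toward the lowest location index.
#'
#' @param pi Probability vector over policies.
#' @param policies Integer matrix from [policy_space()].
#' @param n_actions Number of actions.
#' @param tie_tol Tie tolerance.
#' @return Integer action index.
#' @export
select_action <- function(pi, policies, n_actions, tie_tol = 1e-9) {
  if (NROW(policies) == 0) {
    stop("select_action(): empty policy space", call. = FALSE)
  }
  marg <- vapply(seq_len(n_actions),
                 function(a) sum(pi[policies[, 1] == a]), numeric(1))
  which(marg >= max(marg) - tie_tol)[1]
}

# one decision step: G for every policy, policy posterior, chosen action
evaluate_policies <- function(model, marginals, zeta, config = av_config()) {
  pols <- policy_space(model)
  G <- vapply(seq_len(nrow(pols)), function(k) {
    expected_free_energy(model, pols[k, ], marginals, zeta, config)
  }, numeric(1))
  pi <- policy_posterior(G, gamma = config$gamma)
  action <- select_action(as.numeric(pi), pols, model$n_actions,
                          config$tie_tol)
  list(G = G, pi = pi, action = action, policies = pols)
}
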