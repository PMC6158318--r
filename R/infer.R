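# Variational state inference.
#
# The approximate posterior factorizes over policies, precision, and state
# factors: Q(s, pi, zeta) = Q(pi) Q(zeta) prod_f Q(s~_f | pi). Each factor's
# temporal chain is kept jointly and updated exactly by forward-backward
# smoothing given the expected log-likelihood messages from the other
# factors' marginals; the mean field is only across factors and precision.
# Coordinate sweeps therefore decrease the free energy monotonically, and for
# a single-factor model one sweep recovers exact Bayesian smoothing.

# modulated log-likelihood arrays for every modality at the current zeta
modulated_logA <- function(model, zeta, eps = 1e-16) {
  lapply(model$modalities, function(m) {
    if (m$modulated) {
      if (!is.null(m$precision_parent) && length(zeta) > 1) {
        Abar <- modulate_likelihood(m$A, zeta, along = m$precision_parent,
                                    eps = eps)
      } else {
        Abar <- modulate_likelihood(m$A, zeta[1], eps = eps)
      }
    } else {
      Abar <- m$A
    }
    log_stable(Abar, eps)
  })
}

# expected log-evidence message for factor `f` at one timestep:
# sum over modalities with f as parent of E_{q(-f)}[ln Abar(o | s_f, s_-f)]
evidence_message <- function(model, lnA_list, marg_tau, o_tau, f) {
  nf <- length(model$factors[[f]]$levels)
  msg <- numeric(nf)
  for (g in seq_along(model$modalities)) {
    m <- model$modalities[[g]]
    if (is.na(o_tau[g]) || !(f %in% m$parents)) next
    lnA_o <- index_outcome(lnA_list[[g]], o_tau[g])
    vs <- lapply(m$parents, function(p) marg_tau[[p]])
    keep <- match(f, m$parents)
    msg <- msg + ttv_except(lnA_o, vs, keep = keep)
  }
  msg
}

# slice a log-likelihood array at outcome index o (drops dim 1)
index_outcome <- function(lnA, o) {
  dims <- dim(lnA)
  idx <- matrix(lnA, nrow = dims[1])[o, ]
  if (length(dims) > 2) array(idx, dim = dims[-1]) else as.numeric(idx)
}

# transition slice for factor f at step tau (actions index the controllable
# factor's slices; others are action independent)
B_slice <- function(model, f, actions, tau) {
  fac <- model$factors[[f]]
  if (fac$controllable) fac$B$B[, , actions[tau]] else fac$B$B[, , 1]
}

# exact forward-backward smoothing of one factor's chain given evidence
# ln_phi (T x n). Returns marginals (T x n), pairwise joints, and log Z.
smooth_chain <- function(D, Bs, ln_phi) {
  T_ <- nrow(ln_phi)
  n <- length(D)
  phi <- exp(ln_phi - apply(ln_phi, 1, max))
  scale_log <- apply(ln_phi, 1, max)
  alpha <- matrix(0, T_, n)
  logZ <- 0
  a <- D * phi[1, ]
  ca <- sum(a)
  logZ <- logZ + log(ca) + scale_log[1]
  alpha[1, ] <- a / ca
  if (T_ > 1) {
    for (tau in 2:T_) {
      a <- phi[tau, ] * as.numeric(Bs[[tau - 1]] %*% alpha[tau - 1, ])
      ca <- sum(a)
      logZ <- logZ + log(ca) + scale_log[tau]
      alpha[tau, ] <- a / ca
    }
  }
  beta <- matrix(1, T_, n)
  if (T_ > 1) {
    for (tau in (T_ - 1):1) {
      b <- as.numeric(t(Bs[[tau]]) %*% (phi[tau + 1, ] * beta[tau + 1, ]))
      beta[tau, ] <- b / max(b)
    }
  }
  marg <- alpha * beta
  marg <- marg / rowSums(marg)
  pair <- vector("list", max(T_ - 1, 0))
  if (T_ > 1) {
    for (tau in 1:(T_ - 1)) {
      # xi[i, j] = q(s_{tau+1} = i, s_tau = j)
      xi <- Bs[[tau]] * outer(phi[tau + 1, ] * beta[tau + 1, ], alpha[tau, ])
      pair[[tau]] <- xi / sum(xi)
    }
  }
  list(marginals = marg, pairwise = pair, logZ = logZ)
}

#' Update state posteriors by variational message passing
#'
#' Runs coordinate sweeps over the hidden-state factors. Each sweep gives
#' every factor an exact forward-backward smoothing pass over its temporal
#' chain, with likelihood messages formed by averaging the precision-modulated
#' log-likelihood over the other factors' current marginals (softmax
#' renormalization is implicit in the smoothing). Sweeps stop when the largest
#' marginal change falls below `config$tol` or after `config$max_sweeps`
#' sweeps; the free energy is non-increasing across sweeps.
#'
#' @param model A `gen_model`.
#' @param observations Integer matrix (timesteps x modalities) of outcome
#'   indices; `NA` marks an unobserved entry (e.g. the pre-saccade start
#'   step).
#' @param actions Integer vector of actions, one per transition
#'   (`nrow(observations) - 1`).
#' @param zeta Expected sensory precision; scalar or per-location vector.
#'   Default: the model's posterior expectation.
#' @param config An [av_config()].
#' @return List with `marginals` (per factor, timestep x level matrices),
#'   `pairwise` joints, free energy `F`, the per-sweep trace `F_trace`,
#'   `converged`, and `sweeps`.
#' @export
infer_states <- function(model, observations, actions = integer(0),
                         zeta = NULL, config = av_config()) {
  observations <- as.matrix(observations)
  T_ <- nrow(observations)
  stopifnot(length(actions) == max(T_ - 1, 0))
  zeta <- zeta %||% expected_precision(model$precision)
  lnA_list <- modulated_logA(model, zeta, config$eps)
  nF <- length(model$factors)
  # initialize marginals by forward prior propagation (no evidence)
  marg <- vector("list", nF)
  pair <- vector("list", nF)
  Bs_all <- lapply(seq_len(nF), function(f) {
    lapply(seq_len(max(T_ - 1, 0)), function(tau) B_slice(model, f, actions, tau))
  })
  for (f in seq_len(nF)) {
    n <- length(model$factors[[f]]$levels)
    m <- matrix(0, T_, n)
    m[1, ] <- as.numeric(model$factors[[f]]$D)
    if (T_ > 1) {
      for (tau in 2:T_) m[tau, ] <- as.numeric(Bs_all[[f]][[tau - 1]] %*% m[tau - 1, ])
    }
    marg[[f]] <- m
  }
  F_trace <- numeric(0)
  converged <- FALSE
  sweeps <- 0L
  for (it in seq_len(config$max_sweeps)) {
    sweeps <- it
    delta <- 0
    for (f in seq_len(nF)) {
      n <- length(model$factors[[f]]$levels)
      ln_phi <- matrix(0, T_, n)
      for (tau in seq_len(T_)) {
        if (all(is.na(observations[tau, ]))) next
        marg_tau <- lapply(marg, function(mm) mm[tau, ])
        ln_phi[tau, ] <- evidence_message(model, lnA_list, marg_tau,
                                          observations[tau, ], f)
      }
      sm <- smooth_chain(as.numeric(model$factors[[f]]$D), Bs_all[[f]], ln_phi)
      delta <- max(delta, max(abs(sm$marginals - marg[[f]])))
      marg[[f]] <- sm$marginals
      pair[[f]] <- sm$pairwise
    }
    belief <- list(marginals = marg, pairwise = pair)
    F_trace <- c(F_trace,
                 free_energy(model, belief, observations, actions,
                             zeta = zeta, config = config))
    if (delta < config$tol) {
      converged <- TRUE
      break
    }
  }
  for (f in seq_len(nF)) {
    dimnames(marg[[f]]) <- list(NULL, model$factors[[f]]$levels)
  }
  list(marginals = marg, pairwise = pair,
       F = F_trace[length(F_trace)], F_trace = F_trace,
       converged = converged, sweeps = sweeps)
}

#' Variational free energy of a belief state
#'
#' Assembles `F = E_Q[ln Q(s, zeta) - ln P(o, s, zeta)]` for the structured
#' posterior: per-factor chain entropies, initial-state and transition
#' cross-terms, expected log-likelihood of the observed outcomes under the
#' precision-modulated mapping, and the `KL[Gamma(1, beta) || Gamma(1,
#' beta_prior)]` penalty on each precision component. At the exact posterior
#' of a single-factor model this equals the negative log evidence.
#'
#' @param model A `gen_model`.
#' @param belief List with `marginals` and `pairwise` as returned by
#'   [infer_states()].
#' @param observations,actions As in [infer_states()].
#' @param zeta Expected precision used for the likelihood terms (defaults to
#'   `1 / beta_posterior`).
#' @param beta_posterior,beta_prior Gamma rates for the precision KL term;
#'   default the model's.
#' @param config An [av_config()].
#' @return Scalar free energy (nats).
#' @export
free_energy <- function(model, belief, observations, actions = integer(0),
                        zeta = NULL, beta_posterior = NULL, beta_prior = NULL,
                        config = av_config()) {
  observations <- as.matrix(observations)
  T_ <- nrow(observations)
  eps <- config$eps
  beta_posterior <- beta_posterior %||% model$precision$beta_posterior
  beta_prior <- beta_prior %||% model$precision$beta_prior
  zeta <- zeta %||% (1 / beta_posterior)
  lnA_list <- modulated_logA(model, zeta, eps)
  marg <- belief$marginals
  pair <- belief$pairwise
  F_ <- 0
  for (f in seq_along(model$factors)) {
    q1 <- marg[[f]][1, ]
    F_ <- F_ + sum(q1 * log_stable(q1, eps)) - sum(q1 * log_stable(as.numeric(model$factors[[f]]$D), eps))
    if (T_ > 1) {
      for (tau in 1:(T_ - 1)) {
        xi <- pair[[f]][[tau]]
        qt <- marg[[f]][tau, ]
        B <- B_slice(model, f, actions, tau)
        # E[ln q(s_{tau+1} | s_tau)] - E[ln B]
        lq <- log_stable(xi, eps) - matrix(log_stable(qt, eps), nrow(xi),
                                           ncol(xi), byrow = TRUE)
        F_ <- F_ + sum(xi * (lq - log_stable(B, eps)))
      }
    }
  }
  for (tau in seq_len(T_)) {
    for (g in seq_along(model$modalities)) {
      if (is.na(observations[tau, g])) next
      m <- model$modalities[[g]]
      lnA_o <- index_outcome(lnA_list[[g]], observations[tau, g])
      vs <- lapply(m$parents, function(p) marg[[p]][tau, ])
      F_ <- F_ - ttv_all(as.array(lnA_o), vs)
    }
  }
  F_ + sum(kl_gamma_rate(beta_posterior, beta_prior))
}

# KL[Gamma(1, b) || Gamma(1, b0)] (exponential distributions, rate form)
kl_gamma_rate <- function(b, b0) {
  log(b / b0) + b0 / b - 1
}
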