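# Shared fixtures and independent oracles, built in code.

# random column-stochastic likelihood matrix
rand_stochastic <- function(n_out, n_cols) {
  m <- matrix(stats::rgamma(n_out * n_cols, 1), n_out)
  sweep(m, 2, colSums(m), "/")
}

# random single-factor chain model (controllable with identical slices so the
# action argument is inert); returns model plus its raw arrays
make_toy_chain <- function(n_states = 3, n_out = 3, horizon = 3) {
  A <- rand_stochastic(n_out, n_states)
  B <- rand_stochastic(n_states, n_states)
  D <- as.numeric(rand_stochastic(n_states, 1))
  m <- build_model(
    factors = list(state_factor("s", paste0("s", seq_len(n_states)), D,
                                array(B, c(n_states, n_states, n_states)),
                                controllable = TRUE)),
    modalities = list(likelihood_mapping("o", A, paste0("o", seq_len(n_out)),
                                         parents = 1)),
    horizon = horizon
  )
  list(model = m, A = A, B = B, D = D)
}

# brute-force posterior over a hidden chain by enumerating every state
# sequence; the independent oracle for the variational state updates
enumerate_chain_posterior <- function(A, B, D, obs) {
  n <- length(D)
  T_ <- length(obs)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), T_),
                                KEEP.OUT.ATTRS = FALSE))
  p <- apply(seqs, 1, function(s) {
    w <- D[s[1]]
    if (!is.na(obs[1])) w <- w * A[obs[1], s[1]]
    if (T_ > 1) {
      for (tau in 2:T_) {
        w <- w * B[s[tau], s[tau - 1]]
        if (!is.na(obs[tau])) w <- w * A[obs[tau], s[tau]]
      }
    }
    w
  })
  evidence <- sum(p)
  marg <- sapply(seq_len(T_), function(tau) {
    sapply(seq_len(n), function(i) sum(p[seqs[, tau] == i])) / evidence
  })
  list(marginals = t(marg), evidence = evidence)
}

# total variation distance between two probability vectors
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# free energy assembled from a single location's observations, as a function
# of zeta; the quantity the analytic precision gradient differentiates
precision_free_energy <- function(A_cols, s, obs, zeta, beta_prior) {
  Abar <- modulate_likelihood(A_cols, zeta)
  lik <- -sum(vapply(obs, function(o) sum(s * log_stable(Abar[o, ])),
                     numeric(1)))
  lik + log(1 / zeta / beta_prior) + beta_prior * zeta - 1
}
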