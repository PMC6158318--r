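test_that("variational posteriors match exact Bayes on enumerable chains", {
  set.seed(21)
  for (i in 1:10) {
    toy <- make_toy_chain(3, 3, horizon = 3)
    obs <- matrix(sample(3, 3, replace = TRUE), ncol = 1)
    acts <- c(1L, 1L)
    bel <- infer_states(toy$model, obs, acts)
    oracle <- enumerate_chain_posterior(toy$A, toy$B, toy$D, obs[, 1])
    for (tau in 1:3) {
      expect_lt(tv_dist(bel$marginals[[1]][tau, ], oracle$marginals[tau, ]),
                1e-4)
    }
    # the bound is tight at the exact posterior
    expect_equal(bel$F, -log(oracle$evidence), tolerance = 1e-6)
  }
})

test_that("free energy increases away from the exact posterior", {
  set.seed(22)
  toy <- make_toy_chain(3, 3, horizon = 3)
  obs <- matrix(c(1L, 2L, 3L), ncol = 1)
  acts <- c(1L, 1L)
  bel <- infer_states(toy$model, obs, acts)
  F_star <- free_energy(toy$model, bel, obs, acts, zeta = 1)
  # a chain-consistent perturbation: smooth under corrupted evidence
  for (k in 1:5) {
    wrong_obs <- obs
    wrong_obs[sample(3, 1), 1] <- sample(3, 1)
    bel2 <- infer_states(toy$model, wrong_obs, acts)
    F_pert <- free_energy(toy$model, bel2, obs, acts, zeta = 1)
    expect_gte(F_pert, F_star - 1e-10)
  }
})

test_that("free energy is non-increasing over update sweeps", {
  m <- build_foraging_model()
  w <- world_state(c("green", "blue", "white", "white"))
  obs <- matrix(NA_integer_, 1, 2)
  acts <- integer(0)
  for (a in c(1L, 2L, 3L)) {
    st <- step_world(w, a)
    w <- st$world
    obs <- rbind(obs, st$observations)
    acts <- c(acts, a)
  }
  bel <- infer_states(m, obs, acts)
  expect_true(all(diff(bel$F_trace) <= 1e-6))
  expect_true(bel$converged)
})

test_that("delta likelihoods concentrate the posterior on the observed state", {
  m <- build_model(
    factors = list(state_factor("s", c("a", "b", "c"), rep(1 / 3, 3),
                                array(diag(3), c(3, 3, 3)),
                                controllable = TRUE)),
    modalities = list(likelihood_mapping("o", diag(3), parents = 1)),
    horizon = 1
  )
  bel <- infer_states(m, matrix(2L, 1, 1))
  expect_gte(bel$marginals[[1]][1, 2], 1 - 1e-6)
})

test_that("zero precision makes observations uninformative", {
  prior <- c(0.7, 0.2, 0.1)
  m <- build_model(
    factors = list(state_factor("s", c("a", "b", "c"), prior,
                                array(diag(3), c(3, 3, 3)),
                                controllable = TRUE)),
    modalities = list(likelihood_mapping("o", diag(3), parents = 1,
                                         modulated = TRUE)),
    horizon = 1
  )
  bel <- infer_states(m, matrix(3L, 1, 1), zeta = 0)
  expect_equal(bel$marginals[[1]][1, ], prior, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("all inferred distributions are normalized and non-negative", {
  set.seed(23)
  toy <- make_toy_chain(4, 3, horizon = 3)
  obs <- matrix(sample(3, 3, replace = TRUE), ncol = 1)
  bel <- infer_states(toy$model, obs, c(1L, 1L))
  for (tau in 1:3) {
    q <- bel$marginals[[1]][tau, ]
    expect_true(all(q >= 0))
    expect_equal(sum(q), 1, tolerance = 1e-8)
  }
  for (xi in bel$pairwise[[1]]) {
    expect_true(all(xi >= 0))
    expect_equal(sum(xi), 1, tolerance = 1e-8)
  }
})
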