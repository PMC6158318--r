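test_that("the analytic precision gradient matches numerical differentiation", {
  set.seed(31)
  rel_err <- replicate(100, {
    n_o <- sample(2:4, 1)
    n_s <- sample(2:6, 1)
    A <- rand_stochastic(n_o, n_s)
    s <- as.numeric(rand_stochastic(n_s, 1))
    o <- sample(n_o, 1)
    zeta <- stats::runif(1, 0.05, 4)
    b0 <- stats::runif(1, 0.3, 3)
    h <- 1e-6 * max(zeta, 1)
    g_num <- (precision_free_energy(A, s, o, zeta + h, b0) -
                precision_free_energy(A, s, o, zeta - h, b0)) / (2 * h)
    g_ana <- precision_gradient(A, s, o, zeta, b0)
    abs(g_ana - g_num) / max(abs(g_ana), 1e-8)
  })
  expect_lt(max(rel_err), 1e-5)
})

test_that("the gradient also differentiates the fully assembled free energy", {
  set.seed(32)
  for (i in 1:5) {
    toy <- make_toy_chain(3, 3, horizon = 2)
    toy$model$modalities[[1]]$modulated <- TRUE
    obs <- matrix(sample(3, 2, replace = TRUE), ncol = 1)
    acts <- 1L
    zeta <- stats::runif(1, 0.2, 2)
    bel <- infer_states(toy$model, obs, acts, zeta = zeta)
    Fz <- function(z) {
      free_energy(toy$model, bel, obs, acts, zeta = z,
                  beta_posterior = 1 / z, beta_prior = 1)
    }
    h <- 1e-6
    g_num <- (Fz(zeta + h) - Fz(zeta - h)) / (2 * h)
    # the assembled likelihood term averages over every timestep's state
    # marginal; sum the per-observation analytic gradients accordingly
    g_ana <- sum(vapply(seq_len(nrow(obs)), function(tau) {
      precision_gradient(toy$A, bel$marginals[[1]][tau, ], obs[tau, 1],
                         zeta, beta_prior = 1)
    }, numeric(1))) - (nrow(obs) - 1) * (1 - 1 / zeta)
    expect_equal(g_ana, g_num, tolerance = 1e-5 * max(1, abs(g_ana)))
  }
})

test_that("confirming observations never decrease precision; conflicting ones
           under a precise prior decrease it", {
  m <- build_foraging_model()
  pb <- m$precision
  # confident, correct prediction of "green" at LL
  s_conf <- list(c(0.001, 0.998, 0.001), rep(1 / 3, 3), rep(1 / 3, 3),
                 rep(1 / 3, 3), c(1, 0, 0, 0))
  pb_up <- update_precision(m, observation = 2L, s_conf, location = 1L,
                            precision = pb)
  expect_gte(expected_precision(pb_up)[1], expected_precision(pb)[1])
  # same confident belief contradicted by "blue"
  pb_down <- update_precision(m, observation = 3L, s_conf, location = 1L,
                              precision = pb)
  expect_lt(expected_precision(pb_down)[1], expected_precision(pb)[1])
  # only the fixated location changes
  expect_equal(pb_down$beta_posterior[-1], pb$beta_posterior[-1])
})

test_that("beta stays positive under extreme conflict", {
  m <- build_foraging_model(visual_confidence = 1)
  s_conf <- list(c(0, 1, 0), rep(1 / 3, 3), rep(1 / 3, 3), rep(1 / 3, 3),
                 c(1, 0, 0, 0))
  cfg <- av_config(kappa = 50, precision_steps = 8)
  pb <- update_precision(m, observation = 3L, s_conf, location = 1L,
                         config = cfg)
  expect_gt(pb$beta_posterior[1], 0)
  expect_true(is.finite(expected_precision(pb)[1]))
})
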