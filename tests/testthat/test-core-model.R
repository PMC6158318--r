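test_that("log_stable floors zeros and matches direct evaluation", {
  expect_equal(log_stable(c(1, 0)), c(0, log(1e-16)))
  expect_equal(log_stable(c(0.5, 0.5)), c(log(0.5), log(0.5)))
  expect_equal(log_stable(c(0.25, 0.75)), c(-1.3862944, -0.2876821),
               tolerance = 1e-6)
  expect_error(log_stable(c(-0.1, 1.1)), "non-negative")
})

test_that("categorical beliefs enforce normalization and unique labels", {
  b <- categorical_belief(c(a = 0.25, b = 0.75))
  expect_s3_class(b, "cat_belief")
  expect_equal(sum(b), 1)
  expect_error(categorical_belief(c(0.5, 0.4)), "sum to")
  expect_error(categorical_belief(c(a = 0.5, a = 0.5)), "unique")
  expect_error(categorical_belief(c(a = -0.1, b = 1.1)), "negative")
})

test_that("build_model validates structure and names offending components", {
  # smallest legal model: one 2-state factor, one modality
  m <- build_model(
    factors = list(state_factor("s", c("x", "y"), c(0.5, 0.5),
                                array(diag(2), c(2, 2, 2)),
                                controllable = TRUE)),
    modalities = list(likelihood_mapping("o", diag(2), c("x", "y"),
                                         parents = 1)),
    horizon = 2
  )
  expect_s3_class(m, "gen_model")
  # non-stochastic likelihood column
  badA <- matrix(c(0.5, 0.4, 0.2, 0.8), 2)
  expect_error(likelihood_mapping("vis", badA, parents = 1), "vis")
  # dangling parent reference
  expect_error(
    build_model(
      factors = list(state_factor("s", c("x", "y"), c(0.5, 0.5),
                                  array(diag(2), c(2, 2, 2)),
                                  controllable = TRUE)),
      modalities = list(likelihood_mapping("o", diag(2), parents = 3)),
      horizon = 2
    ),
    "missing"
  )
  # non-positive precision rate
  expect_error(precision_belief(beta_prior = 0), "positive")
})

test_that("the foraging spec builds 5 factors and 2 modalities", {
  m <- build_foraging_model()
  expect_length(m$factors, 5)
  expect_length(m$modalities, 2)
  expect_equal(m$controllable, 5L)
  expect_true(m$modalities$visual$modulated)
  expect_false(m$modalities$proprioceptive$modulated)
  expect_length(m$precision$beta_prior, 4)
  # feature transitions are identity for every action
  for (f in 1:4) expect_equal(m$factors[[f]]$B$B[, , 1], diag(3))
})

test_that("models serialize and reload bit for bit", {
  m <- build_foraging_model(
    feature_priors = make_feature_priors(
      c(LL = "green", LR = "blue", UL = "white", UR = "white"), 0.97),
    beta_prior = 1.5, horizon = 7
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$modalities$visual$A, m$modalities$visual$A)
  for (f in seq_along(m$factors)) {
    expect_identical(m2$factors[[f]]$B$B, m$factors[[f]]$B$B)
    expect_identical(unclass(m2$factors[[f]]$D), unclass(m$factors[[f]]$D))
  }
  expect_identical(m2$precision$beta_prior, m$precision$beta_prior)
})

test_that("any validated model yields finite log-arrays", {
  set.seed(7)
  for (i in 1:10) {
    toy <- make_toy_chain(sample(2:4, 1), sample(2:4, 1))
    for (mod in toy$model$modalities) {
      expect_true(all(is.finite(log_stable(mod$A))))
    }
    for (f in toy$model$factors) {
      expect_true(all(is.finite(log_stable(f$B$B))))
    }
  }
})
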