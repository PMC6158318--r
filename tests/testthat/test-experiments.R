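test_that("scenario runs are fully reproducible", {
  a <- run_search_scenario("weak_wrong")
  b <- run_search_scenario("weak_wrong")
  expect_identical(a$record, b$record)
  expect_identical(a$precision$beta_posterior, b$precision$beta_posterior)
})

test_that("trial records carry the tidy interface", {
  sc <- run_search_scenario("matched")
  td <- tidy(sc)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$location), av_locations)
  expect_equal(nrow(td), nrow(sc$record) * 4)
  gl <- glance(sc)
  expect_equal(nrow(gl), 1)
  s <- scenario_location_summary(sc)
  expect_equal(s$location, av_locations)
})

test_that("fixtures are seed-deterministic and valid", {
  f1 <- generate_fixture(99, "conflict")
  f2 <- generate_fixture(99, "conflict")
  expect_identical(as.character(fixture_json(f1)),
                   as.character(fixture_json(f2)))
  expect_true(any(f1$believed != f1$world$features))
  fa <- generate_fixture(5, "agreement")
  expect_equal(unname(fa$believed), unname(fa$world$features))
  # a batch of seeds all produce models passing validation
  for (seed in 1:20) {
    fx <- generate_fixture(seed)
    m <- build_foraging_model(feature_priors = fx$feature_priors)
    expect_s3_class(m, "gen_model")
  }
})

test_that("the prior-confidence sweep shows the truth-to-prior crossover", {
  sw <- sweep_prior_precision(c(1 / 3 + 1e-9, 0.6, 0.9, 0.999, 0.9999))
  # flat prior: evidence wins and precision barely moves
  expect_true(sw$posterior_matches_truth[1])
  expect_lt(abs(sw$delta_zeta_contradicted[1]), 0.25)
  # very confident prior: the prior wins and precision collapses
  n <- nrow(sw)
  expect_true(sw$posterior_matches_prior[n])
  expect_lt(sw$delta_zeta_contradicted[n], -0.25)
  # prior dominance is monotone in confidence along the grid
  expect_true(all(diff(as.integer(sw$posterior_matches_prior)) >= 0))
  expect_true(is.finite(attr(sw, "crossover")))
})

test_that("hierarchical scenario wrappers expose their signatures", {
  h <- run_scene_scenario("healthy", schedule = epoch_schedule(2, 5))
  expect_equal(h$variant, "healthy")
  expect_equal(h$informative_location, "LL")
  expect_equal(glance(h)$map_scene, "LL-green")
  l <- run_scene_scenario("lesioned", schedule = epoch_schedule(2, 5))
  expect_equal(as.numeric(l$library$prior["LL-green"]), 0)
  expect_false(glance(l)$map_scene == "LL-green")
})

test_that("plot builders return ggplot objects", {
  sc <- run_search_scenario("matched")
  expect_s3_class(autoplot(sc), "ggplot")
  h <- run_scene_scenario("healthy", schedule = epoch_schedule(1, 5))
  expect_s3_class(autoplot(h), "ggplot")
  expect_s3_class(plot_precision_trace(h), "ggplot")
  expect_s3_class(plot_feature_beliefs(h$feature_posteriors), "ggplot")
})
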