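test_that("the visual likelihood reports the fixated feature", {
  m <- build_foraging_model(visual_confidence = 1)
  A <- m$modalities$visual$A
  # fixation = LL (1), feature at LL = green (2): delta on "green"
  expect_equal(A[, 2, 1, 1, 1, 1], c(0, 1, 0))
  # every column is a delta at confidence 1
  cols <- matrix(A, nrow = 3)
  expect_true(all(apply(cols, 2, max) == 1))
  # default confidence spreads the remainder evenly
  m2 <- build_foraging_model()
  cols2 <- matrix(m2$modalities$visual$A, nrow = 3)
  expect_true(all(abs(apply(cols2, 2, max) - 0.9) < 1e-12))
  expect_true(all(abs(apply(cols2, 2, min) - 0.05) < 1e-12))
})

test_that("precise priors land on the believed values", {
  pr <- make_feature_priors(c(LL = "green", LR = "blue", UL = "white",
                              UR = "white"), 0.98)
  m <- build_foraging_model(feature_priors = pr)
  expect_equal(as.numeric(m$factors$feat_LL$D), c(0.01, 0.98, 0.01))
  expect_equal(as.numeric(m$factors$feat_LR$D), c(0.01, 0.01, 0.98))
  expect_s3_class(m, "gen_model")
})

test_that("the world steps deterministically and without side effects", {
  w <- world_state(c(LL = "green", LR = "blue", UL = "white", UR = "white"))
  st <- step_world(w, "LL")
  expect_equal(st$world$fixation, "LL")
  expect_equal(unname(st$observations),
               c(match("green", av_features), 1L))
  # repeated fixation of a static world yields identical outcomes
  st2 <- step_world(st$world, "LL")
  expect_equal(st2$observations, st$observations)
  # purity: the original world is untouched
  expect_equal(w$fixation, "LL")
  expect_error(step_world(w, 9), "invalid")
  # a commanded trajectory is followed exactly
  traj <- c(2L, 3L, 4L, 1L, 2L)
  ww <- w
  seen <- integer(0)
  for (a in traj) {
    s <- step_world(ww, a)
    ww <- s$world
    seen <- c(seen, s$observations[["proprioceptive"]])
  }
  expect_equal(seen, traj)
})

test_that("the default scene library is the 8 one-object scenes", {
  lib <- default_scene_library()
  expect_length(lib$scenes, 8)
  expect_equal(unname(lib$prior), rep(1 / 8, 8))
  expect_equal(unname(lib$scenes[["LL-green"]]$assignment),
               c("green", "white", "white", "white"))
  # every pair of scenes differs somewhere
  for (i in 1:7) for (j in (i + 1):8) {
    expect_false(all(lib$scenes[[i]]$assignment ==
                       lib$scenes[[j]]$assignment))
  }
})

test_that("lesioning renormalizes and preserves untouched ratios", {
  lib <- default_scene_library()
  l1 <- lesion_scene_prior(lib, 3)
  expect_equal(unname(l1$prior), c(rep(1 / 7, 2), 0, rep(1 / 7, 5)))
  # lesioning an already-zero scene changes nothing
  expect_equal(lesion_scene_prior(l1, 3)$prior, l1$prior)
  # double lesion
  l2 <- lesion_scene_prior(l1, "UR-blue")
  expect_equal(unname(l2$prior), c(rep(1 / 6, 2), 0, rep(1 / 6, 4), 0))
  # ratios of survivors are preserved under a skewed prior
  skew <- scene_library(unname(lib$scenes), prior = (1:8) / sum(1:8))
  ls <- lesion_scene_prior(skew, 1)
  expect_equal(unname(ls$prior[3] / ls$prior[2]), 3 / 2, tolerance = 1e-12)
  only <- scene_library(unname(lib$scenes),
                        prior = c(1, rep(0, 7)))
  expect_error(lesion_scene_prior(only, 1), "only scene")
})
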