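# Configured scenario runners. All runners are deterministic given their
# configuration (action selection is argmax with a fixed tie-break); seeds
# enter only through the random fixture generator.

#' Per-location feature priors from believed contents and a confidence
#'
#' @param believed Character vector of believed feature values (named by
#'   location or in location order).
#' @param confidence Prior mass on the believed value (`1/3` = flat); the
#'   remainder splits evenly over the other two values.
#' @return Named list of per-location probability vectors.
#' @export
make_feature_priors <- function(believed, confidence) {
  if (!is.null(names(believed))) believed <- believed[av_locations]
  stopifnot(length(believed) == 4, all(believed %in% av_features),
            confidence >= 1 / 3, confidence <= 1)
  off <- (1 - confidence) / 2
  priors <- lapply(seq_along(av_locations), function(l) {
    p <- rep(off, 3)
    p[match(believed[[l]], av_features)] <- confidence
    stats::setNames(p, av_features)
  })
  stats::setNames(priors, av_locations)
}

#' Default study conditions of the single-level scenarios
#'
#' The true scene, the believed scene of the wrong-prior variants, and the
#' confidence levels. True scene: green lower-left, blue lower-right, upper
#' locations empty. Wrong-prior variants swap the believed colors of the two
#' lower locations, so LL and LR are the contradicted locations.
#'
#' @return List with `truth`, `believed_wrong`, `confidence_precise`,
#'   `confidence_weak`, `n_saccades`, `visual_confidence`, `beta_prior`.
#' @export
scenario_defaults <- function() {
  list(
    truth = c(LL = "green", LR = "blue", UL = "white", UR = "white"),
    believed_wrong = c(LL = "blue", LR = "green", UL = "white", UR = "white"),
    confidence_precise = 0.9999,
    confidence_weak = 0.5,
    n_saccades = 10,
    visual_confidence = 0.9,
    beta_prior = 1
  )
}

#' Run a single-level perception scenario
#'
#' Three prior/world regimes of a 10-saccade visual search:
#' * `matched` — a precise prior that agrees with the true scene: the
#'   posterior matches prior and truth, and the inferred sensory precision
#'   changes little.
#' * `weak_wrong` — an imprecise prior that disagrees with the true scene:
#'   sensory evidence dominates and the posterior follows the truth.
#' * `precise_wrong` — a precise prior that disagrees: the prior dominates,
#'   and the conflict is resolved by a collapse of the inferred precision at
#'   the contradicted locations.
#'
#' @param variant `"matched"`, `"weak_wrong"` or `"precise_wrong"`.
#' @param defaults Parameter bundle from [scenario_defaults()] (override
#'   fields to customize).
#' @param config An [av_config()].
#' @return An `av_scenario`: the underlying `av_trial` plus `variant`,
#'   `truth`, `believed`, `contradicted` (location labels where the prior
#'   MAP differs from the truth), and initial `zeta0`.
#' @examples
#' sc <- run_search_scenario("precise_wrong")
#' glance(sc)
#' @export
run_search_scenario <- function(variant = c("matched", "weak_wrong",
                                            "precise_wrong"),
                                defaults = scenario_defaults(),
                                config = av_config()) {
  variant <- match.arg(variant)
  truth <- defaults$truth
  believed <- switch(variant, matched = truth, defaults$believed_wrong)
  confidence <- switch(variant,
                       weak_wrong = defaults$confidence_weak,
                       defaults$confidence_precise)
  priors <- make_feature_priors(believed, confidence)
  model <- build_foraging_model(feature_priors = priors,
                                beta_prior = defaults$beta_prior,
                                horizon = defaults$n_saccades,
                                visual_confidence = defaults$visual_confidence)
  trial <- run_trial(model, world_state(truth), config = config)
  out <- trial
  out$variant <- variant
  out$truth <- truth
  out$believed <- stats::setNames(believed[av_locations], av_locations)
  out$contradicted <- av_locations[believed[av_locations] != truth[av_locations]]
  out$zeta0 <- 1 / model$precision$beta_prior
  class(out) <- c("av_scenario", class(trial))
  out
}

#' Run a hierarchical scene-construction scenario
#'
#' * `healthy` — uniform prior over the default eight-scene library: the true
#'   scene is inferred and consistency between the descending empirical prior
#'   and the sensory data raises the inferred precision.
#' * `lesioned` — the true scene's prior is set to zero (simulated loss of
#'   the neurons encoding that hypothesis): a confident but wrong scene
#'   posterior forms, descends confident wrong empirical priors, and the
#'   conflict depresses the precision at the informative location — false
#'   perceptual inference sustained by a permissive loss of sensory gain.
#'
#' @param variant `"healthy"` or `"lesioned"`.
#' @param true_scene Scene id in the library (default `"LL-green"`).
#' @param schedule An [epoch_schedule()]. Set `rescue = TRUE` instead to
#'   append a forced-fixation epoch at the informative location.
#' @param rescue If `TRUE`, the schedule gains a final epoch in which every
#'   saccade fixates the true scene's colored location.
#' @param library A `scene_library` (default [default_scene_library()]).
#' @param defaults Bundle from [scenario_defaults()].
#' @param config An [av_config()].
#' @return An `av_hscenario`: the `av_htrial` plus `variant`, `true_scene`,
#'   and `informative_location`.
#' @export
run_scene_scenario <- function(variant = c("healthy", "lesioned"),
                               true_scene = "LL-green",
                               schedule = epoch_schedule(3, 5),
                               rescue = FALSE,
                               library = default_scene_library(),
                               defaults = scenario_defaults(),
                               config = av_config()) {
  variant <- match.arg(variant)
  stopifnot(true_scene %in% names(library$scenes))
  scn <- library$scenes[[true_scene]]
  informative <- av_locations[scn$assignment != "white"][1]
  if (variant == "lesioned") {
    library <- lesion_scene_prior(library, true_scene)
  }
  if (rescue) {
    schedule$rescue_location <- informative
  }
  h <- run_hierarchical_trial(library, scene_world(scn),
                              schedule = schedule, config = config,
                              beta_prior = defaults$beta_prior,
                              visual_confidence = defaults$visual_confidence)
  h$variant <- variant
  h$true_scene <- true_scene
  h$informative_location <- informative
  class(h) <- c("av_hscenario", class(h))
  h
}

#' Sweep prior confidence against a contradictory world
#'
#' Runs the wrong-prior single-level scenario over a grid of prior
#' confidences and reports, per grid point, whether the final MAP posterior
#' at the contradicted locations tracks the truth or the prior, and the
#' relative precision change there. Below a crossover confidence the
#' sensory evidence wins; above it the prior wins and precision collapses.
#'
#' @param confidences Numeric grid of prior MAP masses in `(1/3, 1)`.
#' @param defaults Bundle from [scenario_defaults()].
#' @param config An [av_config()].
#' @return A tibble with one row per confidence: `confidence`,
#'   `posterior_matches_truth`, `posterior_matches_prior`,
#'   `delta_zeta_contradicted` (mean relative change), and the estimated
#'   `crossover` (first confidence where the prior wins) as an attribute.
#' @export
sweep_prior_precision <- function(confidences = c(seq(0.35, 0.95, by = 0.1),
                                                  0.99, 0.999, 0.9999),
                                  defaults = scenario_defaults(),
                                  config = av_config()) {
  stopifnot(all(confidences >= 1 / 3), all(confidences <= 1))
  rows <- lapply(confidences, function(conf) {
    d <- defaults
    d$confidence_precise <- conf
    sc <- run_search_scenario("precise_wrong", defaults = d, config = config)
    s <- scenario_location_summary(sc)
    contr <- s[s$location %in% sc$contradicted, ]
    tibble::tibble(
      confidence = conf,
      posterior_matches_truth = all(contr$map == contr$truth),
      posterior_matches_prior = all(contr$map == contr$believed),
      delta_zeta_contradicted = mean(contr$delta_zeta_rel)
    )
  })
  out <- dplyr::bind_rows(rows)
  cross <- out$confidence[out$posterior_matches_prior]
  attr(out, "crossover") <- if (length(cross)) min(cross) else NA_real_
  out
}

#' Per-location summary of a single-level scenario
#'
#' @param sc An `av_scenario`.
#' @return Tibble with one row per location: prior belief (`believed`),
#'   `truth`, final MAP (`map`), initial and final zeta, and the relative
#'   change `delta_zeta_rel`.
#' @export
scenario_location_summary <- function(sc) {
  stopifnot(inherits(sc, "av_scenario"))
  posts <- final_feature_posteriors(sc)
  zeta_final <- expected_precision(sc$precision)
  tibble::tibble(
    location = av_locations,
    believed = unname(sc$believed),
    truth = unname(sc$truth[av_locations]),
    map = vapply(posts, function(p) names(p)[which.max(p)], character(1)),
    map_prob = vapply(posts, max, numeric(1)),
    zeta_initial = unname(sc$zeta0),
    zeta_final = unname(zeta_final),
    delta_zeta_rel = unname((zeta_final - sc$zeta0) / sc$zeta0),
    contradicted = av_locations %in% sc$contradicted
  )
}

#' Generate a reproducible random fixture
#'
#' Draws a random true world (feature values i.i.d. uniform), a believed
#' scene and prior confidence, from a fixed seed. `difficulty = "conflict"`
#' guarantees at least one location where the believed value differs from
#' the truth; `"agreement"` makes the believed scene the truth.
#'
#' @param seed Integer seed.
#' @param difficulty `"random"`, `"conflict"` or `"agreement"`.
#' @param confidence_range Range the prior confidence is drawn from.
#' @return List with `world`, `believed`, `confidence`, `feature_priors`,
#'   `library`, and the `seed`; identical seeds give identical fixtures.
#' @export
generate_fixture <- function(seed, difficulty = c("random", "conflict",
                                                  "agreement"),
                             confidence_range = c(0.5, 0.998)) {
  difficulty <- match.arg(difficulty)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    truth <- sample(av_features, 4, replace = TRUE)
    believed <- switch(
      difficulty,
      agreement = truth,
      conflict = {
        b <- sample(av_features, 4, replace = TRUE)
        if (all(b == truth)) {
          l <- sample.int(4, 1)
          b[l] <- sample(setdiff(av_features, truth[l]), 1)
        }
        b
      },
      sample(av_features, 4, replace = TRUE)
    )
    confidence <- stats::runif(1, confidence_range[1], confidence_range[2])
    list(world = world_state(stats::setNames(truth, av_locations)),
         believed = stats::setNames(believed, av_locations),
         confidence = confidence,
         feature_priors = make_feature_priors(believed, confidence),
         library = default_scene_library(),
         seed = as.integer(seed))
  })
}

#' Serialize a fixture to canonical JSON
#'
#' @param fixture From [generate_fixture()].
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
fixture_json <- function(fixture, path = NULL) {
  x <- list(seed = fixture$seed,
            truth = unname(fixture$world$features),
            believed = unname(fixture$believed),
            confidence = fixture$confidence,
            scenes = lapply(fixture$library$scenes,
                            function(s) unname(s$assignment)),
            scene_prior = unname(fixture$library$prior))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
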