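# Two-level scene construction. The second level holds a categorical belief
# over scene hypotheses with identity dynamics and no policies; it talks to
# the first level only at epoch boundaries: descending empirical priors
# before each epoch of saccadic foraging, ascending soft evidence afterwards.
# Sensory precision is reset to its prior whenever a new empirical prior is
# set (the separation of temporal scales between levels).

#' Epoch schedule for hierarchical trials
#'
#' @param n_epochs Number of forage-then-update epochs (default 3).
#' @param saccades_per_epoch Saccades within each epoch before the scene
#'   belief is updated (default 5).
#' @param rescue_location Optional location label; if given, one extra final
#'   epoch is run in which every saccade is forced to this location (the
#'   consistent-fixation probe).
#' @param rescue_saccades Length of that forced epoch (default 12).
#' @return An `epoch_schedule` list.
#' @export
epoch_schedule <- function(n_epochs = 3, saccades_per_epoch = 5,
                           rescue_location = NULL, rescue_saccades = 12) {
  stopifnot(n_epochs >= 1, saccades_per_epoch >= 1)
  structure(list(n_epochs = as.integer(n_epochs),
                 saccades_per_epoch = as.integer(saccades_per_epoch),
                 rescue_location = rescue_location,
                 rescue_saccades = as.integer(rescue_saccades)),
            class = "epoch_schedule")
}

#' Descending empirical prior from scene beliefs
#'
#' Mixes the scenes' deterministic feature assignments by their posterior
#' probabilities: the level-1 prior over feature values at location `f` is
#' `sum_m Q(m) [(1 - eta) delta(scene m's value at f) + eta/3]`. The small
#' `eta` smoothing keeps descended priors away from exact deltas, which
#' bounds the empirical prior's log-odds (~`log((1-eta)/(eta/3))` nats) — the
#' same bound used on the ascending side — so that sustained contradictory
#' evidence remains able, in principle, to overturn an empirical prior.
#'
#' @param scene_posterior Probability vector over the library's scenes.
#' @param library A `scene_library`.
#' @param eta Smoothing mass (default `1e-3`).
#' @return Named list of per-location priors over feature values.
#' @export
descend_empirical_prior <- function(scene_posterior, library, eta = 1e-3) {
  stopifnot(inherits(library, "scene_library"))
  q <- as.numeric(scene_posterior)
  stopifnot(is_prob_vector(q), length(q) == length(library$scenes))
  nf <- length(av_features)
  priors <- lapply(av_locations, function(loc) {
    p <- rep(eta / nf, nf)
    for (m in seq_along(library$scenes)) {
      v <- match(library$scenes[[m]]$assignment[[loc]], av_features)
      p[v] <- p[v] + q[m] * (1 - eta)
    }
    stats::setNames(normalize(p), av_features)
  })
  stats::setNames(priors, av_locations)
}

#' Ascending evidence from level-1 posteriors to scene beliefs
#'
#' Treats the epoch's final feature posteriors as soft evidence for each
#' scene hypothesis:
#' `ln Q(m) = ln prior(m) + sum_f sum_v s_f(v) ln((1 - eta) [scene m assigns
#' v at f] + eta/3)`, softmax-normalized. Scenes with zero prior stay at
#' (numerically) zero posterior: the smoothing bounds the evidence any scene
#' can gain below the log floor of a zeroed prior.
#'
#' @param feature_posteriors Named list of per-location probability vectors
#'   over feature values (e.g. [final_feature_posteriors()]).
#' @param library A `scene_library`.
#' @param scene_prior Prior over scenes; defaults to the library prior.
#' @param eta Smoothing mass (default `1e-3`).
#' @return A [categorical_belief()] over scenes.
#' @export
ascend_evidence <- function(feature_posteriors, library, scene_prior = NULL,
                            eta = 1e-3) {
  stopifnot(inherits(library, "scene_library"))
  prior <- as.numeric(scene_prior %||% library$prior)
  nf <- length(av_features)
  lnq <- log_stable(prior)
  for (m in seq_along(library$scenes)) {
    asg <- library$scenes[[m]]$assignment
    for (loc in av_locations) {
      s <- as.numeric(feature_posteriors[[loc]])
      lik <- rep(eta / nf, nf)
      lik[match(asg[[loc]], av_features)] <- 1 - eta + eta / nf
      lnq[m] <- lnq[m] + sum(s * log(lik))
    }
  }
  categorical_belief(softmax(lnq), names(library$scenes))
}

#' Reset precision beliefs to their priors
#'
#' Applied whenever a new empirical prior descends: the posterior Gamma rate
#' of every location returns to its prior value; priors are untouched.
#' Idempotent.
#'
#' @param pb A [precision_belief()].
#' @return The reset `precision_belief`.
#' @export
reset_precision <- function(pb) {
  stopifnot(inherits(pb, "precision_belief"))
  pb$beta_posterior <- pb$beta_prior
  pb
}

#' Run a two-level hierarchical trial
#'
#' For each epoch: descend the empirical prior from the current scene
#' belief, reset the sensory precision, run an epoch of level-1 active
#' inference ([run_trial()]) against the true world, then ascend the epoch's
#' feature posteriors into the scene belief. Level-2 beliefs change only at
#' epoch boundaries. An optional rescue epoch forces every saccade to one
#' location.
#'
#' @param library A `scene_library` (its prior is the level-2 prior; lesion
#'   it first with [lesion_scene_prior()] to simulate pathology).
#' @param world A [world_state()]: the true scene.
#' @param schedule An [epoch_schedule()].
#' @param config An [av_config()].
#' @param beta_prior,visual_confidence Passed to [build_foraging_model()].
#' @param eta Smoothing of the ascending/descending messages.
#' @return An `av_htrial` list: `record` (per-saccade tibble with epoch
#'   index), `scene_trace` (per-epoch scene posteriors, tibble), final
#'   `scene_posterior`, `feature_posteriors` and `precision` from the last
#'   epoch, `library`, `schedule`, `config`.
#' @examples
#' lib <- default_scene_library()
#' w <- scene_world(lib$scenes[["LL-green"]])
#' h <- run_hierarchical_trial(lib, w, epoch_schedule(2, 5))
#' h$scene_trace
#' @export
run_hierarchical_trial <- function(library, world, schedule = epoch_schedule(),
                                   config = av_config(), beta_prior = 1,
                                   visual_confidence = 0.9, eta = 1e-3) {
  stopifnot(inherits(library, "scene_library"),
            inherits(world, "world_state"),
            inherits(schedule, "epoch_schedule"))
  q_scene <- as.numeric(library$prior)
  records <- list()
  trace <- list(tibble::tibble(epoch = 0L,
                               scene = names(library$scenes),
                               posterior = q_scene))
  n_rescue <- if (!is.null(schedule$rescue_location)) 1L else 0L
  feature_posteriors <- NULL
  precision <- NULL
  trial <- NULL
  for (e in seq_len(schedule$n_epochs + n_rescue)) {
    rescue <- e > schedule$n_epochs
    priors <- descend_empirical_prior(q_scene, library, eta)
    model <- build_foraging_model(
      feature_priors = priors, beta_prior = beta_prior,
      horizon = schedule$saccades_per_epoch,
      visual_confidence = visual_confidence,
      start = world$fixation
    )
    model$precision <- reset_precision(model$precision)
    n_sac <- if (rescue) schedule$rescue_saccades else schedule$saccades_per_epoch
    forced <- if (rescue) rep(schedule$rescue_location, n_sac) else NULL
    trial <- run_trial(model, world, n_saccades = n_sac, config = config,
                       forced_actions = forced, epoch = e)
    world <- trial$world
    records[[e]] <- trial$record
    feature_posteriors <- final_feature_posteriors(trial)
    precision <- trial$precision
    q_scene <- as.numeric(
      ascend_evidence(feature_posteriors, library, scene_prior = q_scene,
                      eta = eta)
    )
    trace[[e + 1L]] <- tibble::tibble(epoch = e,
                                      scene = names(library$scenes),
                                      posterior = q_scene)
  }
  structure(list(
    record = dplyr::bind_rows(records),
    scene_trace = dplyr::bind_rows(trace),
    scene_posterior = categorical_belief(q_scene, names(library$scenes)),
    feature_posteriors = feature_posteriors,
    precision = precision,
    library = library, schedule = schedule, config = config,
    world = world
  ), class = "av_htrial")
}

#' @export
print.av_htrial <- function(x, ...) {
  cat("<hierarchical trial:", max(x$record$epoch), "epochs,",
      nrow(x$record), "saccades>\n")
  best <- which.max(as.numeric(x$scene_posterior))
  cat("final scene belief:", names(x$scene_posterior)[best], "=",
      round(max(as.numeric(x$scene_posterior)), 4), "\n")
  invisible(x)
}
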