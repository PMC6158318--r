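#' Run a single-level active-inference trial
#'
#' The perception-action cycle of the foraging task. At each step the agent
#' scores every candidate saccade by expected free energy, selects the most
#' probable action under `softmax(-G)` (ties to the lowest location index),
#' executes it in the true world, observes the visual and proprioceptive
#' outcomes, re-infers the state posteriors over the whole trajectory under
#' the current expected precision, and then takes a few free-energy gradient
#' steps on the fixated location's precision belief. The chain has
#' `n_saccades + 1` timesteps; the first carries no observation (the start
#' state before the first saccade).
#'
#' @param model A `gen_model` from [build_foraging_model()] (any model whose
#'   controllable factor indexes the precision components works).
#' @param world A [world_state()] giving the true scene.
#' @param n_saccades Number of saccades; defaults to the model horizon.
#' @param config An [av_config()].
#' @param forced_actions Optional integer/character vector of saccade targets
#'   overriding policy selection (used for the consistent-fixation probes);
#'   `G` and the policy posterior are not evaluated on forced steps.
#' @param epoch Epoch index stamped into the record (hierarchical callers).
#' @return An `av_trial` list: `record` (one tibble row per saccade),
#'   `beliefs` (final posterior marginals per factor), `precision`,
#'   `observations`, `actions`, `model`, `world`, `config`.
#' @examples
#' m <- build_foraging_model()
#' w <- world_state(c("green", "blue", "white", "white"))
#' tr <- run_trial(m, w, n_saccades = 4)
#' tr$record
#' @export
run_trial <- function(model, world, n_saccades = NULL, config = av_config(),
                      forced_actions = NULL, epoch = NA_integer_) {
  stopifnot(inherits(model, "gen_model"), inherits(world, "world_state"))
  n_saccades <- n_saccades %||% model$horizon
  if (!is.null(forced_actions)) {
    if (is.character(forced_actions)) {
      forced_actions <- match(forced_actions, av_locations)
    }
    stopifnot(length(forced_actions) == n_saccades,
              all(forced_actions %in% seq_len(model$n_actions)))
  }
  n_mod <- length(model$modalities)
  obs <- matrix(NA_integer_, nrow = 1, ncol = n_mod)
  actions <- integer(0)
  pb <- model$precision
  beliefs <- infer_states(model, obs, actions,
                          zeta = expected_precision(pb), config = config)
  n_loc <- length(pb$labels)
  rows <- vector("list", n_saccades)
  for (t in seq_len(n_saccades)) {
    zeta <- expected_precision(pb)
    cur <- lapply(beliefs$marginals, function(m) m[nrow(m), ])
    if (is.null(forced_actions)) {
      dec <- evaluate_policies(model, cur, zeta, config)
      action <- dec$action
      G <- dec$G[seq_len(model$n_actions)]
      pi_action <- as.numeric(dec$pi)[seq_len(model$n_actions)]
    } else {
      action <- forced_actions[t]
      G <- rep(NA_real_, model$n_actions)
      pi_action <- rep(NA_real_, model$n_actions)
    }
    stepped <- step_world(world, action)
    world <- stepped$world
    obs <- rbind(obs, stepped$observations[seq_len(n_mod)])
    actions <- c(actions, action)
    beliefs <- infer_states(model, obs, actions, zeta = zeta, config = config)
    tau <- nrow(obs)
    vis_idx <- which(vapply(model$modalities, function(m) m$modulated,
                            logical(1)))[1]
    if (!is.na(vis_idx)) {
      parents <- model$modalities[[vis_idx]]$parents
      s_beliefs <- lapply(parents, function(p) beliefs$marginals[[p]][tau, ])
      pb <- update_precision(model, stepped$observations[[vis_idx]],
                             s_beliefs, location = action,
                             precision = pb, config = config)
      # re-smooth under the updated gain so beliefs and precision agree
      # before the next saccade is scored (a collapsed zeta retrospectively
      # discounts the conflicting evidence it responded to)
      beliefs <- infer_states(model, obs, actions,
                              zeta = expected_precision(pb), config = config)
    }
    zeta_new <- expected_precision(pb)
    map_feat <- vapply(seq_len(min(n_loc, length(beliefs$marginals) - 1)),
                       function(l) {
                         q <- beliefs$marginals[[l]][tau, ]
                         colnames(beliefs$marginals[[l]])[which.max(q)]
                       }, character(1))
    row <- tibble::tibble(
      epoch = epoch, step = t,
      fixation = av_locations[action],
      outcome = av_features[stepped$observations[["visual"]]] %||% NA_character_,
      free_energy = beliefs$F,
      converged = beliefs$converged
    )
    for (l in seq_len(n_loc)) {
      row[[paste0("zeta_", pb$labels[l])]] <- zeta_new[l]
    }
    for (l in seq_along(map_feat)) {
      row[[paste0("map_", av_locations[l])]] <- map_feat[l]
    }
    for (a in seq_len(model$n_actions)) {
      row[[paste0("G_", av_locations[a] %||% a)]] <- G[a]
    }
    rows[[t]] <- row
  }
  record <- dplyr::bind_rows(rows)
  structure(list(record = record, beliefs = beliefs, precision = pb,
                 observations = obs, actions = actions, model = model,
                 world = world, config = config),
            class = "av_trial")
}

#' @export
print.av_trial <- function(x, ...) {
  cat("<active-inference trial:", nrow(x$record), "saccades>\n")
  print(x$record, n = 6)
  invisible(x)
}

#' Posterior feature beliefs per location at the end of a trial
#'
#' @param trial An `av_trial`.
#' @return Named list of probability vectors over feature values, one per
#'   location (the smoothed marginals at the final timestep).
#' @export
final_feature_posteriors <- function(trial) {
  stopifnot(inherits(trial, "av_trial"))
  n_loc <- length(av_locations)
  out <- lapply(seq_len(n_loc), function(l) {
    m <- trial$beliefs$marginals[[l]]
    m[nrow(m), ]
  })
  stats::setNames(out, av_locations)
}
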