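#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trial record into long per-location form
#'
#' @param x An `av_trial`.
#' @param ... Unused.
#' @return Tibble with columns `epoch`, `step`, `fixation`, `outcome`,
#'   `location`, `zeta`, `map`.
#' @export
tidy.av_trial <- function(x, ...) {
  rec <- x$record
  zl <- tidyr::pivot_longer(
    rec[, c("epoch", "step", "fixation", "outcome",
            paste0("zeta_", av_locations))],
    cols = dplyr::starts_with("zeta_"),
    names_to = "location", names_prefix = "zeta_", values_to = "zeta"
  )
  ml <- tidyr::pivot_longer(
    rec[, c("step", paste0("map_", av_locations))],
    cols = dplyr::starts_with("map_"),
    names_to = "location", names_prefix = "map_", values_to = "map"
  )
  dplyr::left_join(zl, ml, by = c("step", "location"))
}

#' One-row summary of a trial
#'
#' @param x An `av_trial`.
#' @param ... Unused.
#' @return Tibble: saccade count, final free energy, convergence, and the
#'   range of final zeta across locations.
#' @export
glance.av_trial <- function(x, ...) {
  zeta <- expected_precision(x$precision)
  tibble::tibble(
    n_saccades = nrow(x$record),
    free_energy = x$beliefs$F,
    all_converged = all(x$record$converged),
    zeta_min = min(zeta), zeta_max = max(zeta)
  )
}

#' Signature summary of a single-level scenario
#'
#' @param x An `av_scenario`.
#' @param ... Unused.
#' @return One row: whether the final MAP posterior matches truth / prior at
#'   every location, at contradicted locations, and the extreme relative
#'   zeta changes at matched and contradicted locations.
#' @export
glance.av_scenario <- function(x, ...) {
  s <- scenario_location_summary(x)
  contr <- s[s$contradicted, ]
  match_ <- s[!s$contradicted, ]
  tibble::tibble(
    variant = x$variant,
    map_matches_truth = all(s$map == s$truth),
    map_matches_prior = all(s$map == s$believed),
    contradicted_follow_prior =
      if (nrow(contr)) all(contr$map == contr$believed) else NA,
    max_abs_dzeta_matched =
      if (nrow(match_)) max(abs(match_$delta_zeta_rel)) else NA_real_,
    min_dzeta_contradicted =
      if (nrow(contr)) min(contr$delta_zeta_rel) else NA_real_,
    max_dzeta_contradicted =
      if (nrow(contr)) max(contr$delta_zeta_rel) else NA_real_
  )
}

#' @rdname tidy.av_trial
#' @export
tidy.av_htrial <- function(x, ...) {
  x$scene_trace
}

#' One-row summary of a hierarchical trial
#'
#' @param x An `av_htrial` (or `av_hscenario`).
#' @param ... Unused.
#' @return Tibble: epochs run, the MAP scene and its posterior mass, and the
#'   final zeta at each location.
#' @export
glance.av_htrial <- function(x, ...) {
  q <- as.numeric(x$scene_posterior)
  out <- tibble::tibble(
    n_epochs = max(x$record$epoch),
    map_scene = names(x$scene_posterior)[which.max(q)],
    map_scene_prob = max(q)
  )
  zeta <- expected_precision(x$precision)
  for (l in seq_along(zeta)) {
    out[[paste0("zeta_", names(zeta)[l])]] <- unname(zeta[l])
  }
  out
}
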