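#' Feature values and fixation locations of the foraging task
#'
#' Fixed orderings used throughout: feature values
#' `{white (absent), green, blue}` and locations
#' `{LL (lower-left), LR (lower-right), UL (upper-left), UR (upper-right)}`.
#' @name foraging_constants
#' @export
av_features <- c("white", "green", "blue")

#' @rdname foraging_constants
#' @export
av_locations <- c("LL", "LR", "UL", "UR")

#' Build the visual-foraging generative model
#'
#' Five hidden-state factors: one feature factor per location (three levels,
#' identity transitions, so prior confidence lives entirely in the
#' initial-state prior) and a controllable fixation factor (four levels,
#' action-deterministic transitions). Two modalities: a visual outcome that
#' reports the feature at the fixated location with probability
#' `visual_confidence` (remainder split over the other two values), modulated
#' by a per-location sensory precision; and a proprioceptive outcome that is
#' an identity mapping of fixation, never modulated.
#'
#' @param feature_priors Per-location priors over feature values: a single
#'   probability vector recycled to all four locations, or a list of four.
#'   Default uniform.
#' @param beta_prior Prior Gamma rate per location (prior expected precision
#'   `1 / beta_prior`). Default 1.
#' @param horizon Trial length in saccades. Default 10.
#' @param visual_confidence Probability that the visual outcome equals the
#'   fixated feature. `1` gives the fully deterministic mapping (delta
#'   columns); the default 0.9 leaves the small outcome noise that a finite
#'   sensory channel implies, which is what lets consistent evidence raise
#'   the inferred precision rather than leave it fixed.
#' @param start Initial fixation location label. Default `"LL"`.
#' @param policy_depth Policy lookahead. Default 1.
#' @return A validated `gen_model`.
#' @examples
#' m <- build_foraging_model()
#' m
#' @export
build_foraging_model <- function(feature_priors = NULL, beta_prior = 1,
                                 horizon = 10, visual_confidence = 0.9,
                                 start = "LL", policy_depth = 1) {
  nf <- length(av_features)
  nl <- length(av_locations)
  if (is.null(feature_priors)) {
    feature_priors <- rep(list(rep(1 / nf, nf)), nl)
  }
  if (!is.list(feature_priors)) feature_priors <- rep(list(feature_priors), nl)
  stopifnot(length(feature_priors) == nl)
  if (visual_confidence <= 1 / nf || visual_confidence > 1) {
    stop("build_foraging_model(): visual_confidence must be in (1/3, 1]",
         call. = FALSE)
  }
  feat_factors <- lapply(seq_len(nl), function(l) {
    state_factor(paste0("feat_", av_locations[l]), av_features,
                 feature_priors[[l]], diag(nf))
  })
  # saccades are realized faithfully: action u sends fixation to location u
  B_fix <- array(0, dim = c(nl, nl, nl))
  for (u in seq_len(nl)) B_fix[u, , u] <- 1
  start_idx <- match(start, av_locations)
  if (is.na(start_idx)) {
    stop("build_foraging_model(): unknown start location '", start, "'",
         call. = FALSE)
  }
  D_fix <- numeric(nl)
  D_fix[start_idx] <- 1
  fix_factor <- state_factor("fixation", av_locations, D_fix, B_fix,
                             controllable = TRUE)
  # visual likelihood: outcome matches the feature at the fixated location
  # with probability visual_confidence
  off <- (1 - visual_confidence) / (nf - 1)
  A_vis <- array(off, dim = c(nf, rep(nf, nl), nl))
  idx <- as.matrix(expand.grid(lapply(c(nf, rep(nf, nl), nl), seq_len),
                               KEEP.OUT.ATTRS = FALSE))
  fix_col <- idx[, nl + 2]
  feat_at_fix <- idx[cbind(seq_len(nrow(idx)), 1 + fix_col)]
  A_vis[idx[idx[, 1] == feat_at_fix, , drop = FALSE]] <- visual_confidence
  visual <- likelihood_mapping("visual", A_vis, outcomes = av_features,
                               parents = seq_len(nl + 1), modulated = TRUE,
                               precision_parent = nl + 1)
  proprio <- likelihood_mapping("proprioceptive", diag(nl),
                                outcomes = av_locations, parents = nl + 1)
  build_model(factors = c(feat_factors, list(fix_factor)),
              modalities = list(visual = visual, proprioceptive = proprio),
              precision = precision_belief(beta_prior, labels = av_locations),
              horizon = horizon, policy_depth = policy_depth)
}

#' True state of the visual scene (generative process)
#'
#' The world the synthetic subject forages: a fixed feature value at each
#' location (identity dynamics; the scene never changes within a trial) and
#' the current fixation.
#'
#' @param features Character vector of four feature values, named or in
#'   location order (LL, LR, UL, UR).
#' @param fixation Current fixation location label.
#' @return A `world_state` object.
#' @examples
#' w <- world_state(c(LL = "green", LR = "blue", UL = "white", UR = "white"))
#' @export
world_state <- function(features, fixation = "LL") {
  if (!is.null(names(features))) features <- features[av_locations]
  features <- unname(features)
  stopifnot(length(features) == length(av_locations))
  if (!all(features %in% av_features)) {
    stop("world_state(): unknown feature value(s): ",
         paste(setdiff(features, av_features), collapse = ", "), call. = FALSE)
  }
  if (!fixation %in% av_locations) {
    stop("world_state(): unknown fixation '", fixation, "'", call. = FALSE)
  }
  structure(list(features = stats::setNames(features, av_locations),
                 fixation = fixation),
            class = "world_state")
}

#' @export
print.world_state <- function(x, ...) {
  g <- matrix(x$features[c("UL", "UR", "LL", "LR")], 2, 2, byrow = TRUE,
              dimnames = list(c("upper", "lower"), c("left", "right")))
  cat("<world state> fixating", x$fixation, "\n")
  print(g, quote = FALSE)
  invisible(x)
}

#' Execute a saccade in the true world
#'
#' Deterministic and noiseless: fixation moves to the commanded location, the
#' visual outcome is the true feature there, and the proprioceptive outcome
#' reports the new fixation.
#'
#' @param world A [world_state()].
#' @param action Target location (integer index or label).
#' @return List with the new `world` and an `observations` integer vector
#'   `(visual, proprioceptive)` indexing [av_features] and [av_locations].
#' @export
step_world <- function(world, action) {
  stopifnot(inherits(world, "world_state"))
  if (is.character(action)) action <- match(action, av_locations)
  if (is.na(action) || action < 1 || action > length(av_locations)) {
    stop("step_world(): invalid saccade target", call. = FALSE)
  }
  loc <- av_locations[action]
  world$fixation <- loc
  obs <- c(visual = match(world$features[[loc]], av_features),
           proprioceptive = action)
  list(world = world, observations = obs)
}
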