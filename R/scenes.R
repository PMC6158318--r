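#' A visual scene hypothesis
#'
#' One second-level hidden state: a deterministic assignment of one feature
#' value to each of the four locations.
#'
#' @param id Scene identifier.
#' @param assignment Character vector of feature values, named by location or
#'   in location order.
#' @return A `scene` object.
#' @export
scene <- function(id, assignment) {
  if (!is.null(names(assignment))) assignment <- assignment[av_locations]
  assignment <- unname(assignment)
  stopifnot(length(assignment) == length(av_locations),
            all(assignment %in% av_features))
  structure(list(id = id,
                 assignment = stats::setNames(assignment, av_locations)),
            class = "scene")
}

#' An ordered library of scene hypotheses with a prior
#'
#' The support of second-level inference. Ordering is fixed at construction
#' so that scene indices are stable (lesions address scenes by index or id).
#'
#' @param scenes List of [scene()] objects (at least 2, distinct ids).
#' @param prior Probability vector over scenes; default uniform.
#' @return A `scene_library`.
#' @export
scene_library <- function(scenes, prior = NULL) {
  stopifnot(length(scenes) >= 2)
  for (s in scenes) stopifnot(inherits(s, "scene"))
  ids <- vapply(scenes, function(s) s$id, character(1))
  if (anyDuplicated(ids) > 0) {
    stop("scene_library(): duplicate scene ids", call. = FALSE)
  }
  prior <- prior %||% rep(1 / length(scenes), length(scenes))
  prior <- as.numeric(prior)
  if (!is_prob_vector(prior) || length(prior) != length(scenes)) {
    stop("scene_library(): prior is not a probability vector over the scenes",
         call. = FALSE)
  }
  structure(list(scenes = stats::setNames(scenes, ids),
                 prior = stats::setNames(prior, ids)),
            class = "scene_library")
}

#' @export
print.scene_library <- function(x, ...) {
  cat("<scene library:", length(x$scenes), "scenes>\n")
  for (i in seq_along(x$scenes)) {
    s <- x$scenes[[i]]
    cat(sprintf("  [%d] %-9s prior %.4f  %s\n", i, s$id, x$prior[i],
                paste(paste0(av_locations, "=", s$assignment),
                      collapse = " ")))
  }
  invisible(x)
}

#' The default eight-scene library
#'
#' One colored circle (green or blue) at one of the four locations, all other
#' locations white, with a uniform prior. Ordered LL-green, LL-blue,
#' LR-green, LR-blue, UL-green, UL-blue, UR-green, UR-blue, so every scene
#' index is well defined.
#'
#' @return A `scene_library` of 8 scenes.
#' @examples
#' default_scene_library()
#' @export
default_scene_library <- function() {
  scenes <- list()
  for (loc in av_locations) {
    for (col in c("green", "blue")) {
      a <- stats::setNames(rep("white", 4), av_locations)
      a[loc] <- col
      scenes <- c(scenes, list(scene(paste0(loc, "-", col), a)))
    }
  }
  scene_library(scenes)
}

#' Lesion a scene's prior
#'
#' Sets the prior probability of one scene hypothesis to zero and
#' renormalizes the remaining mass, simulating the loss of the neuronal
#' population encoding that hypothesis. The relative ratios of the untouched
#' scenes are preserved.
#'
#' @param library A `scene_library`.
#' @param id Scene id (character) or index (integer).
#' @return The lesioned `scene_library`.
#' @examples
#' lesion_scene_prior(default_scene_library(), "LL-green")
#' @export
lesion_scene_prior <- function(library, id) {
  stopifnot(inherits(library, "scene_library"))
  idx <- if (is.character(id)) match(id, names(library$scenes)) else as.integer(id)
  if (is.na(idx) || idx < 1 || idx > length(library$scenes)) {
    stop("lesion_scene_prior(): no scene '", id, "'", call. = FALSE)
  }
  p <- library$prior
  if (sum(p[-idx]) <= 0) {
    stop("lesion_scene_prior(): cannot lesion the only scene with positive ",
         "prior", call. = FALSE)
  }
  p[idx] <- 0
  library$prior <- p / sum(p)
  library
}

#' The true world corresponding to a scene
#'
#' @param scn A [scene()] (or a `scene_library` plus an id/index).
#' @param fixation Starting fixation.
#' @return A [world_state()].
#' @export
scene_world <- function(scn, fixation = "LL") {
  stopifnot(inherits(scn, "scene"))
  world_state(scn$assignment, fixation)
}
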