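#' Hidden-state factor
#'
#' One factor of the factorized hidden state: its level labels, an
#' initial-state prior (the `P(s1)` belief), a transition mapping, and a flag
#' marking the single controllable factor (fixation location in the foraging
#' task).
#'
#' @param name Factor name.
#' @param levels Character labels of the factor's levels.
#' @param D Initial-state prior; numeric probability vector over `levels`.
#' @param B A [transition_mapping()] (or matrix / 3-d array coerced to one).
#'   Controllable factors need one action slice per action; others one slice.
#' @param controllable Logical; do actions select this factor's transitions?
#' @return A `state_factor` object.
#' @export
state_factor <- function(name, levels, D, B, controllable = FALSE) {
  if (!inherits(B, "transition_mapping")) B <- transition_mapping(name, B)
  if (dim(B$B)[1] != length(levels)) {
    stop("state_factor('", name, "'): B dimension does not match levels",
         call. = FALSE)
  }
  D <- as.numeric(D)
  if (!is_prob_vector(D) || length(D) != length(levels)) {
    stop("state_factor('", name, "'): initial prior D is not a probability ",
         "vector over the factor's levels", call. = FALSE)
  }
  structure(list(name = name, levels = levels,
                 D = stats::setNames(D, levels), B = B,
                 controllable = isTRUE(controllable)),
            class = "state_factor")
}

#' Build and validate a generative model
#'
#' Assembles the discrete-state generative model
#' `P(o, s, pi, zeta) = P(pi) P(s1) P(zeta) * prod_t P(s_t+1 | s_t, pi) P(o_t | s_t, zeta)`:
#' a list of hidden-state factors (each with transition mapping and
#' initial-state prior), sensory modalities (each with a likelihood mapping),
#' outcome priors `C`, Gamma beliefs about sensory precision, and the time
#' horizon. Exactly one factor must be controllable; its number of levels
#' defines the action set (saccade targets).
#'
#' @param factors List of [state_factor()] objects.
#' @param modalities List of [likelihood_mapping()] objects.
#' @param C Optional list of outcome priors (one probability vector per
#'   modality). Default: uniform for every modality, so uncertainty
#'   resolution alone drives policy selection.
#' @param precision A [precision_belief()]; default a single Gamma(1, 1)
#'   component (prior expected precision 1).
#' @param horizon Number of discrete saccade steps in a trial.
#' @param policy_depth Lookahead depth of the policy space (action sequences
#'   of this length, re-evaluated each step). Default 1.
#' @return A validated `gen_model` object.
#' @examples
#' m <- build_model(
#'   factors = list(state_factor("where", c("a", "b"), c(0.5, 0.5),
#'                               diag(2), controllable = TRUE)),
#'   modalities = list(likelihood_mapping("sense", diag(2), c("a", "b"),
#'                                        parents = 1)),
#'   horizon = 3
#' )
#' @export
build_model <- function(factors, modalities, C = NULL,
                        precision = precision_belief(1),
                        horizon = 10, policy_depth = 1) {
  stopifnot(length(factors) >= 1, length(modalities) >= 1)
  for (f in factors) stopifnot(inherits(f, "state_factor"))
  for (m in modalities) stopifnot(inherits(m, "likelihood_mapping"))
  if (!inherits(precision, "precision_belief")) {
    stop("build_model(): 'precision' must be a precision_belief", call. = FALSE)
  }
  ctrl <- which(vapply(factors, function(f) f$controllable, logical(1)))
  if (length(ctrl) != 1) {
    stop("build_model(): exactly one factor must be controllable (got ",
         length(ctrl), ")", call. = FALSE)
  }
  n_levels <- vapply(factors, function(f) length(f$levels), integer(1))
  for (m in modalities) {
    if (any(m$parents < 1L) || any(m$parents > length(factors))) {
      stop("build_model(): modality '", m$name, "' references a missing ",
           "state factor", call. = FALSE)
    }
    expected <- c(length(m$outcomes), n_levels[m$parents])
    if (!identical(as.integer(dim(m$A)), as.integer(expected))) {
      stop("build_model(): modality '", m$name, "' likelihood array has dim [",
           paste(dim(m$A), collapse = ", "), "], expected [",
           paste(expected, collapse = ", "), "]", call. = FALSE)
    }
    if (!is.null(m$precision_parent)) {
      pp <- m$precision_parent
      if (pp < 1 || pp > length(m$parents)) {
        stop("build_model(): modality '", m$name, "' precision_parent out of ",
             "range", call. = FALSE)
      }
      if (n_levels[m$parents[pp]] != length(precision$beta_prior)) {
        stop("build_model(): modality '", m$name, "' needs one precision ",
             "component per level of its precision parent", call. = FALSE)
      }
    }
  }
  if (is.null(C)) {
    C <- lapply(modalities, function(m) {
      categorical_belief(rep(1 / length(m$outcomes), length(m$outcomes)),
                         m$outcomes)
    })
  }
  if (length(C) != length(modalities)) {
    stop("build_model(): need one outcome prior per modality", call. = FALSE)
  }
  C <- lapply(seq_along(C), function(g) {
    cg <- as.numeric(C[[g]])
    if (!is_prob_vector(cg) || length(cg) != length(modalities[[g]]$outcomes)) {
      stop("build_model(): outcome prior for modality '",
           modalities[[g]]$name, "' is not a probability vector", call. = FALSE)
    }
    stats::setNames(cg, modalities[[g]]$outcomes)
  })
  # actions: one per level of the controllable factor; non-controllable
  # factors must be action independent (single B slice)
  for (f in factors) {
    if (!f$controllable && dim(f$B$B)[3] != 1) {
      stop("build_model(): non-controllable factor '", f$name,
           "' must have action-independent transitions", call. = FALSE)
    }
  }
  n_actions <- n_levels[ctrl]
  if (dim(factors[[ctrl]]$B$B)[3] != n_actions) {
    stop("build_model(): controllable factor '", factors[[ctrl]]$name,
         "' needs one transition slice per action (", n_actions, ")",
         call. = FALSE)
  }
  names(factors) <- vapply(factors, function(f) f$name, character(1))
  names(modalities) <- vapply(modalities, function(m) m$name, character(1))
  names(C) <- names(modalities)
  structure(list(factors = factors, modalities = modalities, C = C,
                 precision = precision, horizon = as.integer(horizon),
                 policy_depth = as.integer(policy_depth),
                 controllable = ctrl, n_actions = n_actions),
            class = "gen_model")
}

#' @export
print.gen_model <- function(x, ...) {
  cat("<generative model>\n")
  cat("  factors:   ",
      paste(sprintf("%s[%d]%s", names(x$factors),
                    vapply(x$factors, function(f) length(f$levels), integer(1)),
                    ifelse(vapply(x$factors, function(f) f$controllable,
                                  logical(1)), "*", "")),
            collapse = ", "), "  (* = controllable)\n")
  cat("  modalities:",
      paste(sprintf("%s[%d]%s", names(x$modalities),
                    vapply(x$modalities, function(m) length(m$outcomes),
                           integer(1)),
                    ifelse(vapply(x$modalities, function(m) m$modulated,
                                  logical(1)), "~zeta", "")),
            collapse = ", "), "\n")
  cat("  horizon:", x$horizon, " policy depth:", x$policy_depth, "\n")
  cat("  precision beta (prior):",
      paste(format(x$precision$beta_prior), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a generative model to JSON
#'
#' Arrays round-trip at full double precision, so a written-then-read model
#' reproduces the original bit for bit.
#'
#' @param model A `gen_model`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "gen_model"))
  spec <- list(
    factors = lapply(model$factors, function(f) {
      list(name = f$name, levels = f$levels, D = unname(unclass(f$D)),
           B = list(dim = dim(f$B$B), values = as.numeric(f$B$B)),
           controllable = f$controllable)
    }),
    modalities = lapply(model$modalities, function(m) {
      list(name = m$name, outcomes = m$outcomes, parents = m$parents,
           modulated = m$modulated,
           precision_parent = m$precision_parent,
           A = list(dim = dim(m$A), values = as.numeric(m$A)))
    }),
    C = lapply(model$C, unname),
    precision = list(beta_prior = unname(model$precision$beta_prior),
                     beta_posterior = unname(model$precision$beta_posterior),
                     labels = model$precision$labels),
    horizon = model$horizon, policy_depth = model$policy_depth
  )
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a generative model from JSON
#'
#' @param path File written by [write_model()].
#' @return A validated `gen_model`.
#' @export
read_model <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyMatrix = FALSE)
  factors <- lapply(spec$factors, function(f) {
    state_factor(f$name, f$levels, f$D,
                 array(f$B$values, dim = f$B$dim),
                 controllable = isTRUE(f$controllable))
  })
  modalities <- lapply(spec$modalities, function(m) {
    pp <- m$precision_parent
    if (length(pp) == 0) pp <- NULL
    likelihood_mapping(m$name, array(m$A$values, dim = m$A$dim),
                       outcomes = m$outcomes, parents = m$parents,
                       modulated = isTRUE(m$modulated),
                       precision_parent = pp)
  })
  build_model(factors, modalities, C = spec$C,
              precision = precision_belief(spec$precision$beta_prior,
                                           spec$precision$beta_posterior,
                                           spec$precision$labels),
              horizon = spec$horizon, policy_depth = spec$policy_depth)
}
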