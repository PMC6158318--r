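#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the inferred sensory precision over a trial
#'
#' One line per location, mirroring the precision line plots of the task's
#' standard figures. Epoch boundaries (hierarchical records) are drawn as
#' dashed verticals.
#'
#' @param object An `av_trial` (or `av_htrial` record via
#'   [autoplot.av_htrial()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.av_trial <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$zeta,
                                  colour = .data$location)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "saccade", y = expression(zeta ~ "(expected precision)"),
                  colour = "location") +
    ggplot2::theme_minimal()
}

#' Plot scene beliefs and precision across epochs
#'
#' Upper panel: the belief over scene hypotheses after each epoch (rows =
#' scenes, shading = posterior probability). Lower panel is available via
#' [plot_precision_trace()].
#'
#' @param object An `av_htrial`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.av_htrial <- function(object, ...) {
  d <- object$scene_trace
  d$scene <- factor(d$scene, levels = rev(names(object$library$scenes)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$scene,
                                  fill = .data$posterior)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "epoch", y = NULL, fill = "Q(scene)") +
    ggplot2::theme_minimal()
}

#' Precision trajectories of a hierarchical record
#'
#' @param htrial An `av_htrial`.
#' @return A ggplot of zeta per location against cumulative saccades, with
#'   epoch boundaries dashed.
#' @export
plot_precision_trace <- function(htrial) {
  rec <- htrial$record
  rec$t <- seq_len(nrow(rec))
  d <- tidyr::pivot_longer(rec[, c("t", "epoch", paste0("zeta_", av_locations))],
                           cols = dplyr::starts_with("zeta_"),
                           names_to = "location", names_prefix = "zeta_",
                           values_to = "zeta")
  bounds <- cumsum(rle(rec$epoch)$lengths)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$zeta,
                                  colour = .data$location)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = utils::head(bounds, -1) + 0.5,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "saccade (cumulative)",
                  y = expression(zeta ~ "(expected precision)")) +
    ggplot2::theme_minimal()
}

#' Tile plot of per-location feature beliefs
#'
#' @param posteriors Named list of per-location probability vectors (e.g.
#'   [final_feature_posteriors()]), or a list of priors.
#' @param title Plot title.
#' @return A ggplot: locations on a 2x2 grid, one tile per feature value,
#'   alpha = probability.
#' @export
plot_feature_beliefs <- function(posteriors, title = "feature beliefs") {
  d <- dplyr::bind_rows(lapply(av_locations, function(loc) {
    tibble::tibble(location = loc, feature = av_features,
                   prob = as.numeric(posteriors[[loc]]))
  }))
  d$col <- ifelse(d$feature == "white", "grey70", d$feature)
  d$x <- ifelse(grepl("L$", d$location), 1, 2)
  d$y <- ifelse(grepl("^L", d$location), 1, 2)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x + (match(d$feature, av_features) - 2) * 0.28,
                                  y = .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$col, alpha = .data$prob),
                       width = 0.25, height = 0.8) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_alpha_identity() +
    ggplot2::geom_text(ggplot2::aes(label = .data$location),
                       data = dplyr::distinct(d, .data$location, .data$x, .data$y),
                       nudge_y = 0.45, size = 3) +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @importFrom rlang .data
NULL
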