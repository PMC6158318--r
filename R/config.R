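#' Inference configuration
#'
#' Numerical settings for belief updating. Defaults are the package's study
#' conditions; every scenario runner threads one of these through.
#'
#' @param kappa Learning rate of the precision (beta) gradient update.
#' @param precision_steps Gradient steps on beta per new observation.
#' @param beta_min Lower clip for the posterior beta rate (keeps zeta finite).
#' @param eps Probability floor applied before logarithms.
#' @param max_sweeps Maximum coordinate sweeps of the state update.
#' @param tol Convergence threshold on the largest marginal change per sweep.
#' @param gamma Policy precision: inverse temperature of `softmax(-gamma G)`.
#'   Fixed at 1; only the sensory precision is inferred.
#' @param tie_tol Two expected free energies closer than this are treated as
#'   tied and broken toward the lowest location index.
#' @return A list of class `av_config`.
#' @export
av_config <- function(kappa = 0.2, precision_steps = 4, beta_min = 1e-6,
                      eps = 1e-16, max_sweeps = 16, tol = 1e-4, gamma = 1,
                      tie_tol = 1e-9) {
  structure(list(kappa = kappa, precision_steps = precision_steps,
                 beta_min = beta_min, eps = eps, max_sweeps = max_sweeps,
                 tol = tol, gamma = gamma, tie_tol = tie_tol),
            class = "av_config")
}
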