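# SOLVE -> ESTIMATE -> MARK -> REFINE loop.  The a-posteriori estimator is
# the weighted collocation residual (momentum + continuity) per node; bulk
# (Doerfler) marking selects the smallest node set carrying a fraction
# theta of the squared estimator, and refinement halves the target spacing
# in a disk around each marked node by adding constraints to the spacing
# field before re-discretizing.

#' Adaptively refined Stokes solve
#'
#' Runs the solve / estimate / mark / refine loop until the global residual
#' estimator drops below `target_estimate` or `max_iter` iterations are
#' exhausted (an error in the latter case, carrying the last estimate).
#'
#' @param domain A [fluid_domain()].
#' @param bodies List of [rigid_body()] objects.
#' @param config A [gmls_config()].
#' @param target_estimate Stopping threshold for the global estimator
#'   (nondimensional residual norm).
#' @param initial_spacing Background spacing of the first iterate.
#' @param max_iter Maximum refinement iterations (default 8).
#' @param theta Doerfler bulk-marking fraction (default 0.5).
#' @param ... Passed to [solve_stokes()] (e.g. `wall_omega`, `body_omega`).
#' @inheritParams discretize
#' @return A `stokes_solution` whose `refinement_history` tibble records the
#'   estimator and node count per iteration.
#' @export
adaptive_solve <- function(domain, bodies, config = gmls_config(),
                           target_estimate, initial_spacing,
                           max_iter = 8, theta = 0.5,
                           slope = 0.3, gap_divisor = 4, ...) {
  constraints <- list()
  history <- tibble::tibble(iteration = integer(), estimator = numeric(),
                            n_nodes = integer())
  sol <- NULL
  for (it in seq_len(max_iter)) {
    nodes <- discretize(domain, bodies, initial_spacing, config = config,
                        slope = slope, gap_divisor = gap_divisor,
                        extra_refine = constraints)
    sol <- solve_stokes(nodes, domain, bodies, config = config, ...)
    est <- sol$residuals$estimator
    history <- dplyr::bind_rows(history, tibble::tibble(
      iteration = it, estimator = est, n_nodes = nrow(nodes)))
    if (est <= target_estimate) {
      sol$refinement_history <- history
      return(sol)
    }
    eta2 <- sol$residuals$eta^2
    ord <- order(eta2, decreasing = TRUE)
    csum <- cumsum(eta2[ord])
    nmark <- which(csum >= theta * sum(eta2))[1]
    marked <- ord[seq_len(nmark)]
    for (i in marked) {
      constraints[[length(constraints) + 1]] <-
        c(nodes$x[i], nodes$y[i], nodes$spacing[i] / 2)
    }
  }
  rlang::abort(
    sprintf("adaptive refinement exhausted %d iterations (estimator %.3g > target %.3g)",
            max_iter, history$estimator[nrow(history)], target_estimate),
    class = "zorbkit_adaptive_exhausted",
    estimator = history$estimator[nrow(history)],
    history = history)
}
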