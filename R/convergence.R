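# Manufactured-solution convergence study for the meshfree Stokes solver.

#' Smooth manufactured Stokes solution on the unit drop
#'
#' A divergence-free velocity built from a stream function
#' `psi = sin(1.3 x + 0.4) * cos(0.9 y - 0.2)` with pressure
#' `p = cos(1.1 x) * sin(0.7 y)`, plus the momentum forcing that makes the
#' pair an exact solution of the (dimensionless) Stokes equations.  When
#' `polynomial = TRUE` a divergence-free quartic field is returned instead,
#' which an order-4 discretization reproduces to machine precision.
#'
#' @param polynomial Use the in-basis quartic variant.
#' @return A list of vectorized functions `u(x,y)`, `v(x,y)`, `p(x,y)`,
#'   `forcing(x,y)`.
#' @export
manufactured_solution <- function(polynomial = FALSE) {
  if (polynomial) {
    # psi = x^2 y^3 -> u = 3 x^2 y^2, v = -2 x y^3 (divergence-free quartic)
    u <- function(x, y) 3 * x^2 * y^2
    v <- function(x, y) -2 * x * y^3
    p <- function(x, y) x^3 - 3 * x * y^2   # harmonic cubic
    forcing <- function(x, y) {
      # grad p - lap u ; lap u = (6 y^2 + 6 x^2, -12 x y)
      cbind(3 * x^2 - 3 * y^2 - (6 * y^2 + 6 * x^2),
            -6 * x * y - (-12 * x * y))
    }
  } else {
    a <- 1.3; b <- 0.4; c <- 0.9; d <- -0.2
    psi_u <- function(x, y) -c * sin(a * x + b) * sin(c * y + d)   # d(psi)/dy
    psi_v <- function(x, y) -a * cos(a * x + b) * cos(c * y + d)   # -d(psi)/dx
    u <- psi_u; v <- psi_v
    p <- function(x, y) cos(1.1 * x) * sin(0.7 * y)
    forcing <- function(x, y) {
      lap_u <- (a^2 + c^2) * c * sin(a * x + b) * sin(c * y + d)
      lap_v <- (a^2 + c^2) * a * cos(a * x + b) * cos(c * y + d)
      cbind(-1.1 * sin(1.1 * x) * sin(0.7 * y) - lap_u,
            0.7 * cos(1.1 * x) * cos(0.7 * y) - lap_v)
    }
  }
  list(u = u, v = v, p = p, forcing = forcing)
}

#' Observed convergence order of the solver
#'
#' Solves the manufactured problem on a sequence of spacings and fits the
#' least-squares slope of `log(error)` against `log(spacing)`.
#'
#' @param spacings Decreasing sequence (>= 3 values) in geometric
#'   progression.
#' @param config A [gmls_config()].
#' @param manufactured A [manufactured_solution()] list.
#' @param norm `"max"` or `"l2"` velocity error at interior nodes.
#' @return A list: `table` (tibble of spacing, error), `order` (fitted
#'   slope), `monotone` (logical; a warning is raised when errors are not
#'   monotonically decreasing).
#' @export
convergence_order <- function(spacings, config = gmls_config(),
                              manufactured = manufactured_solution(),
                              norm = c("max", "l2")) {
  norm <- match.arg(norm)
  if (length(spacings) < 3) rlang::abort("need at least 3 spacings")
  dom <- fluid_domain(1, nu = 1, rho = 1, units = "dimensionless")
  errs <- vapply(spacings, function(h) {
    nodes <- discretize(dom, list(), h, config = config)
    sol <- solve_stokes(nodes, dom, list(), config = config,
                        forcing = manufactured$forcing,
                        wall_velocity = function(x, y)
                          cbind(manufactured$u(x, y), manufactured$v(x, y)))
    iq <- nodes$kind == "fluid"
    du <- sol$u[iq] - manufactured$u(nodes$x[iq], nodes$y[iq])
    dv <- sol$v[iq] - manufactured$v(nodes$x[iq], nodes$y[iq])
    if (norm == "max") max(abs(c(du, dv))) else sqrt(mean(du^2 + dv^2))
  }, numeric(1))
  monotone <- all(diff(errs[order(spacings, decreasing = TRUE)]) < 0)
  if (!monotone) rlang::warn("convergence errors are not monotone")
  fit <- stats::lm(log(errs) ~ log(spacings))
  list(table = tibble::tibble(spacing = spacings, error = errs),
       order = unname(stats::coef(fit)[2]), monotone = monotone)
}
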