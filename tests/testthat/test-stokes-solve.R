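# Solver checks against closed-form Stokes solutions.  The geometry for
# most cases is a rotating disk inside the drop (Taylor-Couette), whose
# azimuthal velocity and wall torque are known exactly.

tc_setup <- function(h = 0.05) {
  dom <- fluid_domain(1, nu = 1, rho = 1, units = "dimensionless")
  body <- rigid_body(1L, "disk", position = c(0, 0), radius = 0.25)
  nodes <- discretize(dom, list(body), h)
  list(dom = dom, body = body, nodes = nodes)
}

test_that("zero boundary data gives the quiescent solution exactly", {
  s <- tc_setup(0.1)
  sol <- solve_stokes(s$nodes, s$dom, list(s$body))
  expect_true(all(sol$u == 0) && all(sol$v == 0))
  expect_true(all(sol$p_hat == 0))
  fn <- traction_force(sol, s$body)
  expect_equal(fn$fx_N, 0)
  expect_equal(fn$fy_N, 0)
  expect_equal(fn$tz_Nm, 0)
})

test_that("a rotating disk in the drop reproduces the Couette profile", {
  s <- tc_setup(0.025)
  sol <- solve_stokes(s$nodes, s$dom, list(s$body), body_omega = c(`1` = 1))
  iq <- which(s$nodes$kind == "fluid")
  r <- sqrt(s$nodes$x[iq]^2 + s$nodes$y[iq]^2)
  uth_ex <- 0.25^2 * (1 / r - r) / (1 - 0.25^2)
  uth <- (s$nodes$x[iq] * sol$v[iq] - s$nodes$y[iq] * sol$u[iq]) / r
  probe <- r > 0.3 & r < 0.9
  expect_lt(max(abs(uth[probe] - uth_ex[probe])) / max(abs(uth_ex)), 0.005)
  # torque per depth on the inner disk: 4 pi mu w a^2 b^2 / (b^2 - a^2)
  fn <- traction_force(sol, s$body)
  T_ex <- -4 * pi * 0.25^2 / (1 - 0.25^2)
  expect_lt(abs(fn$tz_Nm - T_ex) / abs(T_ex), 0.01)
  # no-slip is eliminated exactly
  expect_equal(sol$residuals$bc, 0)
})

test_that("velocity reconstructions are divergence-free to machine precision", {
  s <- tc_setup(0.06)
  sol <- solve_stokes(s$nodes, s$dom, list(s$body), body_omega = c(`1` = 1))
  expect_lt(sol$residuals$divfree, 1e-8)
})

test_that("drag is exactly linear in speed and viscosity", {
  dom <- fluid_domain(1, nu = 1, rho = 1, units = "dimensionless")
  body <- rigid_body(1L, "disk", position = c(0.1, 0), radius = 0.2,
                     velocity = c(1, 0))
  nodes <- discretize(dom, list(body), 0.07)
  f1 <- traction_force(solve_stokes(nodes, dom, list(body)), body)
  body2 <- rigid_body(1L, "disk", position = c(0.1, 0), radius = 0.2,
                      velocity = c(3, 0))
  f3 <- traction_force(solve_stokes(nodes, dom, list(body2)), body2)
  expect_equal(f3$fx_N, 3 * f1$fx_N, tolerance = 1e-8)
  expect_equal(f3$fy_N, 3 * f1$fy_N, tolerance = 1e-6)
  dom5 <- fluid_domain(1, nu = 5, rho = 1, units = "dimensionless")
  f5 <- traction_force(solve_stokes(nodes, dom5, list(body)), body)
  expect_equal(f5$fx_N, 5 * f1$fx_N, tolerance = 1e-8)
})

test_that("forces flip exactly under point reflection of the whole scene", {
  # two identical disks with opposite velocities: solving the scene and its
  # point-reflected image (identical node cloud, reflected) must give
  # forces equal in magnitude and opposite in direction
  dom <- fluid_domain(1, nu = 1, rho = 1, units = "dimensionless")
  b1 <- rigid_body(1L, "disk", position = c(-0.35, 0), radius = 0.15,
                   velocity = c(1, 0))
  b2 <- rigid_body(2L, "disk", position = c(0.35, 0), radius = 0.15,
                   velocity = c(-1, 0))
  nodes <- discretize(dom, list(b1, b2), 0.07)
  sol <- solve_stokes(nodes, dom, list(b1, b2))
  f1 <- traction_force(sol, b1)
  f2 <- traction_force(sol, b2)
  # reflected scene on the reflected cloud
  nodes_r <- nodes
  nodes_r$x <- -nodes$x; nodes_r$y <- -nodes$y
  nodes_r$nx <- -nodes$nx; nodes_r$ny <- -nodes$ny
  b1r <- rigid_body(1L, "disk", position = c(0.35, 0), radius = 0.15,
                    velocity = c(-1, 0))
  b2r <- rigid_body(2L, "disk", position = c(-0.35, 0), radius = 0.15,
                    velocity = c(1, 0))
  sol_r <- solve_stokes(nodes_r, dom, list(b1r, b2r))
  f1r <- traction_force(sol_r, b1r)
  expect_equal(f1r$fx_N, -f1$fx_N, tolerance = 1e-6)
  expect_equal(f1r$fy_N, -f1$fy_N, tolerance = 1e-4)
  # the continuous problem is antisymmetric: the two bodies' forces are
  # opposite up to discretization error
  expect_lt(abs(f1$fx_N + f2$fx_N) / abs(f1$fx_N), 0.05)
})

test_that("a free neutrally-buoyant disk in a quiescent drop stays at rest", {
  dom <- fluid_domain(1, nu = 1, rho = 1, units = "dimensionless")
  body <- rigid_body(1L, "disk", position = c(0.1, 0.1), radius = 0.2,
                     velocity = "free")
  nodes <- discretize(dom, list(body), 0.08)
  sol <- solve_stokes(nodes, dom, list(body), mode = "mobility")
  expect_lt(max(abs(sol$body_velocities$vx), abs(sol$body_velocities$vy)), 1e-8)
  fn <- traction_force(sol, body)
  expect_lt(abs(fn$fx_N) + abs(fn$fy_N), 1e-8)
})

test_that("drag on a disk grows as the drop shrinks (wall effect)", {
  drag_at <- function(R) {
    dom <- fluid_domain(R, nu = 1, rho = 1, units = "dimensionless")
    body <- rigid_body(1L, "disk", position = c(0, 0), radius = 0.2,
                       velocity = c(1, 0))
    nodes <- discretize(dom, list(body), R / 14)
    abs(traction_force(solve_stokes(nodes, dom, list(body)), body)$fx_N)
  }
  d <- vapply(c(2, 1, 0.6), drag_at, numeric(1))
  expect_true(all(diff(d) > 0))
})
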