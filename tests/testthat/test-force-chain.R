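test_that("stroking force scales the gliding force by the contact-area ratio", {
  g <- cell_geometry(6.7, 0.716)
  expect_equal(g$S_L, 6.7 * 0.716)
  expect_equal(g$S_W, pi * 0.358^2)
  expect_equal(g$area_ratio, pi * 0.716 / (4 * 6.7))
  # square-aspect limit
  expect_equal(stroking_force(1, cell_geometry(2, 2)), pi / 4)
  # the printed force pair: 5.48 fN -> 0.46 fN with the 6.7 um cell
  fs <- stroking_force(5.48e-15, cell_geometry(6.7, 0.716))
  expect_equal(fs, 0.46e-15, tolerance = 5e-3)
  expect_equal(stroking_force(0, g), 0)
  expect_error(stroking_force(-1, g))
  expect_error(cell_geometry(1, 2))
})

test_that("base-cell scaling models evaluate and round as printed", {
  pf <- scaling_model("power_fit")
  bc <- base_cell_count(50, pf)
  expect_equal(bc$expected, 0.2 * 50^1.36)
  expect_equal(round(bc$expected, 1), 40.9)
  expect_equal(bc$count, 41L)
  # hypothesis A with the printed 0.05 coefficient at D = 10
  expect_equal(0.05 * 10^2, 5)
  hA <- scaling_model("hypothesis_A")
  expect_equal(base_cell_count(10, hA)$expected,
               0.25 * pi * (0.48 * 10 / 2)^2)
  # hypothesis B
  hB <- scaling_model("hypothesis_B")
  expect_equal(base_cell_count(10, hB)$expected, 2.5)
  expect_error(base_cell_count(0, pf))
})

test_that("hypothesis A coefficient and density invert each other", {
  cA <- hypothesisA_coefficient(0.25, 0.48)
  expect_equal(round(cA, 2), 0.05)
  expect_equal(cA, 0.25 * pi * 0.24^2)
  expect_equal(hypothesisA_coefficient(0, 0.48), 0)
  # round trip n -> N -> n at several diameters
  for (D in c(5, 10, 37, 80)) {
    N <- hypothesisA_coefficient(0.25, 0.48) * D^2
    expect_equal(base_cell_density(N, D, 0.48), 0.25, tolerance = 1e-12)
  }
  expect_equal(base_cell_density(0, 10), 0)
  expect_error(base_cell_density(1, 0))
})

test_that("the density resolved from the fitted law at D = 10 is 0.25", {
  N10 <- base_cell_count(10, scaling_model("power_fit"))$expected
  n <- base_cell_density(N10, 10, 0.48)
  expect_equal(round(n, 2), 0.25)
  # one base cell per ~4 um^2
  expect_equal(round(1 / n), 4)
})

test_that("maximum propulsion and NFP reproduce the printed chain", {
  expect_equal(max_prop_force(0.46e-15, 41), 18.86e-15)
  expect_equal(max_prop_force(1, 0), 0)
  expect_equal(max_prop_force(2e-15, 10), 2 * max_prop_force(1e-15, 10))
  r <- nfp(7.38e-15, 18.86e-15, sd = 4.79e-15)
  expect_equal(round(r$nfp_percent, 1), 39.1)
  expect_equal(round(r$nfp_sd_percent, 1), 25.4)
  expect_equal(nfp(5, 5)$nfp_percent, 100)
  expect_equal(nfp(0, 5)$nfp_percent, 0)
  expect_error(nfp(1, 0))
})

test_that("the full chain from printed intermediates gives NFP 39.1 +/- 25.4", {
  ch <- force_chain(5.48e-15, cell_geometry(6.7, 0.716),
                    scaling_model("power_fit"), D = 50,
                    F_prop = 7.38e-15, F_prop_sd = 4.79e-15)
  expect_equal(ch$N_base, 41L)
  expect_equal(round(ch$nfp_percent, 1), 39.1, tolerance = 2e-3)
  expect_equal(round(ch$nfp_sd_percent, 1), 25.4, tolerance = 2e-3)
  td <- tidy(ch)
  expect_equal(td$estimate[td$term == "NFP"], ch$nfp_percent)
})

test_that("NFP is invariant to common rescaling of both forces", {
  set.seed(3)
  for (k in 1:20) {
    s <- exp(rnorm(1))
    base <- nfp(7.38e-15, 18.86e-15)$nfp_percent
    expect_equal(nfp(7.38e-15 * s, 18.86e-15 * s)$nfp_percent, base,
                 tolerance = 1e-12)
  }
})

test_that("NFP doubles when the colony velocity doubles under linear drag", {
  ch1 <- force_chain(5.48e-15, cell_geometry(6.7, 0.716),
                     scaling_model("power_fit"), 50, 7.38e-15)
  ch2 <- force_chain(5.48e-15, cell_geometry(6.7, 0.716),
                     scaling_model("power_fit"), 50, 2 * 7.38e-15)
  expect_equal(ch2$nfp_percent, 2 * ch1$nfp_percent)
})

test_that("hypothesis B predicts size-independent Stokes-law velocity", {
  hB <- scaling_model("hypothesis_B")
  pf <- scaling_model("power_fit")
  D <- c(10, 30, 50, 80, 100)
  vB <- base_cell_count(D, hB)$expected / D     # v ~ N / D
  vP <- base_cell_count(D, pf)$expected / D
  expect_equal(diff(range(vB)), 0, tolerance = 1e-14)
  expect_true(all(diff(vP) > 0))                # b > 1: speed grows with size
})

test_that("chains computed under different depth scales refuse to combine", {
  gl <- tibble::tibble(fx_N = 5.48e-15, fy_N = 0)
  co <- tibble::tibble(fx_N = 7.38e-15, fy_N = 0)
  expect_error(chain_from_scene(gl, co, cell_geometry(6.7, 0.716),
                                scaling_model("power_fit"), 50,
                                v_glide = 2, v_colony = 0.031,
                                depth_scale_glide = 1, depth_scale_colony = 2),
               "depth_scale")
  ch <- chain_from_scene(gl, co, cell_geometry(6.7, 0.716),
                         scaling_model("power_fit"), 50,
                         v_glide = 2, v_colony = 0.031, v_colony_sd = 0.021)
  expect_equal(ch$F_prop_sd_N, 7.38e-15 * 0.021 / 0.031)
})

test_that("the NFP pipeline varies smoothly and stays finite across sizes", {
  # solver drag at the measured mean speed for single colonies of several
  # diameters, pushed through the chain with the fitted scaling law
  geom <- cell_geometry(6.7, 0.716)
  model <- scaling_model("power_fit")
  Fs <- stroking_force(5.48e-15, geom)
  nfps <- vapply(c(10, 40, 80), function(D) {
    dom <- fluid_domain(300)
    body <- rigid_body(1L, "disk", position = c(0, 0), radius = D / 2,
                       velocity = c(0.031, 0))
    nodes <- discretize(dom, list(body), 25)
    # coarse surfaces are fine here: only smooth variation is asserted
    fr <- suppressWarnings(
      traction_force(solve_stokes(nodes, dom, list(body)), body))
    Fp <- sqrt(fr$fx_N^2 + fr$fy_N^2)
    nfp(Fp, max_prop_force(Fs, base_cell_count(D, model)$count))$nfp_percent
  }, numeric(1))
  expect_true(all(is.finite(nfps) & nfps > 0))
  # N grows faster than drag, so the percentage falls smoothly with size
  expect_true(all(diff(nfps) < 0))
})
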