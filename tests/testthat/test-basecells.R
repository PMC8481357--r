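test_that("a blank image has zero base cells", {
  res <- count_base_cells(matrix(0, 64, 64), prominence = 0.2)
  expect_equal(res$n, 0)
  expect_error(count_base_cells(matrix(0, 8, 8)), "prominence")
})

test_that("synthetic spots of known prominence are counted and localized", {
  # hypothesis-B law at D = 80 gives exactly 20 well-separated spots
  g <- gen_basecell_image(80, law = scaling_model("hypothesis_B"),
                          noise = "none", seed = 4, snr = 0)
  expect_equal(g$n_true, 20L)
  res <- count_base_cells(g$image, prominence = 0.25, D = 80, roi = FALSE)
  expect_equal(res$n, g$n_true)
  # each detection within 1 px of a true spot
  for (k in seq_len(res$n)) {
    d <- sqrt((g$coordinates$x_px - res$coordinates$x_px[k])^2 +
              (g$coordinates$y_px - res$coordinates$y_px[k])^2)
    expect_lte(min(d), 1.5)
  }
})

test_that("two peaks closer than the prominence ridge collapse to one", {
  mk <- function(sep) {
    img <- matrix(0, 64, 64)
    ax <- seq_len(64)
    for (cx in c(32 - sep / 2, 32 + sep / 2)) {
      img <- img + outer(exp(-(ax - cx)^2 / (2 * 2^2)),
                         exp(-(ax - 32)^2 / (2 * 2^2)))
    }
    img / max(img)
  }
  far <- count_base_cells(mk(14), prominence = 0.3, bg_radius = 20)
  near <- count_base_cells(mk(3), prominence = 0.3, bg_radius = 20)
  expect_equal(far$n, 2)
  expect_equal(near$n, 1)
})

test_that("power-law fit recovers exact data to machine precision", {
  D <- seq(10, 100, by = 10)
  N <- 0.2 * D^1.36
  f <- suppressWarnings(fit_power_law(D, N))   # exact data: lm warns
  expect_equal(f$a, 0.2, tolerance = 1e-10)
  expect_equal(f$b, 1.36, tolerance = 1e-10)
  # constant counts give a flat exponent
  f0 <- suppressWarnings(fit_power_law(D, rep(7, 10) * exp(rnorm(10, 0, 1e-12))))
  expect_equal(f0$b, 0, tolerance = 1e-6)
  expect_error(fit_power_law(c(1, 2), c(1, 2)))
  expect_error(fit_power_law(c(-1, 2, 3), c(1, 2, 3)))
})

test_that("the fit is scale-equivariant in D", {
  set.seed(13)
  D <- runif(40, 10, 100)
  N <- 0.2 * D^1.36 * exp(rnorm(40, 0, 0.2))
  f1 <- fit_power_law(D, N)
  k <- 3.7
  f2 <- fit_power_law(k * D, N)
  expect_equal(f2$b, f1$b, tolerance = 1e-10)
  expect_equal(f2$a, f1$a * k^(-f1$b), tolerance = 1e-10)
})

test_that("log-log and nonlinear fits agree on low-noise data", {
  set.seed(17)
  D <- runif(60, 10, 100)
  N <- 0.2 * D^1.36 * exp(rnorm(60, 0, 0.05))
  f1 <- fit_power_law(D, N)
  f2 <- fit_power_law(D, N, method = "nls")
  expect_equal(f1$b, f2$b, tolerance = 0.05)
  expect_equal(tidy(f1)$term, c("a", "b"))
  expect_true(glance(f1)$r.squared > 0.95)
})

test_that("counting plus fitting recovers the generator exponent", {
  set.seed(31)
  Ds <- runif(40, 20, 95)
  ns <- integer(0); ds <- numeric(0)
  for (i in seq_along(Ds)) {
    g <- gen_basecell_image(Ds[i], noise = "poisson", seed = 1000 + i, snr = 0)
    if (g$n_true == 0) next
    res <- count_base_cells(g$image, prominence = 0.22, D = Ds[i], roi = FALSE)
    if (res$n > 0) { ns <- c(ns, res$n); ds <- c(ds, Ds[i]) }
  }
  f <- fit_power_law(ds, ns)
  expect_equal(f$b, 1.36, tolerance = 0.25)
})
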