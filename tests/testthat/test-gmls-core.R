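test_that("compact-support weight matches the kernel formula", {
  expect_equal(gmls_weight(0, 1), 1)
  expect_equal(gmls_weight(1, 1), 0)          # support edge excluded
  expect_equal(gmls_weight(0.5, 1), 0.9375)   # 1 - (1/2)^4
  expect_equal(gmls_weight(2, 1), 0)
  expect_error(gmls_weight(-0.1, 1))
  expect_error(gmls_weight(0.1, 0))
  # positivity and bounds inside the support
  r <- seq(0, 0.999, length.out = 50)
  w <- gmls_weight(r, 1)
  expect_true(all(w > 0 & w <= 1))
})

test_that("neighbourhoods match a brute-force all-pairs scan", {
  cfg <- gmls_config(order = 2, min_neighbors = 6)
  nodes <- random_cloud(200, support = 0.2, seed = 42, config = cfg)
  nb <- build_neighborhoods(nodes, cfg, min_neighbors = 1)
  oracle <- brute_neighbors(cbind(nodes$x, nodes$y), nodes$support)
  for (i in seq_along(nb)) {
    expect_setequal(nb[[i]]$neighbor_indices, oracle[[i]])
    expect_true(all(nb[[i]]$distances < nodes$support[i]))
    expect_true(all(nb[[i]]$weights > 0 & nb[[i]]$weights <= 1))
  }
})

test_that("three collinear points give the middle node two neighbours", {
  cfg <- gmls_config(order = 1)
  nodes <- gmls_nodes(cbind(c(0, 1, 2), 0), rep("fluid", 3),
                      spacing = 1, support = 1.5, config = cfg)
  nb <- build_neighborhoods(nodes, cfg, min_neighbors = 1)
  expect_equal(sort(nb[[2]]$neighbor_indices), c(1, 3))
  expect_equal(length(nb[[1]]$neighbor_indices), 1)
})

test_that("an isolated node is a configuration error naming the node", {
  cfg <- gmls_config(order = 1, min_neighbors = 3)
  nodes <- gmls_nodes(cbind(0, 0), "fluid", spacing = 1, config = cfg)
  expect_error(build_neighborhoods(nodes, cfg), "node 1")
})

test_that("reconstruction reproduces in-basis polynomials exactly", {
  cfg <- gmls_config(order = 4)
  nodes <- random_cloud(400, support = 0.35, seed = 7, config = cfg)
  nb <- build_neighborhoods(nodes, cfg)
  i <- 200
  idx <- nb[[i]]$neighbor_indices
  # constant field
  rec <- gmls_reconstruct(nodes, nb[[i]], rep(3, length(idx)), cfg)
  expect_equal(apply_operator(rec, c(0, 0)), 3, tolerance = 1e-9)
  expect_lt(abs(apply_operator(rec, c(1, 0))), 1e-9)
  expect_lt(abs(apply_operator(rec, c(2, 1))), 1e-8)
  # random quartic: all derivatives to order 4 recovered
  set.seed(5)
  co <- rnorm(15)
  ex <- polynomial_basis(4, "scalar")$exponents
  q <- function(x, y) {
    rowSums(vapply(seq_len(15), function(k)
      co[k] * x^ex$i[k] * y^ex$j[k], numeric(length(x))))
  }
  samples <- q(nodes$x[idx], nodes$y[idx])
  rec <- gmls_reconstruct(nodes, nb[[i]], samples, cfg)
  x0 <- nodes$x[i]; y0 <- nodes$y[i]
  for (al in list(c(0, 0), c(1, 0), c(0, 1), c(2, 2), c(4, 0))) {
    exact <- sum(vapply(seq_len(15), function(k) {
      i1 <- ex$i[k]; j1 <- ex$j[k]
      if (i1 < al[1] || j1 < al[2]) return(0)
      co[k] * factorial(i1) / factorial(i1 - al[1]) * x0^(i1 - al[1]) *
        factorial(j1) / factorial(j1 - al[2]) * y0^(j1 - al[2])
    }, numeric(1)))
    expect_equal(apply_operator(rec, al), exact, tolerance = 1e-7)
  }
  expect_error(apply_operator(rec, c(3, 2)), "exceeds")
})

test_that("polynomial reproduction holds across many random clouds", {
  cfg <- gmls_config(order = 3)
  ex <- polynomial_basis(3, "scalar")$exponents
  for (s in 1:10) {
    nodes <- random_cloud(350, support = 0.4, seed = s, config = cfg)
    nb <- build_neighborhoods(nodes, cfg)
    i <- sample(350, 1)
    set.seed(s + 100)
    co <- rnorm(nrow(ex))
    idx <- nb[[i]]$neighbor_indices
    samples <- rowSums(vapply(seq_len(nrow(ex)), function(k)
      co[k] * nodes$x[idx]^ex$i[k] * nodes$y[idx]^ex$j[k],
      numeric(length(idx))))
    rec <- gmls_reconstruct(nodes, nb[[i]], samples, cfg)
    exact <- sum(vapply(seq_len(nrow(ex)), function(k)
      co[k] * nodes$x[i]^ex$i[k] * nodes$y[i]^ex$j[k], numeric(1)))
    expect_equal(apply_operator(rec, c(0, 0)), exact, tolerance = 1e-8)
  }
})

test_that("collinear neighbourhoods raise a degenerate-geometry error", {
  cfg <- gmls_config(order = 2, min_neighbors = 6)
  pos <- cbind(seq(0, 1, length.out = 15), 0)
  nodes <- gmls_nodes(pos, rep("fluid", 15), spacing = 0.07, support = 0.6,
                      config = cfg)
  nb <- build_neighborhoods(nodes, cfg, min_neighbors = 6)
  expect_error(
    gmls_reconstruct(nodes, nb[[8]], rnorm(length(nb[[8]]$neighbor_indices)), cfg),
    "degenerate")
})

test_that("gradient stencils gain roughly 4th-order accuracy under halving", {
  cfg <- gmls_config(order = 4)
  f <- function(x, y) sin(x) * cos(y)
  fx <- function(x, y) cos(x) * cos(y)
  err_at <- function(h) {
    g <- as.matrix(expand.grid(x = seq(-3.5 * h, 3.5 * h, by = h),
                               y = seq(-3.5 * h, 3.5 * h, by = h)))
    g <- g + 0.123 * h      # avoid exact symmetry
    nodes <- gmls_nodes(rbind(c(0, 0), g), rep("fluid", nrow(g) + 1),
                        spacing = h, support = 3.2 * h, config = cfg)
    nb <- build_neighborhoods(nodes, cfg, min_neighbors = 5)
    idx <- nb[[1]]$neighbor_indices
    rec <- gmls_reconstruct(nodes, nb[[1]], f(nodes$x[idx], nodes$y[idx]), cfg)
    abs(apply_operator(rec, c(1, 0)) - fx(0, 0))
  }
  e1 <- err_at(0.1); e2 <- err_at(0.05)
  expect_gt(e1 / e2, 2^3.5)   # observed order >= r - |alpha| + 0.5
})

test_that("laplacian of x^2 + y^2 is 4 anywhere", {
  cfg <- gmls_config(order = 2)
  nodes <- random_cloud(300, support = 0.3, seed = 11, config = cfg)
  nb <- build_neighborhoods(nodes, cfg)
  for (i in c(3, 150, 280)) {
    idx <- nb[[i]]$neighbor_indices
    rec <- gmls_reconstruct(nodes, nb[[i]], nodes$x[idx]^2 + nodes$y[idx]^2, cfg)
    lap <- apply_operator(rec, c(2, 0)) + apply_operator(rec, c(0, 2))
    expect_equal(lap, 4, tolerance = 1e-8)
  }
})
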