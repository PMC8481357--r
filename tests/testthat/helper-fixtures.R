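# shared helpers: independent oracles and small fixture builders

# brute-force all-pairs neighbour search (oracle for build_neighborhoods)
brute_neighbors <- function(pos, support) {
  lapply(seq_len(nrow(pos)), function(i) {
    d <- sqrt((pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2)
    which(d < support[i] & seq_len(nrow(pos)) != i)
  })
}

# exhaustive minimum-cost assignment over all permutations (oracle for LAP)
brute_lap <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v)) {
      for (p in perms(v[-k])) out[[length(out) + 1]] <- c(v[k], p)
    }
    out
  }
  best <- NULL; bestc <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < bestc) { bestc <- cc; best <- p }
  }
  list(assignment = best, cost = bestc)
}

# random quasi-uniform node cloud in the unit square wrapped as gmls_nodes
random_cloud <- function(n, support, seed = 1, config = gmls_config()) {
  set.seed(seed)
  pos <- cbind(runif(n), runif(n))
  gmls_nodes(pos, rep("fluid", n), spacing = support / config$support_factor,
             support = support, config = config)
}

# render three well-separated dark disks on a bright background
three_disk_frame <- function(npx = 200, pixel_size = 1) {
  img <- matrix(0.85, npx, npx)
  disks <- list(c(50, 50, 18), c(140, 60, 12), c(80, 150, 15))
  for (d in disks) {
    ix <- which(abs(seq_len(npx) - d[1]) <= d[3])
    iy <- which(abs(seq_len(npx) - d[2]) <= d[3])
    sub <- outer((ix - d[1])^2, (iy - d[2])^2, `+`) <= d[3]^2
    img[ix, iy][sub] <- 0.25
  }
  list(image = img, disks = disks)
}
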