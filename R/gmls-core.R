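#' GMLS discretization settings
#'
#' Collects the parameters of the generalized moving least squares (GMLS)
#' approximation: the polynomial order of the local reconstructions, the
#' factor converting local node spacing into the compact support radius of
#' the weight function, the exponent of the weight kernel, and a safety
#' floor on neighbour counts.
#'
#' @param order Polynomial order `r` of the local reconstructions
#'   (default 4, giving 4th-order consistency for values).
#' @param support_factor Dimensionless multiplier: a node with local spacing
#'   `h` gets support radius `eps = support_factor * h`.  Must exceed 1; the
#'   default 3.0 makes order-4 bases comfortably overdetermined on
#'   quasi-uniform clouds.
#' @param weight_exponent Exponent of the kernel
#'   `W(r) = 1 - (r/eps)^weight_exponent` (default 4).
#' @param min_neighbors Minimum admissible neighbour count per node.  The
#'   default is `ceiling(1.5 * basis dimension)`, for least-squares
#'   robustness on irregular clouds.
#' @return An object of class `gmls_config`.
#' @examples
#' gmls_config()
#' gmls_config(order = 2)
#' @export
gmls_config <- function(order = 4, support_factor = 3.0, weight_exponent = 4,
                        min_neighbors = NULL) {
  if (!is.numeric(order) || order < 1 || order != round(order)) {
    rlang::abort("`order` must be an integer >= 1.")
  }
  if (!is.numeric(support_factor) || support_factor <= 1) {
    rlang::abort("`support_factor` must be > 1.")
  }
  basis_dim <- (order + 1) * (order + 2) / 2
  if (is.null(min_neighbors)) min_neighbors <- ceiling(1.5 * basis_dim)
  if (min_neighbors < basis_dim) {
    rlang::abort(sprintf(
      "`min_neighbors` (%d) must be at least the basis dimension (%d).",
      min_neighbors, basis_dim))
  }
  structure(list(order = as.integer(order), support_factor = support_factor,
                 weight_exponent = as.integer(weight_exponent),
                 min_neighbors = as.integer(min_neighbors),
                 basis_dim = as.integer(basis_dim)),
            class = "gmls_config")
}

#' @export
print.gmls_config <- function(x, ...) {
  cat(sprintf("<gmls_config> order=%d support_factor=%.2f weight_exponent=%d min_neighbors=%d\n",
              x$order, x$support_factor, x$weight_exponent, x$min_neighbors))
  invisible(x)
}

#' Construct a GMLS node set
#'
#' A node set is a tibble of collocation points with a kind label
#' (`"fluid"`, `"drop_boundary"`, or `"body_boundary"`), a per-node local
#' spacing and a per-node support radius.  Body-boundary nodes carry the id
#' of their body plus the outward normal and an arc-length quadrature
#' weight, used when integrating surface tractions.
#'
#' @param positions Two-column matrix or data frame of coordinates.
#' @param kind Character vector of node kinds.
#' @param spacing Per-node local spacing `h_i` (positive).
#' @param support Per-node support radius `eps_i`; defaults to
#'   `config$support_factor * spacing`.
#' @param body_id Integer id per node (NA for non-body nodes).
#' @param normal Optional two-column matrix of outward unit normals for
#'   boundary nodes.
#' @param arc_weight Optional quadrature weight (arc length) per boundary node.
#' @param config A [gmls_config()].
#' @return A tibble of class `gmls_nodes` with columns
#'   `x, y, kind, body_id, spacing, support, nx, ny, arc_weight`.
#' @export
gmls_nodes <- function(positions, kind, spacing, support = NULL,
                       body_id = NA_integer_, normal = NULL, arc_weight = NA_real_,
                       config = gmls_config()) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 2, length(kind) == n)
  kinds_ok <- kind %in% c("fluid", "drop_boundary", "body_boundary")
  if (!all(kinds_ok)) rlang::abort("unknown node kind(s)")
  spacing <- rep_len(spacing, n)
  if (any(spacing <= 0)) rlang::abort("all spacings must be > 0")
  if (is.null(support)) support <- config$support_factor * spacing
  support <- rep_len(support, n)
  if (any(support <= 0)) rlang::abort("all supports must be > 0")
  if (is.null(normal)) normal <- matrix(NA_real_, n, 2)
  out <- tibble::tibble(
    x = positions[, 1], y = positions[, 2],
    kind = kind, body_id = rep_len(body_id, n),
    spacing = spacing, support = support,
    nx = normal[, 1], ny = normal[, 2],
    arc_weight = rep_len(arc_weight, n))
  class(out) <- c("gmls_nodes", class(out))
  out
}

#' Compact-support GMLS weight function
#'
#' `W(r) = 1 - (r/eps)^p` inside the support (distance strictly below
#' `eps`) and exactly 0 at and beyond the support edge.
#'
#' @param r_ij Distance(s), `>= 0`.
#' @param eps Support radius, `> 0`.
#' @param exponent Kernel exponent `p` (default 4).
#' @return Weight value(s) in `[0, 1]`.
#' @examples
#' gmls_weight(0, 1)      # 1
#' gmls_weight(0.5, 1)    # 0.9375
#' gmls_weight(1, 1)      # 0
#' @export
gmls_weight <- function(r_ij, eps, exponent = 4) {
  if (any(r_ij < 0) || any(eps <= 0)) {
    rlang::abort("`r_ij` must be >= 0 and `eps` > 0.")
  }
  ifelse(r_ij < eps, 1 - (r_ij / eps)^exponent, 0)
}

# cell-list fixed-radius neighbour search; returns list of integer vectors
# (self excluded).  Radii may vary per node.
radius_neighbors <- function(pos, support) {
  n <- nrow(pos)
  cs <- max(support)
  cx <- floor(pos[, 1] / cs); cy <- floor(pos[, 2] / cs)
  key <- cx * 536870912 + cy   # collision-free for |index| < 2^28
  cells <- split(seq_len(n), key)
  keymap <- as.numeric(names(cells))
  lookup <- function(kx, ky) {
    k <- kx * 536870912 + ky
    unlist(cells[match(k, keymap)], use.names = FALSE)
  }
  out <- vector("list", n)
  off <- expand.grid(dx = -1:1, dy = -1:1)
  for (i in seq_len(n)) {
    cand <- lookup(cx[i] + off$dx, cy[i] + off$dy)
    cand <- cand[!is.na(cand)]
    d2 <- (pos[cand, 1] - pos[i, 1])^2 + (pos[cand, 2] - pos[i, 2])^2
    out[[i]] <- cand[d2 < support[i]^2 & cand != i]
  }
  out
}

#' Build epsilon-neighbourhoods for every node
#'
#' For each node, lists all and only the nodes at distance strictly less
#' than the node's support radius (the node itself is excluded), together
#' with distances and kernel weights.
#'
#' @param nodes A [gmls_nodes()] tibble.
#' @param config A [gmls_config()].
#' @param min_neighbors Override of the neighbour-count floor (defaults to
#'   the configured value; lower values are useful when inspecting
#'   neighbourhood structure alone, without reconstruction).
#' @return A list of neighbourhoods; each is a list with fields
#'   `center_index`, `neighbor_indices`, `distances`, `weights`.
#' @export
build_neighborhoods <- function(nodes, config = gmls_config(),
                                min_neighbors = config$min_neighbors) {
  if (!nrow(nodes)) rlang::abort("`nodes` must be non-empty.")
  pos <- cbind(nodes$x, nodes$y)
  nb <- radius_neighbors(pos, nodes$support)
  cnt <- lengths(nb)
  config <- utils::modifyList(config, list(min_neighbors = as.integer(min_neighbors)))
  if (any(cnt < config$min_neighbors)) {
    bad <- which.min(cnt)
    rlang::abort(sprintf(
      "node %d at (%.4g, %.4g) has %d neighbours; at least %d required (increase support or node density)",
      bad, nodes$x[bad], nodes$y[bad], cnt[bad], config$min_neighbors))
  }
  lapply(seq_along(nb), function(i) {
    idx <- nb[[i]]
    d <- sqrt((nodes$x[idx] - nodes$x[i])^2 + (nodes$y[idx] - nodes$y[i])^2)
    list(center_index = i, neighbor_indices = idx, distances = d,
         weights = gmls_weight(d, nodes$support[i], config$weight_exponent))
  })
}

#' Local GMLS reconstruction at a node
#'
#' Fits the weighted least-squares polynomial of the configured order to
#' sample values at the neighbours of a node, minimizing
#' `sum_j (psi_j - P(x_j)' c)^2 W_ij`.  Monomials are shifted to the centre
#' and scaled by the support radius before the normal equations are solved,
#' which keeps the Gram matrix well conditioned.
#'
#' @param nodes A [gmls_nodes()] tibble.
#' @param neighborhood One element of [build_neighborhoods()].
#' @param samples Sample values at `neighborhood$neighbor_indices`.
#' @param config A [gmls_config()].
#' @return An object of class `gmls_reconstruction` with the fitted
#'   coefficients (in scaled coordinates), the exponent table, the centre,
#'   the support radius and the Gram condition number.
#' @export
gmls_reconstruct <- function(nodes, neighborhood, samples, config = gmls_config()) {
  idx <- neighborhood$neighbor_indices
  if (length(samples) != length(idx)) {
    rlang::abort("`samples` must match the neighbourhood size.")
  }
  if (length(idx) < config$basis_dim) {
    rlang::abort("fewer neighbours than basis dimension; reconstruction is underdetermined.")
  }
  i <- neighborhood$center_index
  eps <- nodes$support[i]
  rel <- cbind(nodes$x[idx] - nodes$x[i], nodes$y[idx] - nodes$y[i]) / eps
  w <- neighborhood$weights
  ex <- monomial_exponents(config$order)
  P <- outer(rel[, 1], ex$i, `^`) * outer(rel[, 2], ex$j, `^`)
  G <- crossprod(P, P * w)
  cond <- kappa(G, exact = FALSE)
  if (!is.finite(cond) || cond > 1e14) {
    rlang::abort(sprintf(
      "degenerate neighbourhood geometry at node %d: Gram condition number %.3g",
      i, cond))
  }
  coef <- solve(G, crossprod(P * w, samples))
  structure(list(center_index = i, center = c(nodes$x[i], nodes$y[i]),
                 eps = eps, order = config$order, exponents = ex,
                 coefficients = as.numeric(coef),
                 gram_condition_number = cond),
            class = "gmls_reconstruction")
}

#' Apply a differential operator to a local reconstruction
#'
#' Evaluates `D^alpha psi_h` at the reconstruction centre:
#' `(D^alpha P)(x_i)' c*`, which for the shifted/scaled monomial basis is
#' `alpha! * c*_alpha / eps^|alpha|`.
#'
#' @param reconstruction A [gmls_reconstruct()] result.
#' @param alpha Length-2 multi-index `c(ax, ay)` of derivative orders.
#' @return The derivative estimate at the centre (`alpha = c(0, 0)` gives the
#'   reconstructed value itself).
#' @export
apply_operator <- function(reconstruction, alpha) {
  stopifnot(length(alpha) == 2, all(alpha >= 0), all(alpha == round(alpha)))
  if (sum(alpha) > reconstruction$order) {
    rlang::abort(sprintf("|alpha| = %d exceeds reconstruction order %d",
                         sum(alpha), reconstruction$order))
  }
  ex <- reconstruction$exponents
  row <- which(ex$i == alpha[1] & ex$j == alpha[2])
  fac <- factorial(alpha[1]) * factorial(alpha[2]) / reconstruction$eps^sum(alpha)
  reconstruction$coefficients[row] * fac
}

# ---- internal stencil machinery for the PDE solver ------------------------

# Stencil weights at an evaluation point for a set of derivative
# multi-indices.  `rel` holds neighbour coordinates relative to the point
# (the point itself, if sampled, must be included in `rel` as a zero row).
# Returns a matrix: one row per alpha, one column per sample.
gmls_stencil <- function(rel, eps, order, alphas, weight_exponent = 4) {
  rel <- rel / eps
  r <- sqrt(rowSums(rel^2))
  w <- pmax(0, 1 - r^weight_exponent)
  ex <- monomial_exponents(order)
  P <- outer(rel[, 1], ex$i, `^`) * outer(rel[, 2], ex$j, `^`)
  G <- crossprod(P, P * w)
  M <- tryCatch(solve(G, t(P * w)), error = function(e) {
    rlang::abort(sprintf("degenerate stencil geometry (%s)", conditionMessage(e)))
  })
  out <- matrix(0, length(alphas), nrow(rel))
  for (k in seq_along(alphas)) {
    a <- alphas[[k]]
    row <- which(ex$i == a[1] & ex$j == a[2])
    out[k, ] <- M[row, ] * factorial(a[1]) * factorial(a[2]) / eps^sum(a)
  }
  out
}

#' Write a node set to CSV
#'
#' Serializes the documented columns `x, y, kind, spacing, support`.
#'
#' @param nodes A [gmls_nodes()] tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_nodes_csv <- function(nodes, path) {
  utils::write.csv(nodes[, c("x", "y", "kind", "spacing", "support")],
                   path, row.names = FALSE)
  invisible(path)
}
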