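#' Circular microdrop fluid domain
#'
#' The under-oil microdrop is modelled as an incompressible Newtonian fluid
#' bounded by a circular no-slip wall.  Lengths are in micrometres; fluid
#' properties default to a dilute aqueous buffer.
#'
#' @param drop_radius Drop radius (um), `> 0`.
#' @param nu Kinematic viscosity (m^2/s), default `1e-6`.
#' @param rho Fluid density (kg/m^3), default `1000`.
#' @param depth_scale Out-of-plane depth (um) used to convert the 2D
#'   force-per-depth into a reported force in newtons.  A 2D Stokes solve
#'   yields force per unit depth; absolute forces are reproducible only up
#'   to this normalization, which is therefore explicit and configurable
#'   (default 1 um).
#' @param units `"um"` (lengths um, speeds um/s, `nu` in m^2/s, `rho` in
#'   kg/m^3; forces reported in newtons) or `"dimensionless"` (one coherent
#'   unit system throughout, used by the benchmark suites).
#' @return An object of class `fluid_domain`.
#' @export
fluid_domain <- function(drop_radius, nu = 1.0e-6, rho = 1000, depth_scale = 1,
                         units = c("um", "dimensionless")) {
  units <- match.arg(units)
  if (drop_radius <= 0 || nu <= 0 || rho <= 0 || depth_scale <= 0) {
    rlang::abort("drop_radius, nu, rho and depth_scale must all be > 0.")
  }
  structure(list(drop_radius = drop_radius, nu = nu, rho = rho,
                 depth_scale = depth_scale, units = units),
            class = "fluid_domain")
}

#' @export
print.fluid_domain <- function(x, ...) {
  cat(sprintf("<fluid_domain> radius=%g um, nu=%g m^2/s, rho=%g kg/m^3, depth=%g um\n",
              x$drop_radius, x$nu, x$rho, x$depth_scale))
  invisible(x)
}

#' Rigid body (bacterium or microcolony) in the drop
#'
#' Bodies are disks (microcolonies) or capsules (rod-shaped bacteria: a
#' rectangle with semicircular caps, length `L` tip-to-tip, width `W`).
#' Each body carries a prescribed rigid translation; rotation is fixed at
#' zero (body spin is treated as negligible).  A body may instead be
#' `"free"`, in which case the mobility solve determines its velocity from
#' the force- and torque-free condition.
#'
#' @param body_id Integer id.
#' @param shape `"disk"` or `"capsule"`.
#' @param position Length-2 centre coordinates (um).
#' @param radius Disk radius (um), for `shape = "disk"`.
#' @param length,width Capsule length and width (um), `length >= width`.
#' @param orientation Capsule axis angle (radians), default 0.
#' @param velocity Length-2 prescribed velocity (um/s), or the string
#'   `"free"` for mobility mode.
#' @return An object of class `rigid_body`.
#' @export
rigid_body <- function(body_id, shape = c("disk", "capsule"), position,
                       radius = NULL, length = NULL, width = NULL,
                       orientation = 0, velocity = c(0, 0)) {
  shape <- match.arg(shape)
  if (shape == "disk") {
    if (is.null(radius) || radius <= 0) rlang::abort("disk needs `radius` > 0")
  } else {
    if (is.null(length) || is.null(width) || width <= 0 || length < width) {
      rlang::abort("capsule needs `length` >= `width` > 0")
    }
  }
  free <- identical(velocity, "free")
  if (!free) {
    velocity <- as.numeric(velocity)
    stopifnot(base::length(velocity) == 2)
  }
  structure(list(body_id = as.integer(body_id), shape = shape,
                 position = as.numeric(position), radius = radius,
                 length = length, width = width, orientation = orientation,
                 velocity = if (free) "free" else velocity, free = free),
            class = "rigid_body")
}

# signed distance to the body surface (< 0 inside), vectorized over points
body_sdist <- function(body, x, y) {
  if (body$shape == "disk") {
    sqrt((x - body$position[1])^2 + (y - body$position[2])^2) - body$radius
  } else {
    a <- (body$length - body$width) / 2
    ca <- cos(body$orientation); sa <- sin(body$orientation)
    dx <- x - body$position[1]; dy <- y - body$position[2]
    t <- pmax(-a, pmin(a, dx * ca + dy * sa))
    sqrt((dx - t * ca)^2 + (dy - t * sa)^2) - body$width / 2
  }
}

# characteristic boundary feature size used to cap local spacing
body_feature <- function(body) {
  if (body$shape == "disk") body$radius / 3 else body$width / 3
}

# boundary points with outward normals; spacing from hfun(x, y)
body_boundary_points <- function(body, hfun) {
  if (body$shape == "disk") {
    R <- body$radius; cx <- body$position[1]; cy <- body$position[2]
    th <- 0; ths <- numeric(0)
    repeat {
      ths <- c(ths, th)
      th <- th + hfun(cx + R * cos(th), cy + R * sin(th)) / R
      if (th >= 2 * pi) break
    }
    ths <- ths * 2 * pi / th
    pts <- cbind(cx + R * cos(ths), cy + R * sin(ths))
    nrm <- cbind(cos(ths), sin(ths))
    arc <- R * ths   # exact arc-length parameter
    per <- 2 * pi * R
  } else {
    a <- (body$length - body$width) / 2; rc <- body$width / 2
    # closed curve: right cap, top edge, left cap, bottom edge (local frame)
    per_pieces <- c(pi * rc, 2 * a, pi * rc, 2 * a)
    cum <- cumsum(c(0, per_pieces)); per <- sum(per_pieces)
    point_at <- function(s) {
      s <- s %% per
      if (s < cum[2]) { th <- -pi / 2 + s / rc
        p <- c(a + rc * cos(th), rc * sin(th)); nv <- c(cos(th), sin(th))
      } else if (s < cum[3]) { t <- s - cum[2]
        p <- c(a - t, rc); nv <- c(0, 1)
      } else if (s < cum[4]) { th <- pi / 2 + (s - cum[3]) / rc
        p <- c(-a + rc * cos(th), rc * sin(th)); nv <- c(cos(th), sin(th))
      } else { t <- s - cum[4]
        p <- c(-a + t, -rc); nv <- c(0, -1)
      }
      c(p, nv)
    }
    ca <- cos(body$orientation); sa <- sin(body$orientation)
    rot <- function(v) c(ca * v[1] - sa * v[2], sa * v[1] + ca * v[2])
    s <- 0; ss <- numeric(0)
    repeat {
      ss <- c(ss, s)
      pl <- point_at(s); pw <- rot(pl[1:2]) + body$position
      s <- s + hfun(pw[1], pw[2])
      if (s >= per) break
    }
    ss <- ss * per / s
    pts <- matrix(0, base::length(ss), 2); nrm <- pts
    for (k in seq_along(ss)) {
      pl <- point_at(ss[k])
      pts[k, ] <- rot(pl[1:2]) + body$position
      nrm[k, ] <- rot(pl[3:4])
    }
    arc <- ss
  }
  # trapezoid weights on the exact arc-length parameter of the closed curve
  darc <- diff(c(arc, arc[1] + per))
  w <- (darc + c(tail(darc, 1), head(darc, -1))) / 2
  list(points = pts, normals = nrm, arc_weights = w)
}

# pairwise body surface separation (>= 0 means no overlap); sampled for capsules
body_separation <- function(b1, b2) {
  if (b1$shape == "disk" && b2$shape == "disk") {
    sqrt(sum((b1$position - b2$position)^2)) - b1$radius - b2$radius
  } else {
    bp <- body_boundary_points(b2, function(x, y) rep(body_feature(b2), base::length(x)))
    min(body_sdist(b1, bp$points[, 1], bp$points[, 2]))
  }
}

# max distance of body surface from drop centre
body_extent <- function(body) {
  if (body$shape == "disk") {
    sqrt(sum(body$position^2)) + body$radius
  } else {
    bp <- body_boundary_points(body, function(x, y) rep(body_feature(body), base::length(x)))
    max(sqrt(rowSums(bp$points^2)))
  }
}

validate_geometry <- function(domain, bodies) {
  for (b in bodies) {
    if (body_extent(b) >= domain$drop_radius) {
      rlang::abort(sprintf("body %d touches or crosses the drop boundary", b$body_id))
    }
  }
  if (base::length(bodies) >= 2) {
    for (i in seq_along(bodies)[-1]) for (j in seq_len(i - 1)) {
      if (body_separation(bodies[[i]], bodies[[j]]) <= 0) {
        rlang::abort(sprintf("bodies %d and %d overlap or touch",
                             bodies[[j]]$body_id, bodies[[i]]$body_id))
      }
    }
  }
  invisible(TRUE)
}

# spacing field: h(x) = min(h0, refinement constraints).  Constraints are
# disks (cx, cy, h_at, slope): spacing h_at at the centre growing linearly
# away from it.  Bodies and narrow gaps contribute constraints.
make_spacing_field <- function(domain, bodies, h0, slope = 0.3,
                               gap_divisor = 4, extra = list()) {
  constraints <- list()
  addc <- function(cx, cy, h_at) {
    constraints[[base::length(constraints) + 1]] <<- c(cx, cy, h_at)
  }
  hbs <- vapply(bodies, function(b) min(h0, body_feature(b)), numeric(1))
  # narrow gaps refine both the gap region and a collar around the whole of
  # each involved body (lubrication pressure spreads along the surface)
  body_gap <- rep(Inf, base::length(bodies))
  if (base::length(bodies) >= 2) {
    for (i in seq_along(bodies)[-1]) for (j in seq_len(i - 1)) {
      s <- body_separation(bodies[[i]], bodies[[j]])
      if (s < 2 * max(hbs[c(i, j)])) {
        mid <- (bodies[[i]]$position + bodies[[j]]$position) / 2
        addc(mid[1], mid[2], max(s / gap_divisor, 1e-6))
        body_gap[c(i, j)] <- pmin(body_gap[c(i, j)], s)
      }
    }
  }
  # gap to the drop wall
  for (i in seq_along(bodies)) {
    s <- domain$drop_radius - body_extent(bodies[[i]])
    if (s < 2 * hbs[i]) {
      dirv <- bodies[[i]]$position / max(sqrt(sum(bodies[[i]]$position^2)), 1e-12)
      surf <- dirv * (domain$drop_radius - s / 2)
      addc(surf[1], surf[2], max(s / gap_divisor, 1e-6))
      body_gap[i] <- min(body_gap[i], s)
    }
  }
  collar_h <- pmin(hbs, body_gap / gap_divisor + 0)
  for (e in extra) addc(e[1], e[2], e[3])
  cmat <- if (base::length(constraints)) do.call(rbind, constraints) else NULL
  hmin <- min(c(h0, collar_h, if (!is.null(cmat)) cmat[, 3]))
  fun <- function(x, y) {
    h <- rep(h0, base::length(x))
    for (k in seq_along(bodies)) {
      d <- abs(body_sdist(bodies[[k]], x, y))
      h <- pmin(h, hbs[k] + slope * d)
      if (is.finite(body_gap[k])) {
        h <- pmin(h, collar_h[k] + slope * (d + body_gap[k]))
      }
    }
    if (!is.null(cmat)) {
      for (k in seq_len(nrow(cmat))) {
        d <- sqrt((x - cmat[k, 1])^2 + (y - cmat[k, 2])^2)
        h <- pmin(h, cmat[k, 3] + slope * d)
      }
    }
    h
  }
  list(fun = fun, hmin = hmin)
}

#' Discretize a drop-with-bodies geometry into a GMLS node set
#'
#' Places boundary nodes along the drop wall and every body surface at the
#' local target arc spacing, and fills the fluid region with a graded
#' multilevel hexagonal cloud (spacing halves per level) that refines near
#' body surfaces and inside narrow gaps: a gap of width `s` between two
#' surfaces receives nodes at spacing `<= s / gap_divisor`.
#'
#' @param domain A [fluid_domain()].
#' @param bodies List of [rigid_body()] objects.
#' @param target_spacing Background spacing `h0` (same units as the domain).
#' @param config A [gmls_config()].
#' @param slope Grading slope of the spacing field away from refined
#'   features (default 0.3).
#' @param gap_divisor Gap width divided by this gives the gap spacing
#'   (default 4; benchmark suites use larger values).
#' @param extra_refine Optional list of `c(x, y, h)` spacing constraints.
#' @return A [gmls_nodes()] tibble.
#' @export
discretize <- function(domain, bodies = list(), target_spacing,
                       config = gmls_config(), slope = 0.3, gap_divisor = 4,
                       extra_refine = list()) {
  validate_geometry(domain, bodies)
  R <- domain$drop_radius
  h0 <- target_spacing
  sf <- make_spacing_field(domain, bodies, h0, slope, gap_divisor, extra_refine)
  hfun <- sf$fun
  maxlev <- max(0, ceiling(log2(h0 / max(sf$hmin, 1e-9))))
  lev_of <- function(h) pmin(maxlev, pmax(0, ceiling(log2(h0 / h) - 1e-9)))
  pts <- NULL
  for (l in 0:maxlev) {
    hl <- h0 / 2^l
    gpos <- seq(hl, R + hl, by = hl)
    g <- c(-rev(gpos), 0, gpos)   # symmetric about the drop centre
    gr <- as.matrix(expand.grid(x = g, y = g))
    gr[, 1] <- gr[, 1] + (match(gr[, 2], g) %% 2) * hl / 2
    hh <- hfun(gr[, 1], gr[, 2])
    keep <- lev_of(hh) == l
    if (any(keep)) pts <- rbind(pts, gr[keep, , drop = FALSE])
  }
  hh <- hfun(pts[, 1], pts[, 2])
  ok <- sqrt(rowSums(pts^2)) < R - 0.5 * hh
  for (b in bodies) ok <- ok & body_sdist(b, pts[, 1], pts[, 2]) > 0.5 * hh
  int <- pts[ok, , drop = FALSE]
  parts <- list(gmls_nodes(int, rep("fluid", nrow(int)), hh[ok], config = config))
  # drop wall
  th <- 0; ths <- numeric(0)
  repeat {
    ths <- c(ths, th)
    th <- th + hfun(R * cos(th), R * sin(th)) / R
    if (th >= 2 * pi) break
  }
  ths <- ths * 2 * pi / th
  dpts <- cbind(R * cos(ths), R * sin(ths))
  dth <- diff(c(ths, ths[1] + 2 * pi))
  dw <- R * (dth + c(tail(dth, 1), head(dth, -1))) / 2
  parts[[2]] <- gmls_nodes(dpts, rep("drop_boundary", nrow(dpts)),
                           hfun(dpts[, 1], dpts[, 2]),
                           normal = cbind(cos(ths), sin(ths)),
                           arc_weight = dw, config = config)
  for (b in bodies) {
    bp <- body_boundary_points(b, hfun)
    parts[[base::length(parts) + 1]] <-
      gmls_nodes(bp$points, rep("body_boundary", nrow(bp$points)),
                 hfun(bp$points[, 1], bp$points[, 2]),
                 body_id = b$body_id, normal = bp$normals,
                 arc_weight = bp$arc_weights, config = config)
  }
  out <- dplyr::bind_rows(parts)
  class(out) <- c("gmls_nodes", class(out))
  out
}
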