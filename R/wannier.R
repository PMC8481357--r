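# Exact Stokes flow between eccentric rotating cylinders (Wannier flow).
#
# The solution is represented through the Goursat form of the biharmonic
# stream function: with analytic functions f, g on the fluid region,
#     u + i v = -f(z) + z * conj(f'(z)) + conj(g'(z)),
#     p       = 4 mu Re f'(z)  (+ constant),
# which satisfies the Stokes equations identically.  The eccentric annulus
# is mapped onto a concentric annulus rho < |w| < 1 by a Moebius map; f and
# g' are expanded there as Laurent series plus a log-pair (the log terms of
# f and g' are locked together so the velocity stays single-valued, which
# is what carries a non-zero net force on the inner cylinder).  The series
# coefficients are determined by collocating the two rigid-rotation no-slip
# conditions at boundary points uniform in the mapped angle and solving the
# resulting least-squares system through a column-equilibrated SVD.
# Coefficients decay geometrically, so the truncated solution is exact to
# near machine precision; the evaluation and force routines share nothing
# with the GMLS solver.

moebius_annulus <- function(r1, r2, ds) {
  c0 <- ds / r2; q <- r1 / r2
  if (abs(c0) < 1e-14) return(list(a = 0, rho = q))
  t <- 1 + c0^2 - q^2
  disc <- t^2 - 4 * c0^2
  if (disc <= 0) rlang::abort("cylinders touch or overlap")
  a1 <- (t + sqrt(disc)) / (2 * c0); a2 <- (t - sqrt(disc)) / (2 * c0)
  a <- if (abs(a1) < 1) a1 else a2
  rho <- abs(((c0 + q) - a) / (1 - a * (c0 + q)))
  list(a = a, rho = rho)
}

#' Analytic Wannier flow between eccentric rotating cylinders
#'
#' Exact solution of the Stokes equations in the gap between an inner
#' cylinder (radius `r1`, centre offset `eccentricity` along +x, angular
#' velocity `omega1`) and an outer cylinder (radius `r2`, centred at the
#' origin, angular velocity `omega2`).  Serves as the independent oracle
#' for the meshfree solver; in the concentric limit it reduces to the
#' Taylor-Couette closed form.
#'
#' @param r1,r2 Inner and outer cylinder radii, `r1 < r2`.
#' @param eccentricity Distance between the cylinder centres,
#'   `>= 0`, with `r1 + eccentricity < r2`.
#' @param omega1,omega2 Angular velocities (rad/time).
#' @param mu Dynamic viscosity.
#' @param n_modes Laurent truncation; the default grows automatically until
#'   the no-slip residual at held-out boundary points is below `tol`.
#' @param tol Target boundary residual (default 1e-10, relative to the
#'   boundary speed scale).
#' @return An object of class `wannier_flow` with the fitted coefficients;
#'   evaluate fields with [wannier_eval()] and the inner-cylinder load with
#'   [wannier_inner_force()].
#' @export
wannier_analytic <- function(r1, r2, eccentricity = 0, omega1 = 0, omega2 = 0,
                             mu = 1, n_modes = NULL, tol = 1e-10) {
  if (r1 <= 0 || r2 <= r1) rlang::abort("need 0 < r1 < r2")
  if (eccentricity < 0 || r1 + eccentricity >= r2) {
    rlang::abort("zero or negative gap: need r1 + eccentricity < r2")
  }
  mp <- moebius_annulus(r1, r2, eccentricity)
  scale_u <- max(abs(omega1) * r1, abs(omega2) * r2, 1e-300)
  Ks <- if (!is.null(n_modes)) n_modes else {
    K0 <- max(24, ceiling(log(1e-13) / log(max(mp$rho, 0.05))))
    unique(pmin(c(K0, ceiling(K0 * 1.6), ceiling(K0 * 2.4), 320), 320))
  }
  fit <- NULL
  for (K in Ks) {
    fit <- wannier_fit(r1, r2, eccentricity, omega1, omega2, mu, mp, K)
    ns <- wannier_noslip_residual(fit)
    fit$noslip_residual <- ns
    if (ns <= tol * scale_u) break
  }
  fit
}

wannier_fit <- function(r1, r2, ds, omega1, omega2, mu, mp, K) {
  a <- mp$a; rho <- mp$rho
  M <- 4 * K + 7
  th <- seq(0, 2 * pi, length.out = M + 1)[-(M + 1)]
  zinv <- function(w) r2 * (w + a) / (1 + a * w)
  z1 <- zinv(rho * exp(1i * th))
  z2 <- zinv(exp(1i * th))
  zb <- c(z1, z2)
  bc <- c(1i * omega1 * (z1 - ds), 1i * omega2 * z2)
  w_of <- function(z) { zt <- z / r2; (zt - a) / (1 - a * zt) }
  dw_of <- function(z) { zt <- z / r2; (1 - a^2) / (1 - a * zt)^2 / r2 }
  ks <- c(seq(-K, -1), seq(1, K))
  ksb <- seq(-K, K)
  W <- w_of(zb); dW <- dw_of(zb)
  nA <- length(ks); nB <- length(ksb)
  colsA <- matrix(0i, length(zb), nA + nB + 1)
  colsB <- matrix(0i, length(zb), nA + nB + 1)
  for (j in seq_along(ks)) {
    k <- ks[j]
    colsA[, j] <- -W^k
    colsB[, j] <- zb * Conj(k * W^(k - 1) * dW)
  }
  for (j in seq_along(ksb)) colsB[, nA + j] <- Conj(W^ksb[j])
  colsA[, nA + nB + 1] <- -2 * log(abs(W))
  colsB[, nA + nB + 1] <- zb * Conj(dW / W)
  Mr <- cbind(Re(colsA + colsB), Re(1i * (colsA - colsB)))
  Mi <- cbind(Im(colsA + colsB), Im(1i * (colsA - colsB)))
  X <- rbind(Mr, Mi)
  y <- c(Re(bc), Im(bc))
  cn <- sqrt(colSums(X^2)); cn[cn == 0] <- 1
  sv <- svd(sweep(X, 2, cn, "/"))
  keep <- sv$d > max(sv$d) * 1e-13
  coef <- (sv$v[, keep] %*% (crossprod(sv$u[, keep], y) / sv$d[keep])) / cn
  nc <- nA + nB + 1
  cc <- coef[1:nc] + 1i * coef[nc + 1:nc]
  structure(list(r1 = r1, r2 = r2, eccentricity = ds,
                 omega1 = omega1, omega2 = omega2, mu = mu,
                 a = a, rho = rho, K = K, ks = ks, ksb = ksb,
                 ak = cc[seq_along(ks)], bk = cc[nA + seq_along(ksb)],
                 A = cc[nA + nB + 1],
                 colloc_residual = max(abs(X %*% coef - y))),
            class = "wannier_flow")
}

#' @export
print.wannier_flow <- function(x, ...) {
  cat(sprintf("<wannier_flow> r1=%g r2=%g ecc=%g gap=%g K=%d boundary residual %.2e\n",
              x$r1, x$r2, x$eccentricity, x$r2 - x$r1 - x$eccentricity,
              x$K, x$colloc_residual))
  invisible(x)
}

#' Evaluate the analytic Wannier fields
#'
#' @param fit A [wannier_analytic()] object.
#' @param z Complex coordinates (or use `x`, `y`).
#' @param x,y Alternative real coordinates.
#' @return A tibble with `u`, `v`, `p` and the velocity gradient components
#'   `ux, uy, vx, vy` at each point.
#' @export
wannier_eval <- function(fit, z = NULL, x = NULL, y = NULL) {
  if (is.null(z)) z <- complex(real = x, imaginary = y)
  r2 <- fit$r2; a <- fit$a
  zt <- z / r2
  W <- (zt - a) / (1 - a * zt)
  dW <- (1 - a^2) / (1 - a * zt)^2 / r2
  d2W <- 2 * a * (1 - a^2) / (1 - a * zt)^3 / r2^2
  A <- fit$A
  fp <- A * dW / W
  fpp <- A * (d2W / W - (dW / W)^2)
  gpp <- -Conj(A) * dW / W
  V <- -2 * A * log(abs(W)) + z * Conj(fp)
  for (j in seq_along(fit$ks)) {
    k <- fit$ks[j]; ak <- fit$ak[j]
    V <- V - ak * W^k + z * Conj(ak * k * W^(k - 1) * dW)
    fp <- fp + ak * k * W^(k - 1) * dW
    fpp <- fpp + ak * (k * (k - 1) * W^(k - 2) * dW^2 + k * W^(k - 1) * d2W)
  }
  for (j in seq_along(fit$ksb)) {
    k <- fit$ksb[j]; bk <- fit$bk[j]
    V <- V + Conj(bk * W^k)
    gpp <- gpp + bk * k * W^(k - 1) * dW
  }
  dVdz <- -fp + Conj(fp)
  dVdzb <- z * Conj(fpp) + Conj(gpp)
  Vx <- dVdz + dVdzb
  Vy <- 1i * (dVdz - dVdzb)
  tibble::tibble(u = Re(V), v = Im(V), p = 4 * fit$mu * Re(fp),
                 ux = Re(Vx), vx = Im(Vx), uy = Re(Vy), vy = Im(Vy))
}

wannier_noslip_residual <- function(fit, m = 157) {
  th <- seq(0.0137, 2 * pi, length.out = m)   # held-out points
  z1 <- fit$eccentricity + fit$r1 * exp(1i * th)
  z2 <- fit$r2 * exp(1i * th)
  e1 <- wannier_eval(fit, z1); e2 <- wannier_eval(fit, z2)
  max(abs(e1$u + 1i * e1$v - 1i * fit$omega1 * (z1 - fit$eccentricity)),
      abs(e2$u + 1i * e2$v - 1i * fit$omega2 * z2))
}

#' Load on the inner cylinder of the analytic Wannier flow
#'
#' Spectrally accurate trapezoid quadrature of the analytic traction.
#'
#' @param fit A [wannier_analytic()] object.
#' @param nq Number of quadrature points (default 1024).
#' @return Named vector `c(fx, fy, tz)`: force per unit depth and torque
#'   per unit depth about the inner cylinder centre.
#' @export
wannier_inner_force <- function(fit, nq = 1024) {
  th <- seq(0, 2 * pi, length.out = nq + 1)[-(nq + 1)]
  z <- fit$eccentricity + fit$r1 * exp(1i * th)
  ev <- wannier_eval(fit, z)
  nx <- cos(th); ny <- sin(th)
  mu <- fit$mu
  txx <- -ev$p + 2 * mu * ev$ux
  tyy <- -ev$p + 2 * mu * ev$vy
  txy <- mu * (ev$uy + ev$vx)
  tx <- txx * nx + txy * ny
  ty <- txy * nx + tyy * ny
  ds <- fit$r1 * 2 * pi / nq
  c(fx = sum(tx) * ds, fy = sum(ty) * ds,
    tz = sum((Re(z) - fit$eccentricity) * ty - Im(z) * tx) * ds)
}

#' Benchmark the meshfree solver against the analytic Wannier solution
#'
#' For each requested gap width the eccentric-cylinder geometry is solved
#' numerically (inner cylinder as a rotating disk body inside a rotating
#' "drop" wall) and the inner-cylinder force is compared with the analytic
#' value.
#'
#' @param gaps Gap widths as fractions of `r1` (default `c(1/2, 1/5, 1/20)`).
#' @param r1,r2 Cylinder radii.
#' @param omega1,omega2 Angular velocities.
#' @param target_spacing Background node spacing for the solver.
#' @param gap_divisor Gap refinement divisor passed to [discretize()]
#'   (default 16: the narrow-gap cases need several nodes across the gap).
#' @param config A [gmls_config()].
#' @return A tibble with one row per geometry: gap, node count, numeric and
#'   analytic force per depth, and the relative error.
#' @export
benchmark_wannier <- function(gaps = c(1 / 2, 1 / 5, 1 / 20), r1 = 0.25, r2 = 1,
                              omega1 = 1, omega2 = 0.3, target_spacing = 0.03,
                              gap_divisor = 16, config = gmls_config()) {
  rows <- lapply(gaps, function(gf) {
    gap <- r1 * gf
    ds <- r2 - r1 - gap
    fit <- wannier_analytic(r1, r2, ds, omega1, omega2, mu = 1)
    fan <- wannier_inner_force(fit)
    dom <- fluid_domain(r2, nu = 1, rho = 1, depth_scale = 1,
                        units = "dimensionless")
    body <- rigid_body(1L, "disk", position = c(ds, 0), radius = r1,
                       velocity = c(0, 0))
    nodes <- discretize(dom, list(body), target_spacing,
                        config = config, slope = 0.25,
                        gap_divisor = gap_divisor)
    sol <- solve_stokes(nodes, dom, list(body), config = config,
                        wall_omega = omega2, body_omega = c(`1` = omega1))
    fn <- traction_force(sol, body)
    rel <- sqrt((fn$fx_per_depth - fan["fx"])^2 + (fn$fy_per_depth - fan["fy"])^2) /
      sqrt(sum(fan[c("fx", "fy")]^2))
    tibble::tibble(gap_fraction = gf, gap = gap, n_nodes = nrow(nodes),
                   fx_numeric = fn$fx_per_depth, fy_numeric = fn$fy_per_depth,
                   fx_analytic = unname(fan["fx"]), fy_analytic = unname(fan["fy"]),
                   rel_error = as.numeric(rel))
  })
  dplyr::bind_rows(rows)
}
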