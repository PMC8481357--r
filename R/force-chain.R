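# Force-balance chain: gliding drag -> per-cell stroking force (contact
# area ratio) -> base-cell count -> theoretical maximum propulsion -> net
# force percentage (NFP).

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Rod-cell contact geometry
#'
#' Cell length and width define the two contact areas: `S_L = L * W` for a
#' cell lying flat on the substrate and `S_W = pi (W/2)^2` for a cell
#' touching by one pole, so the stroking/gliding force ratio is
#' `S_W / S_L = pi W / (4 L)`.
#'
#' @param length,width Cell length and width (um), `length >= width > 0`.
#' @return An object of class `cell_geometry` with derived areas and ratio.
#' @examples
#' cell_geometry(6.7, 0.716)$area_ratio   # ~0.0839
#' @export
cell_geometry <- function(length, width) {
  if (width <= 0 || length < width) {
    rlang::abort("need cell length >= width > 0")
  }
  structure(list(length = length, width = width,
                 S_L = length * width, S_W = pi * (width / 2)^2,
                 area_ratio = pi * width / (4 * length)),
            class = "cell_geometry")
}

#' Base-cell scaling model N(D)
#'
#' Three models for the number of base cells `N` under a microcolony of
#' diameter `D`:
#' * `power_fit`: `N = a D^b`, the empirical fit (defaults `a = 0.2`,
#'   `b = 1.36`);
#' * `hypothesis_A`: constant surface density `n` over the base contact
#'   disk, `N = n pi (d_over_D * D / 2)^2` (area scaling, `N ~ D^2`);
#' * `hypothesis_B`: perimeter-like scaling, `N = n D`.
#'
#' @param kind One of `"power_fit"`, `"hypothesis_A"`, `"hypothesis_B"`.
#' @param a,b Power-law coefficient and exponent.
#' @param n Base-cell surface density (cells/um^2) or linear density
#'   (cells/um) depending on the hypothesis; default 0.25.
#' @param d_over_D Mean ratio of base diameter to colony diameter
#'   (default 0.48).
#' @return An object of class `scaling_model`; call it like a function or
#'   use [base_cell_count()].
#' @export
scaling_model <- function(kind = c("power_fit", "hypothesis_A", "hypothesis_B"),
                          a = 0.2, b = 1.36, n = 0.25, d_over_D = 0.48) {
  kind <- match.arg(kind)
  if (n < 0 || d_over_D <= 0 || d_over_D > 1) {
    rlang::abort("need n >= 0 and 0 < d_over_D <= 1")
  }
  structure(list(kind = kind, a = a, b = b, n = n, d_over_D = d_over_D),
            class = "scaling_model")
}

predict_scaling <- function(model, D) {
  switch(model$kind,
         power_fit = model$a * D^model$b,
         hypothesis_A = model$n * pi * (model$d_over_D * D / 2)^2,
         hypothesis_B = model$n * D)
}

#' Expected base-cell count at a given colony diameter
#'
#' @param D Colony diameter(s), um, `> 0`.
#' @param model A [scaling_model()].
#' @return A tibble with `D`, the real-valued `expected` count and the
#'   half-up rounded `count`.
#' @examples
#' base_cell_count(50, scaling_model("power_fit"))   # expected 40.9 -> 41
#' @export
base_cell_count <- function(D, model = scaling_model("power_fit")) {
  if (any(D <= 0)) rlang::abort("D must be > 0")
  expected <- predict_scaling(model, D)
  tibble::tibble(D = D, expected = expected,
                 count = as.integer(round_half_up(expected)))
}

#' Quadratic coefficient of the constant-density hypothesis
#'
#' Under constant base-cell density `n` over the base contact disk of
#' diameter `d = d_over_D * D`, the count is `N = c D^2` with
#' `c = n pi (d_over_D / 2)^2`.
#'
#' @param n Surface density (cells/um^2), `>= 0`.
#' @param d_over_D Base-to-colony diameter ratio in (0, 1].
#' @return The coefficient `c`.
#' @examples
#' hypothesisA_coefficient(0.25, 0.48)   # 0.04524, printed 0.05
#' @export
hypothesisA_coefficient <- function(n, d_over_D) {
  if (n < 0 || d_over_D <= 0 || d_over_D > 1) {
    rlang::abort("need n >= 0 and 0 < d_over_D <= 1")
  }
  n * pi * (d_over_D / 2)^2
}

#' Base-cell surface density from a count
#'
#' Inverts the constant-density relation: `n = N / (pi (d_over_D * D/2)^2)`.
#'
#' @param N Base-cell count.
#' @param D Colony diameter (um), `> 0`.
#' @param d_over_D Base-to-colony diameter ratio.
#' @return Density in cells/um^2.
#' @examples
#' base_cell_density(base_cell_count(10)$expected, 10)   # ~0.25
#' @export
base_cell_density <- function(N, D, d_over_D = 0.48) {
  if (any(D <= 0)) rlang::abort("D must be > 0")
  area <- pi * (d_over_D * D / 2)^2
  if (any(area == 0)) rlang::abort("zero base contact area")
  N / area
}

#' Per-cell stroking force from the gliding force
#'
#' Scales the gliding force by the pole-to-flat contact-area ratio
#' `S_W / S_L = pi W / (4 L)`.
#'
#' @param F_gliding Gliding force (N), `>= 0`.
#' @param geom A [cell_geometry()].
#' @return Stroking force (N).
#' @examples
#' stroking_force(5.48e-15, cell_geometry(6.7, 0.716))   # ~0.46e-15
#' @export
stroking_force <- function(F_gliding, geom) {
  if (any(F_gliding < 0)) rlang::abort("F_gliding must be >= 0")
  if (!inherits(geom, "cell_geometry")) rlang::abort("`geom` must be a cell_geometry")
  F_gliding * geom$area_ratio
}

#' Theoretical maximum propulsion force of a microcolony
#'
#' All base cells stroking in the same direction: `F_max = F_stroking * N`.
#'
#' @param F_stroking Per-cell stroking force (N).
#' @param N_base Base-cell count, `>= 0`.
#' @return Maximum propulsion force (N).
#' @export
max_prop_force <- function(F_stroking, N_base) {
  if (any(N_base < 0)) rlang::abort("N_base must be >= 0")
  F_stroking * N_base
}

#' Net force percentage
#'
#' `NFP = F_prop / F_max * 100`; the uncertainty on `F_prop` propagates
#' linearly (`F_max` is treated as exact).
#'
#' @param F_prop Net propulsion force (N), optionally with `sd`.
#' @param F_max Theoretical maximum (N), `> 0`.
#' @param sd Standard deviation of `F_prop` (N), default 0.
#' @return A tibble with `nfp_percent` and `nfp_sd_percent`.
#' @examples
#' nfp(7.38e-15, 18.86e-15, sd = 4.79e-15)   # 39.1 +/- 25.4 %
#' @export
nfp <- function(F_prop, F_max, sd = 0) {
  if (any(F_max <= 0)) rlang::abort("F_max must be > 0")
  tibble::tibble(nfp_percent = F_prop / F_max * 100,
                 nfp_sd_percent = sd / F_max * 100)
}

#' Assemble the full force-balance chain
#'
#' Builds the chain gliding force -> stroking force -> base-cell count ->
#' maximum propulsion -> NFP, either from printed force values or from
#' solver results via [chain_from_scene()].
#'
#' @param F_gliding Gliding force (N).
#' @param geom A [cell_geometry()].
#' @param model A [scaling_model()].
#' @param D Colony diameter (um).
#' @param F_prop Net propulsion force (N).
#' @param F_prop_sd Its standard deviation (N), default 0.
#' @param v_glide,v_colony Underlying speeds (um/s), carried as metadata.
#' @param depth_scale Depth normalization (um) the forces were computed
#'   under, carried for consistency checks.
#' @return A one-row `force_chain` tibble.
#' @export
force_chain <- function(F_gliding, geom, model, D, F_prop, F_prop_sd = 0,
                        v_glide = NA_real_, v_colony = NA_real_,
                        depth_scale = NA_real_) {
  Fs <- stroking_force(F_gliding, geom)
  Nb <- base_cell_count(D, model)$count
  Fm <- max_prop_force(Fs, Nb)
  np <- nfp(F_prop, Fm, F_prop_sd)
  out <- tibble::tibble(
    F_gliding_N = F_gliding, F_stroking_N = Fs, N_base = Nb,
    F_max_N = Fm, F_prop_N = F_prop, F_prop_sd_N = F_prop_sd,
    nfp_percent = np$nfp_percent, nfp_sd_percent = np$nfp_sd_percent,
    D_um = D, v_glide_um_s = v_glide, v_colony_um_s = v_colony,
    depth_scale_um = depth_scale)
  class(out) <- c("force_chain", class(out))
  out
}

#' Force chain from solver results
#'
#' Takes the drag on the target gliding bacterium and on the target
#' microcolony (both from [scene_drag()] or [traction_force()]), balances
#' propulsion against drag, and assembles the chain.  Refuses to combine
#' forces computed under different depth normalizations.
#'
#' @param gliding_force,colony_force [traction_force()] rows for the target
#'   bacterium and target microcolony.
#' @param geom A [cell_geometry()].
#' @param model A [scaling_model()].
#' @param D Colony diameter (um).
#' @param v_glide,v_colony Speeds (um/s) used in the two scenes.
#' @param v_colony_sd Speed standard deviation (um/s); scales into the
#'   F_prop uncertainty through drag linearity.
#' @param depth_scale_glide,depth_scale_colony Depth normalizations (um)
#'   under which each force was computed.
#' @return A `force_chain` tibble.
#' @export
chain_from_scene <- function(gliding_force, colony_force, geom, model, D,
                             v_glide, v_colony, v_colony_sd = 0,
                             depth_scale_glide = 1, depth_scale_colony = 1) {
  if (!isTRUE(all.equal(depth_scale_glide, depth_scale_colony))) {
    rlang::abort("forces computed under different depth_scale cannot be compared")
  }
  Fg <- sqrt(gliding_force$fx_N^2 + gliding_force$fy_N^2)
  Fp <- sqrt(colony_force$fx_N^2 + colony_force$fy_N^2)
  Fp_sd <- if (v_colony > 0) Fp * v_colony_sd / v_colony else 0
  force_chain(Fg, geom, model, D, Fp, Fp_sd,
              v_glide = v_glide, v_colony = v_colony,
              depth_scale = depth_scale_glide)
}

#' @export
tidy.force_chain <- function(x, ...) {
  tibble::tibble(
    term = c("F_gliding", "F_stroking", "N_base", "F_max", "F_prop", "NFP"),
    estimate = c(x$F_gliding_N, x$F_stroking_N, x$N_base, x$F_max_N,
                 x$F_prop_N, x$nfp_percent),
    std.error = c(NA, NA, NA, NA, x$F_prop_sd_N, x$nfp_sd_percent),
    unit = c("N", "N", "cells", "N", "N", "%"))
}

#' @export
glance.force_chain <- function(x, ...) {
  tibble::tibble(nfp_percent = x$nfp_percent,
                 nfp_sd_percent = x$nfp_sd_percent,
                 N_base = x$N_base, D_um = x$D_um)
}
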