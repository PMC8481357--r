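# Simulation scenes for the force-balance chain: a crowd of gliding
# bacteria (single-cell drag) and a drop full of moving microcolonies.

#' Gliding-bacteria scene for the single-cell drag computation
#'
#' Arranges parallel rod-shaped bacteria (capsules) in a cropped microdrop,
#' all moving in the same direction, with the target bacterium at the
#' centre.  Defaults follow the experimental setup: 8 cells of length
#' 6.7 um in an 18 um drop, gliding at 2 um/s in +x.
#'
#' @param n_cells Number of bacteria (default 8; a compact parallel raft is
#'   filled outward from the central target cell).
#' @param cell_length,cell_width Capsule dimensions (um).  The default
#'   width 0.716 um makes the perpendicular-to-flat contact-area ratio
#'   `pi W / (4 L)` equal 0.0839 for the 6.7 um cell.
#' @param drop_radius Drop radius (um), default 18.
#' @param speed Gliding speed (um/s), default 2 (the literature maximum).
#' @param row_spacing Lateral centre spacing of the raft rows (um).
#' @param column_gap End-to-end gap between cells in a row (um).
#' @return A list with `domain`, `bodies` (target first, at the drop
#'   centre) and `target_id`.
#' @export
scene_gliding_bacteria <- function(n_cells = 8, cell_length = 6.7,
                                   cell_width = 0.716, drop_radius = 18,
                                   speed = 2, row_spacing = 2.4,
                                   column_gap = 1.5) {
  if (n_cells < 1) rlang::abort("need at least one cell")
  domain <- fluid_domain(drop_radius)
  dx <- cell_length + column_gap
  # compact raft: two files of parallel cells side by side; the raft is
  # shifted so the target (the innermost cell) sits at the drop centre
  n_left <- ceiling(n_cells / 2); n_right <- n_cells - n_left
  pos <- rbind(
    if (n_left) cbind(-dx / 2, (seq_len(n_left) - (n_left + 1) / 2) * row_spacing),
    if (n_right) cbind(dx / 2, (seq_len(n_right) - (n_right + 1) / 2) * row_spacing))
  if (n_cells == 1) pos <- matrix(0, 1, 2)
  target <- which.min(pos[, 1]^2 + pos[, 2]^2)
  pos <- sweep(pos, 2, pos[target, ])
  bodies <- lapply(seq_len(n_cells), function(k)
    rigid_body(k, "capsule", position = pos[k, ],
               length = cell_length, width = cell_width,
               orientation = 0, velocity = c(speed, 0)))
  validate_geometry(domain, bodies)
  list(domain = domain, bodies = bodies, target_id = as.integer(target))
}

#' Microcolony scene for the propulsion-force computation
#'
#' Places disk-shaped microcolonies at non-overlapping random positions in
#' the microdrop, each moving at the same speed in an independent random
#' direction.  Defaults: 21 colonies of 50 um diameter in a 2 mm drop at
#' 0.031 um/s, the measured mean speed of 50 um colonies.
#'
#' @param n_colonies Number of colonies (default 21).
#' @param diameter Colony diameter (um), default 50.
#' @param drop_radius Drop radius (um), default 1000.
#' @param speed Speed (um/s), default 0.031.
#' @param seed RNG seed; placement and directions are reproducible.
#' @param margin Minimum surface separation (um), default 10.
#' @param max_tries Placement retries before a packing error.
#' @return A list with `domain`, `bodies` (target colony first, at the
#'   centre) and `target_id`.
#' @export
scene_colonies <- function(n_colonies = 21, diameter = 50, drop_radius = 1000,
                           speed = 0.031, seed = 1, margin = 10,
                           max_tries = 5000) {
  r <- diameter / 2
  domain <- fluid_domain(drop_radius)
  rdir <- function() { a <- runif(1, 0, 2 * pi); speed * c(cos(a), sin(a)) }
  bodies <- list()
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code()
  }
  bodies <- withr_seed(function() {
    out <- list(rigid_body(1L, "disk", position = c(0, 0), radius = r,
                           velocity = if (n_colonies == 1) speed * c(1, 0) else rdir()))
    placed <- matrix(c(0, 0), 1, 2)
    k <- 1L; tries <- 0L
    while (k < n_colonies) {
      tries <- tries + 1L
      if (tries > max_tries) {
        rlang::abort("could not place all colonies without overlap")
      }
      pos <- runif(2, -1, 1) * (drop_radius - r - margin)
      if (sqrt(sum(pos^2)) > drop_radius - r - margin) next
      if (any(sqrt((placed[, 1] - pos[1])^2 + (placed[, 2] - pos[2])^2) <
                2 * r + margin)) next
      k <- k + 1L
      placed <- rbind(placed, pos)
      out[[k]] <- rigid_body(k, "disk", position = pos, radius = r,
                             velocity = rdir())
    }
    out
  })
  validate_geometry(domain, bodies)
  list(domain = domain, bodies = bodies, target_id = 1L)
}

#' Drag force on the target body of a scene
#'
#' Discretizes and solves a scene from [scene_gliding_bacteria()] or
#' [scene_colonies()] in resistance mode and integrates the traction on
#' the target body.
#'
#' @param scene A scene list.
#' @param target_spacing Background node spacing (um); default one sixth of
#'   the smallest body feature.
#' @param config A [gmls_config()].
#' @return The [traction_force()] tibble for the target body, with the node
#'   count attached as attribute `n_nodes`.
#' @export
scene_drag <- function(scene, target_spacing = NULL, config = gmls_config()) {
  if (is.null(target_spacing)) {
    feat <- min(vapply(scene$bodies, body_feature, numeric(1)))
    target_spacing <- min(scene$domain$drop_radius / 12, 6 * feat)
  }
  nodes <- discretize(scene$domain, scene$bodies, target_spacing, config = config)
  sol <- solve_stokes(nodes, scene$domain, scene$bodies, config = config)
  target <- scene$bodies[[scene$target_id]]
  out <- traction_force(sol, target)
  attr(out, "n_nodes") <- nrow(nodes)
  attr(out, "residuals") <- sol$residuals[c("momentum", "continuity", "normal_eq")]
  out
}
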