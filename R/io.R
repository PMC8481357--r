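# File formats: TIFF stacks, result CSV/JSON, YAML scene files.

#' Read a grayscale TIFF stack
#'
#' @param path Single- or multi-page TIFF, 8/16-bit grayscale.
#' @return A list: `frames` (list of numeric matrices in `[0, 1]`) and
#'   `n_frames`.  RGB input or a missing file raises a format error;
#'   physical metadata (pixel size, frame interval) must come from the run
#'   configuration, never from silent defaults.
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) rlang::abort(sprintf(
                      "not a readable TIFF: %s (%s)", path, conditionMessage(e))))
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) {
      rlang::abort("RGB TIFF input is not supported; supply grayscale images")
    }
    p
  })
  list(frames = frames, n_frames = length(frames))
}

#' Write a list of matrices as a multi-page 16-bit TIFF
#'
#' @param frames List of numeric matrices in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(frames, path) {
  tiff::writeTIFF(lapply(frames, function(f) pmin(pmax(f, 0), 1)), path,
                  bits.per.sample = 16)
  invisible(path)
}

#' Write tracking results, events and a force chain to disk
#'
#' Tracks go to `tracks.csv` with the documented schema
#' `frame, colony_id, x_um, y_um, area_um2, diameter_um, volume_um3,
#' velocity_um_s, event_flag`; events to `events.csv`; the force chain (if
#' any) to `chain.json` with units in the key names; and `run_info.json`
#' records the tool version, a hash of the configuration and the seed.
#'
#' @param tracks A [link_tracks()] result (or `NULL`).
#' @param chain A [force_chain()] row (or `NULL`).
#' @param dir Output directory (created if needed).
#' @param config List of configuration values to hash into the provenance
#'   record.
#' @param seed Seed to record.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tracks = NULL, chain = NULL, dir, config = list(),
                          seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(tracks)) {
    tr <- tracks$tracks
    out <- data.frame(frame = tr$frame, colony_id = tr$track_id,
                      x_um = tr$x_um, y_um = tr$y_um, area_um2 = tr$area_um2,
                      diameter_um = tr$diameter_um, volume_um3 = tr$volume_um3,
                      velocity_um_s = tr$velocity_um_s,
                      event_flag = tr$event_flag)
    p <- file.path(dir, "tracks.csv")
    utils::write.csv(out, p, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(dir, "events.csv")
    utils::write.csv(as.data.frame(tracks$events), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(chain)) {
    p <- file.path(dir, "chain.json")
    jsonlite::write_json(as.list(chain), p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  info <- list(tool = "zorbkit",
               version = as.character(utils::packageVersion("zorbkit")),
               config_hash = rlang::hash(config), seed = seed)
  p <- file.path(dir, "run_info.json")
  jsonlite::write_json(info, p, auto_unbox = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Read a Stokes scene from YAML
#'
#' Fields: `drop_radius_um, nu_m2_s, rho_kg_m3, depth_scale_um, seed` and
#' `bodies` (each with `shape`, `dims_um`, `x_um`, `y_um`, and either
#' `vx_um_s`/`vy_um_s` or `free: true`).
#'
#' @param path YAML file.
#' @return A scene list (`domain`, `bodies`, `seed`).
#' @export
read_scene <- function(path) {
  y <- yaml::read_yaml(path)
  domain <- fluid_domain(y$drop_radius_um,
                         nu = y$nu_m2_s %||% 1e-6,
                         rho = y$rho_kg_m3 %||% 1000,
                         depth_scale = y$depth_scale_um %||% 1)
  bodies <- lapply(seq_along(y$bodies), function(k) {
    b <- y$bodies[[k]]
    vel <- if (isTRUE(b$free)) "free" else c(b$vx_um_s %||% 0, b$vy_um_s %||% 0)
    if (b$shape == "disk") {
      rigid_body(k, "disk", position = c(b$x_um, b$y_um),
                 radius = b$dims_um[[1]] / 2, velocity = vel)
    } else {
      rigid_body(k, "capsule", position = c(b$x_um, b$y_um),
                 length = b$dims_um[[1]], width = b$dims_um[[2]],
                 orientation = b$orientation_rad %||% 0, velocity = vel)
    }
  })
  list(domain = domain, bodies = bodies, seed = y$seed %||% NA, target_id = 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scene to YAML
#'
#' @param scene Scene list (`domain`, `bodies`, optional `seed`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  d <- scene$domain
  y <- list(drop_radius_um = d$drop_radius, nu_m2_s = d$nu,
            rho_kg_m3 = d$rho, depth_scale_um = d$depth_scale,
            seed = scene$seed %||% NA,
            bodies = lapply(scene$bodies, function(b) {
              base <- list(shape = b$shape, x_um = b$position[1],
                           y_um = b$position[2])
              base$dims_um <- if (b$shape == "disk") list(2 * b$radius) else
                list(b$length, b$width)
              if (b$shape == "capsule") base$orientation_rad <- b$orientation
              if (b$free) base$free <- TRUE else {
                base$vx_um_s <- b$velocity[1]; base$vy_um_s <- b$velocity[2]
              }
              base
            }))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write a Stokes solution summary to JSON
#'
#' @param solution A [solve_stokes()] result.
#' @param forces Tibble of [traction_force()] rows (one per body).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stokes_result <- function(solution, forces, path) {
  per_body <- lapply(seq_len(nrow(forces)), function(k) {
    list(body_id = forces$body_id[k],
         force_N = c(forces$fx_N[k], forces$fy_N[k]),
         torque_Nm = forces$tz_Nm[k])
  })
  res <- solution$residuals
  out <- list(per_body = per_body,
              residuals = res[c("momentum", "continuity", "bc", "normal_eq")],
              node_count = nrow(solution$nodes),
              estimator_history = if (!is.null(solution$refinement_history))
                solution$refinement_history$estimator else res$estimator)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
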