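# Synthetic-data generators: every fixture used by the quantification
# pipeline can be produced in code with known ground truth.  Generators are
# pure functions of their parameters plus a seed (bit-reproducible).

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Scene specification for a synthetic microcolony time-lapse
#'
#' Encodes the statistical structure the analysis assumes: dark disks on a
#' bright noisy background that grow, move with a speed positively
#' correlated with size, and merge on schedule.  The speed model is
#' `v = coeff * D^gamma` with multiplicative noise, anchored so that a
#' 50 um colony moves at 0.031 um/s on average with 0.021 um/s spread (the
#' measured values); the size exponent `gamma = 0.5` is a fixture
#' parameter, not an inference.
#'
#' @param n_colonies Number of colonies.
#' @param frames Number of frames.
#' @param diameter_range Initial diameter range (um).
#' @param growth_rate Diameter growth (um/frame).
#' @param speed_anchor Mean speed (um/s) at the anchor diameter.
#' @param speed_sd Speed spread (um/s) at the anchor diameter.
#' @param anchor_D Anchor diameter (um), default 50.
#' @param speed_gamma Size exponent of the speed model.
#' @param merge_schedule List of `list(frame =, ids = c(a, b))` scripted
#'   merges.
#' @param pixel_size um/px (default 1.04).
#' @param frame_interval Seconds per frame (default 300).
#' @param img_size Image size in px (square), default 256.
#' @param snr Contrast-to-noise ratio (default 8).
#' @param seed RNG seed.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(n_colonies = 5, frames = 10,
                       diameter_range = c(20, 60), growth_rate = 0.2,
                       speed_anchor = 0.031, speed_sd = 0.021, anchor_D = 50,
                       speed_gamma = 0.5, merge_schedule = list(),
                       pixel_size = 1.04, frame_interval = 300,
                       img_size = 256, snr = 8, seed = 1) {
  structure(as.list(environment()), class = "scene_spec")
}

render_disks <- function(xy, D, spec) {
  npx <- spec$img_size
  img <- matrix(0.85, npx, npx)
  ax <- ((seq_len(npx)) - 1) * spec$pixel_size
  for (k in seq_len(nrow(xy))) {
    r <- D[k] / 2
    ix <- which(abs(ax - xy[k, 1]) <= r)
    iy <- which(abs(ax - xy[k, 2]) <= r)
    if (!length(ix) || !length(iy)) next
    sub <- outer((ax[ix] - xy[k, 1])^2, (ax[iy] - xy[k, 2])^2, `+`) <= r^2
    img[ix, iy][sub] <- 0.25
  }
  img
}

#' Generate a synthetic microcolony time-lapse with ground truth
#'
#' @param spec A [scene_spec()].
#' @return A list: `frames` (list of image matrices), `truth` (per-frame
#'   tibble of true id, centre, diameter, speed), `events` (true merge
#'   list), `spec`.
#' @export
gen_timelapse <- function(spec) {
  with_seed(spec$seed, {
    npx <- spec$img_size
    fov <- (npx - 1) * spec$pixel_size
    n <- spec$n_colonies
    D <- runif(n, spec$diameter_range[1], spec$diameter_range[2])
    margin <- max(D) / 2 + 2
    xy <- cbind(runif(n, margin, fov - margin), runif(n, margin, fov - margin))
    # reject overlaps by redrawing (bounded)
    for (tries in 1:500) {
      dd <- as.matrix(stats::dist(xy))
      diag(dd) <- Inf
      bad <- which(apply(dd - outer(D, D, `+`) / 2 - 4, 1, min) < 0)
      if (!length(bad)) break
      xy[bad, ] <- cbind(runif(length(bad), margin, fov - margin),
                         runif(length(bad), margin, fov - margin))
    }
    coeff <- spec$speed_anchor / spec$anchor_D^spec$speed_gamma
    cv <- if (spec$speed_anchor > 0) spec$speed_sd / spec$speed_anchor else 0
    speed <- pmax(0, coeff * D^spec$speed_gamma * (1 + cv * rnorm(n)))
    ang <- runif(n, 0, 2 * pi)
    vel <- cbind(cos(ang), sin(ang)) * speed
    sched <- spec$merge_schedule
    # scripted merges: partners start adjacent and drift together so that
    # they are in contact when the merge fires
    for (ev in sched) {
      a <- ev$ids[1]; b <- ev$ids[2]
      # the pair closes at 7 um per frame so it is still clearly separated
      # (~10 um, beyond the segmentation blur reach) one frame before contact
      # and overlaps by ~2 um at the scheduled frame
      step <- 12
      gap0 <- step * max(ev$frame, 1) - 2
      dist <- (D[a] + D[b]) / 2 + gap0
      # place the partner towards the field centre (jittered) so the
      # full approach path stays inside the rendered area
      ctr <- c(fov / 2, fov / 2)
      base_ang <- atan2(ctr[2] - xy[a, 2], ctr[1] - xy[a, 1])
      ang_b <- base_ang + runif(1, -0.3, 0.3)
      xy[b, ] <- xy[a, ] + dist * c(cos(ang_b), sin(ang_b))
      xy[b, ] <- pmin(pmax(xy[b, ], margin), fov - margin)
      dirv <- (xy[a, ] - xy[b, ]) / sqrt(sum((xy[a, ] - xy[b, ])^2))
      vel[b, ] <- vel[a, ] + (step / spec$frame_interval) * dirv
      speed[b] <- sqrt(sum(vel[b, ]^2))
    }
    alive <- rep(TRUE, n)
    frames <- vector("list", spec$frames)
    truth <- vector("list", spec$frames)
    events <- list()
    id <- seq_len(n)
    for (f in seq_len(spec$frames)) {
      for (ev in sched) {
        if (ev$frame == f - 1) {
          a <- ev$ids[1]; b <- ev$ids[2]
          if (!alive[a] || !alive[b]) rlang::abort("merge schedule references a consumed colony")
          area <- pi * (D[a]^2 + D[b]^2) / 4
          xy[a, ] <- (xy[a, ] * D[a]^2 + xy[b, ] * D[b]^2) / (D[a]^2 + D[b]^2)
          D[a] <- 2 * sqrt(area / pi)
          alive[b] <- FALSE
          events[[length(events) + 1]] <- list(frame = f - 1, parents = c(id[a], id[b]),
                                               child = id[a])
        }
      }
      keep <- which(alive)
      frames[[f]] <- render_disks(xy[keep, , drop = FALSE], D[keep], spec)
      if (spec$snr > 0) {
        frames[[f]] <- frames[[f]] +
          matrix(rnorm(npx * npx, 0, 0.6 / spec$snr), npx, npx)
        frames[[f]] <- pmin(pmax(frames[[f]], 0), 1)
      }
      truth[[f]] <- tibble::tibble(frame = f - 1L, id = id[keep],
                                   x_um = xy[keep, 1], y_um = xy[keep, 2],
                                   diameter_um = D[keep],
                                   speed_um_s = speed[keep])
      # advance; reflect at the field margins so colonies keep their
      # nominal speed instead of sticking to the wall
      step <- vel * spec$frame_interval
      xy[keep, ] <- xy[keep, , drop = FALSE] + step[keep, , drop = FALSE]
      for (k in keep) for (c2 in 1:2) {
        if (xy[k, c2] < margin) {
          xy[k, c2] <- 2 * margin - xy[k, c2]; vel[k, c2] <- -vel[k, c2]
        } else if (xy[k, c2] > fov - margin) {
          xy[k, c2] <- 2 * (fov - margin) - xy[k, c2]; vel[k, c2] <- -vel[k, c2]
        }
      }
      # keep unscripted colonies disjoint: pairs not scheduled to merge
      # bounce apart elastically when they would touch
      sched_pairs <- vapply(sched, function(ev) paste(sort(ev$ids), collapse = "-"),
                            character(1))
      if (base::length(keep) >= 2) {
        for (ii in seq_along(keep)[-1]) for (jj in seq_len(ii - 1)) {
          k <- keep[ii]; l <- keep[jj]
          if (paste(sort(c(id[k], id[l])), collapse = "-") %in% sched_pairs) next
          dv <- xy[k, ] - xy[l, ]
          d <- sqrt(sum(dv^2))
          minsep <- (D[k] + D[l]) / 2 + 6
          if (d < minsep && d > 0) {
            nrm <- dv / d
            push <- (minsep - d) / 2
            xy[k, ] <- xy[k, ] + push * nrm
            xy[l, ] <- xy[l, ] - push * nrm
            vk <- sum(vel[k, ] * nrm); vl <- sum(vel[l, ] * nrm)
            if (vk - vl < 0) {   # approaching: exchange normal components
              vel[k, ] <- vel[k, ] + (vl - vk) * nrm
              vel[l, ] <- vel[l, ] + (vk - vl) * nrm
            }
          }
        }
      }
      D[keep] <- D[keep] + spec$growth_rate
    }
    list(frames = frames, truth = dplyr::bind_rows(truth), events = events,
         spec = spec)
  })
}

#' Synthetic base-cell image for a colony of given diameter
#'
#' Bright Gaussian spots on a dark background; the spot count is the
#' scaling-law prediction, optionally Poisson-distributed, and spots are
#' confined to the base circle of diameter `d_over_D * D`.
#'
#' @param D Colony diameter (um), in the measured 10-100 um range.
#' @param law A [scaling_model()] (default the fitted power law).
#' @param noise `"poisson"` or `"none"` count noise.
#' @param seed RNG seed.
#' @param pixel_size um/px (default 1).
#' @param d_over_D Base circle ratio (default 0.48).
#' @param spot_sigma Spot width in px (default 1.6).
#' @param snr Background noise level as contrast/noise (default 12;
#'   0 disables noise).
#' @return A list: `image`, `n_true`, `coordinates` (true spot centres,
#'   px), `D`.
#' @export
gen_basecell_image <- function(D, law = scaling_model("power_fit"),
                               noise = c("poisson", "none"), seed = 1,
                               pixel_size = 0.5, d_over_D = 0.48,
                               spot_sigma = 1.4, snr = 12) {
  noise <- match.arg(noise)
  if (D < 10 || D > 100) {
    rlang::warn("D outside the measured 10-100 um range")
  }
  with_seed(seed, {
    mean_n <- predict_scaling(law, D)
    n_true <- if (noise == "poisson") rpois(1, mean_n) else
      as.integer(round_half_up(mean_n))
    npx <- ceiling(D / pixel_size) + 24
    img <- matrix(0, npx, npx)
    c0 <- (npx + 1) / 2
    r_px <- d_over_D * D / 2 / pixel_size
    # spots kept ~3 sigma apart so each remains a resolvable maximum; the
    # separation relaxes for crowded small bases (down to 2 sigma)
    sep <- 3 * spot_sigma
    repeat {
      pts <- matrix(numeric(0), 0, 2)
      guard <- 0
      while (nrow(pts) < n_true && guard < 20000) {
        guard <- guard + 1
        a <- runif(1, 0, 2 * pi); r <- r_px * sqrt(runif(1))
        p <- c(c0 + r * cos(a), c0 + r * sin(a))
        if (!nrow(pts) || min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) > sep^2) {
          pts <- rbind(pts, p)
        }
      }
      if (nrow(pts) == n_true) break
      sep <- sep * 0.85
      if (sep < 2 * spot_sigma) {
        rlang::abort("could not place all spots with the minimum separation")
      }
    }
    ax <- seq_len(npx)
    for (k in seq_len(nrow(pts))) {
      gx <- exp(-(ax - pts[k, 1])^2 / (2 * spot_sigma^2))
      gy <- exp(-(ax - pts[k, 2])^2 / (2 * spot_sigma^2))
      img <- img + outer(gx, gy)
    }
    img <- pmin(img, 1.5) / 1.5
    if (snr > 0) {
      img <- pmin(pmax(img + matrix(rnorm(npx^2, 0, (1 / 1.5) / snr), npx, npx), 0), 1)
    }
    list(image = img, n_true = as.integer(n_true),
         coordinates = tibble::tibble(x_px = pts[, 1], y_px = pts[, 2]),
         D = D)
  })
}

# moment-matched truncated-normal parameters: find (mu0, sigma0) such that
# the normal truncated at zero has the requested mean and sd
truncnorm_params <- function(mean, sd) {
  if (sd == 0) return(c(mean, 0))
  obj <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    al <- -mu / s
    lam <- stats::dnorm(al) / (1 - stats::pnorm(al))
    m <- mu + s * lam
    v <- s^2 * (1 + al * lam - lam^2)
    (m - mean)^2 + (sqrt(max(v, 0)) - sd)^2
  }
  par <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))$par
  c(par[1], exp(par[2]))
}

#' Synthetic colony speed samples
#'
#' Draws from a normal truncated at zero whose post-truncation moments
#' match the requested mean and sd (the measured 0.031 +/- 0.021 um/s for
#' 50 um colonies); the underlying normal parameters are adjusted for the
#' truncation, so the sample moments converge to the targets.
#'
#' @param n Number of samples, `>= 1`.
#' @param mean Target mean (um/s), default 0.031.
#' @param sd Target sd (um/s), default 0.021.
#' @param seed RNG seed.
#' @return Numeric vector of non-negative speeds.
#' @export
gen_velocity_samples <- function(n, mean = 0.031, sd = 0.021, seed = 1) {
  stopifnot(n >= 1)
  if (sd == 0) return(rep(mean, n))
  par <- truncnorm_params(mean, sd)
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      draw <- rnorm(2 * (n - length(out)) + 10, par[1], par[2])
      out <- c(out, draw[draw >= 0])
    }
    out[seq_len(n)]
  })
}

#' Synthetic field of rod-shaped cells with an orientation model
#'
#' @param n_cells Number of cells, `>= 1`.
#' @param mean_length Mean cell length (um), default 6.7.
#' @param model `"aligned"` (all parallel), `"random"` (uniform angles) or
#'   `"clustered"` (patches of common orientation).
#' @param field Field side length (um), default 60.
#' @param seed RNG seed.
#' @param render Also rasterize the rods into an image (default `FALSE`).
#' @param pixel_size um/px when rendering.
#' @return A list: `cells` tibble (`x`, `y`, `angle`, `length`), and
#'   `image` when rendered.
#' @export
gen_cell_field <- function(n_cells, mean_length = 6.7,
                           model = c("aligned", "random", "clustered"),
                           field = 60, seed = 1, render = FALSE,
                           pixel_size = 0.5) {
  model <- match.arg(model)
  stopifnot(n_cells >= 1)
  with_seed(seed, {
    x <- runif(n_cells, 0, field); y <- runif(n_cells, 0, field)
    len <- pmax(1, rnorm(n_cells, mean_length, mean_length * 0.15))
    angle <- switch(model,
      aligned = rep(0, n_cells),
      random = runif(n_cells, 0, 180),
      clustered = {
        k <- max(1, round(n_cells / 12))
        centers <- cbind(runif(k, 0, field), runif(k, 0, field))
        base <- runif(k, 0, 180)
        nearest <- apply(cbind(x, y), 1, function(p)
          which.min((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2))
        (base[nearest] + rnorm(n_cells, 0, 8)) %% 180
      })
    cells <- tibble::tibble(x = x, y = y, angle = angle, length = len)
    out <- list(cells = cells)
    if (render) {
      npx <- ceiling(field / pixel_size)
      img <- matrix(0, npx, npx)
      for (i in seq_len(n_cells)) {
        t <- seq(-len[i] / 2, len[i] / 2, by = pixel_size / 2)
        px <- round((x[i] + t * cos(angle[i] * pi / 180)) / pixel_size)
        py <- round((y[i] + t * sin(angle[i] * pi / 180)) / pixel_size)
        ok <- px >= 1 & px <= npx & py >= 1 & py <= npx
        img[cbind(px[ok], py[ok])] <- 1
      }
      out$image <- img
    }
    out
  })
}
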