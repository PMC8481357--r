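# Frame-to-frame linear-assignment tracking with merge/split detection.

#' Solve a linear assignment problem (Hungarian algorithm)
#'
#' Minimum-cost perfect matching on a square cost matrix, by the O(n^3)
#' augmenting-path (Jonker-Volgenant style) algorithm with dual potentials.
#'
#' @param cost Square numeric cost matrix (finite values).
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`.
#' @export
solve_lap <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0) return(integer(0))
  # potentials and assignment, 1-based port of the classical algorithm
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j] = row assigned to column j (0 = none)
  way <- integer(n + 1)
  INF <- sum(abs(cost)) + 1
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0 + 0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1) break
    }
  }
  ans <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) ans[p[j]] <- j - 1
  ans
}

# frame-to-frame links: square LAP with birth/death padding
link_frames <- function(rec0, rec1, max_dist) {
  n0 <- nrow(rec0); n1 <- nrow(rec1)
  if (n0 == 0 || n1 == 0) {
    return(tibble::tibble(from = integer(), to = integer()))
  }
  BIG <- 1e6
  d <- sqrt(outer(rec0$x_um, rec1$x_um, `-`)^2 + outer(rec0$y_um, rec1$y_um, `-`)^2)
  d[d > max_dist] <- BIG
  m <- n0 + n1
  C <- matrix(BIG, m, m)
  C[seq_len(n0), seq_len(n1)] <- d
  C[cbind(seq_len(n0), n1 + seq_len(n0))] <- max_dist * 1.05   # death
  C[cbind(n0 + seq_len(n1), seq_len(n1))] <- max_dist * 1.05   # birth
  C[n0 + seq_len(n1), n1 + seq_len(n0)] <- 0
  a <- solve_lap(C)
  from <- seq_len(n0)
  to <- a[seq_len(n0)]
  ok <- to <= n1 & C[cbind(from, to)] < BIG & C[cbind(from, to)] <= max_dist
  tibble::tibble(from = from[ok], to = to[ok])
}

#' Link per-frame colony records into tracks, with merge/split events
#'
#' Frame-to-frame assignment minimizes total centroid displacement under a
#' maximum linking distance (solved as a padded linear assignment problem).
#' An unlinked colony whose footprint overlaps two or more colonies of the
#' previous frame is recorded as a merge; the time-reversed pattern as a
#' split.  Event steps are excluded from displacement statistics, which
#' removes the spurious centre-of-mass jumps merges would otherwise inject
#' into the velocity series.
#'
#' @param records Tibble of per-frame colony records ([morphometrics()]
#'   output over several frames; frames must be 0-based and consecutive).
#' @param label_stacks Optional list of label matrices (one per frame), used
#'   for the overlap test of merge/split detection; without masks the test
#'   falls back to a centroid-within-radius rule.
#' @param max_dist Maximum linking distance (um) per step (default 30).
#' @param frame_interval Seconds between frames (default 300, i.e. 5 min).
#' @param area_slack Relative tolerance on parent-area vs child-area
#'   consistency for events (default 0.3).
#' @return A list of class `track_set`: `tracks` (records plus `track_id`
#'   and per-step `velocity_um_s`, `NA` at event steps), `events` tibble.
#' @export
link_tracks <- function(records, label_stacks = NULL, max_dist = 30,
                        frame_interval = 300, area_slack = 0.3) {
  frames <- sort(unique(records$frame))
  recs <- records
  recs$track_id <- NA_integer_
  recs$event_flag <- ""
  next_id <- 0L
  events <- list()
  by_frame <- split(seq_len(nrow(recs)), recs$frame)
  # seed first frame
  if (length(frames)) {
    i0 <- by_frame[[as.character(frames[1])]]
    recs$track_id[i0] <- seq_along(i0)
    next_id <- length(i0)
  }
  for (fi in seq_along(frames)[-1]) {
    f0 <- frames[fi - 1]; f1 <- frames[fi]
    i0 <- by_frame[[as.character(f0)]]
    i1 <- by_frame[[as.character(f1)]]
    r0 <- recs[i0, ]; r1 <- recs[i1, ]
    ln <- link_frames(r0, r1, max_dist)
    unlinked1 <- setdiff(seq_len(nrow(r1)), ln$to)
    unlinked0 <- setdiff(seq_len(nrow(r0)), ln$from)
    overlap_parents <- function(k1) {
      if (!is.null(label_stacks)) {
        lab0 <- label_stacks[[fi - 1]]; lab1 <- label_stacks[[fi]]
        sel <- lab1 == r1$label[k1]
        hits <- unique(lab0[sel]); hits <- hits[hits > 0]
        which(r0$label %in% hits)
      } else {
        # parent disks lie (mostly) inside the merged child: centres within
        # the sum of the two radii
        dd <- sqrt((r0$x_um - r1$x_um[k1])^2 + (r0$y_um - r1$y_um[k1])^2)
        which(dd <= (r1$diameter_um[k1] + r0$diameter_um) / 2)
      }
    }
    # merge detection considers every child whose footprint covers >= 2
    # prior colonies, whether the assignment linked it or not: a linked
    # child showing a sudden area increase plus a vanished overlapping
    # parent is the centre-of-mass jump signature of a merge
    merge_candidates <- c(unlinked1,
                          ln$to[r1$area_um2[ln$to] >
                                  (1 + area_slack) * r0$area_um2[ln$from]])
    for (k1 in unique(merge_candidates)) {
      linked_par <- ln$from[ln$to == k1]
      par <- union(linked_par, intersect(overlap_parents(k1), unlinked0))
      if (length(par) >= 2) {
        a_before <- sum(r0$area_um2[par]); a_after <- r1$area_um2[k1]
        if (abs(a_after - a_before) / a_before <= area_slack) {
          events[[length(events) + 1]] <- tibble::tibble(
            type = "merge", frame = f1,
            parents = paste(recs$track_id[i0[par]], collapse = ";"),
            children = NA_character_,
            area_before = a_before, area_after = a_after)
          next_id <- next_id + 1L
          recs$track_id[i1[k1]] <- next_id
          recs$event_flag[i1[k1]] <- "merge"
          events[[length(events)]]$children <- as.character(next_id)
          if (length(linked_par)) {
            ln <- ln[ln$to != k1, ]
            unlinked0 <- setdiff(unlinked0, par)
          }
          unlinked1 <- setdiff(unlinked1, k1)
          next
        }
      }
      if (k1 %in% unlinked1) {
        next_id <- next_id + 1L
        recs$track_id[i1[k1]] <- next_id
      }
    }
    recs$track_id[i1[ln$to]] <- recs$track_id[i0[ln$from]]
    # splits: one vanished colony overlapping >= 2 new colonies
    newborn <- unlinked1[recs$event_flag[i1[unlinked1]] == ""]
    for (k0 in unlinked0) {
      if (!is.null(label_stacks)) {
        lab0 <- label_stacks[[fi - 1]]; lab1 <- label_stacks[[fi]]
        sel <- lab0 == r0$label[k0]
        hits <- unique(lab1[sel]); hits <- hits[hits > 0]
        ch <- which(r1$label %in% hits)
      } else {
        dd <- sqrt((r1$x_um - r0$x_um[k0])^2 + (r1$y_um - r0$y_um[k0])^2)
        ch <- which(dd <= (r0$diameter_um[k0] + r1$diameter_um) / 2)
      }
      ch <- intersect(ch, newborn)
      if (length(ch) >= 2) {
        a_before <- r0$area_um2[k0]; a_after <- sum(r1$area_um2[ch])
        if (abs(a_after - a_before) / a_before <= area_slack) {
          events[[length(events) + 1]] <- tibble::tibble(
            type = "split", frame = f1,
            parents = as.character(recs$track_id[i0[k0]]),
            children = paste(recs$track_id[i1[ch]], collapse = ";"),
            area_before = a_before, area_after = a_after)
          recs$event_flag[i1[ch]] <- "split"
        }
      }
    }
  }
  # per-step velocities within tracks; NA at event-flagged steps
  recs <- dplyr::arrange(recs, .data$track_id, .data$frame)
  recs <- dplyr::group_by(recs, .data$track_id)
  recs <- dplyr::mutate(recs,
    step_um = sqrt((.data$x_um - dplyr::lag(.data$x_um))^2 +
                   (.data$y_um - dplyr::lag(.data$y_um))^2),
    velocity_um_s = ifelse(.data$event_flag == "" ,
                           .data$step_um / frame_interval, NA_real_))
  recs <- dplyr::ungroup(recs)
  ev <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(type = character(), frame = integer(), parents = character(),
                   children = character(), area_before = numeric(),
                   area_after = numeric())
  structure(list(tracks = recs, events = ev,
                 frame_interval = frame_interval),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d records, %d tracks, %d events\n",
              nrow(x$tracks), dplyr::n_distinct(x$tracks$track_id),
              nrow(x$events)))
  invisible(x)
}

#' Volume-weighted per-frame summary of a track set
#'
#' Spherical-equivalent colony volumes weight all means, so large colonies
#' dominate the reported diameter and velocity trends.  Frames with no
#' colonies (or no valid velocities) yield `NA`, not 0.
#'
#' @param tracks A [link_tracks()] result.
#' @return A tibble with per-frame `weighted_mean_D`,
#'   `weighted_mean_velocity`, and `n_colonies`.
#' @export
weighted_timeseries <- function(tracks) {
  tr <- tracks$tracks
  wm <- function(x, w) {
    ok <- !is.na(x) & !is.na(w)
    if (!any(ok)) return(NA_real_)
    sum(x[ok] * w[ok]) / sum(w[ok])
  }
  out <- dplyr::group_by(tr, .data$frame)
  dplyr::summarise(out,
    weighted_mean_D = wm(.data$diameter_um, .data$volume_um3),
    weighted_mean_velocity = wm(.data$velocity_um_s, .data$volume_um3),
    n_colonies = dplyr::n())
}

#' Mature-microcolony size/abundance comparison between two timepoints
#'
#' Only components strictly greater than the pixel-area threshold enter
#' (1000 px^2 by default, which at ~1.04 um/px corresponds to mature
#' colonies of D > 37 um), so newly formed microcolonies are excluded.
#'
#' @param labels_t1,labels_t2 Label matrices at the two timepoints.
#' @param pixel_size Pixel size (um/px).
#' @param min_area_px2 Strict pixel-area threshold (default 1000).
#' @return A list: `colonies` tibble (timepoint, label, area_px2,
#'   diameter_um) and `summary` tibble (count and median D per timepoint).
#' @export
cccp_table <- function(labels_t1, labels_t2, pixel_size, min_area_px2 = 1000) {
  if (missing(pixel_size) || is.null(pixel_size)) {
    rlang::abort("`pixel_size` (um/px) is required")
  }
  one <- function(lab, tp) {
    nlab <- max(lab)
    if (nlab == 0) return(NULL)
    area_px <- tabulate(lab[lab > 0], nlab)
    keep <- which(area_px > min_area_px2)
    if (!length(keep)) return(NULL)
    tibble::tibble(timepoint = tp, label = keep, area_px2 = area_px[keep],
                   diameter_um = 2 * sqrt(area_px[keep] * pixel_size^2 / pi))
  }
  colonies <- dplyr::bind_rows(one(labels_t1, 1L), one(labels_t2, 2L))
  if (is.null(colonies) || !nrow(colonies)) {
    colonies <- tibble::tibble(timepoint = integer(), label = integer(),
                               area_px2 = numeric(), diameter_um = numeric())
  }
  summary <- dplyr::summarise(dplyr::group_by(colonies, .data$timepoint),
                              n = dplyr::n(),
                              median_D = stats::median(.data$diameter_um))
  list(colonies = colonies, summary = summary)
}
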