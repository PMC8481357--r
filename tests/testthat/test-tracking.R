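test_that("the LAP solver matches exhaustive enumeration", {
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n)
    a <- solve_lap(cost)
    oracle <- brute_lap(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]), oracle$cost, tolerance = 1e-12)
  }
})

make_records <- function(frames_xy, area = 400) {
  # frames_xy: list per frame of matrix (n x 2) centroids in um
  dplyr::bind_rows(lapply(seq_along(frames_xy), function(f) {
    xy <- frames_xy[[f]]
    if (!nrow(xy)) return(NULL)
    D <- 2 * sqrt(area / pi)
    tibble::tibble(frame = f - 1L, label = seq_len(nrow(xy)),
                   x_um = xy[, 1], y_um = xy[, 2], area_um2 = area,
                   diameter_um = D, volume_um3 = (4 / 3) * pi * (D / 2)^3,
                   inside_roi = TRUE)
  }))
}

test_that("two stationary colonies give two tracks, no events, zero velocity", {
  xy <- cbind(c(20, 60), c(20, 60))
  recs <- make_records(rep(list(xy), 5))
  tr <- link_tracks(recs, frame_interval = 300)
  expect_equal(dplyr::n_distinct(tr$tracks$track_id), 2)
  expect_equal(nrow(tr$events), 0)
  v <- tr$tracks$velocity_um_s
  expect_true(all(v[!is.na(v)] == 0))
})

test_that("jittered assignments equal the brute-force global minimum", {
  set.seed(8)
  for (rep in 1:6) {
    n <- sample(3:6, 1)
    xy0 <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    xy1 <- xy0 + matrix(rnorm(2 * n, 0, 2), n)
    perm <- sample(n)
    r0 <- make_records(list(xy0))
    r1 <- make_records(list(xy1[perm, , drop = FALSE]))
    r1$frame <- 1L
    ln <- zorbkit:::link_frames(r0, r1, max_dist = 30)
    cost <- sqrt(outer(xy0[, 1], xy1[perm, 1], `-`)^2 +
                 outer(xy0[, 2], xy1[perm, 2], `-`)^2)
    oracle <- brute_lap(cost)
    got <- ln$to[order(ln$from)]
    expect_equal(got, oracle$assignment)
  }
})

test_that("a scripted merge is detected and kept out of the velocity series", {
  # two colonies approach then merge at frame 5 (areas add, centroid jumps)
  frames <- list()
  a1 <- 400; a2 <- 500
  for (f in 0:9) {
    if (f < 5) {
      xy <- rbind(c(30 + f, 50), c(70 - f, 50))
      frames[[f + 1]] <- xy
    } else {
      frames[[f + 1]] <- rbind(c(52, 50))
    }
  }
  recs <- dplyr::bind_rows(lapply(seq_along(frames), function(f) {
    xy <- frames[[f]]
    areas <- if (nrow(xy) == 2) c(a1, a2) else a1 + a2
    D <- 2 * sqrt(areas / pi)
    tibble::tibble(frame = f - 1L, label = seq_len(nrow(xy)),
                   x_um = xy[, 1], y_um = xy[, 2], area_um2 = areas,
                   diameter_um = D, volume_um3 = (4 / 3) * pi * (D / 2)^3,
                   inside_roi = TRUE)
  }))
  tr <- link_tracks(recs, max_dist = 10, frame_interval = 300)
  expect_equal(nrow(tr$events), 1)
  expect_equal(tr$events$type, "merge")
  expect_equal(tr$events$frame, 5)
  # the merged colony's first step carries no velocity (flagged event)
  merged <- tr$tracks[tr$tracks$event_flag == "merge", ]
  expect_equal(nrow(merged), 1)
  expect_true(is.na(merged$velocity_um_s))
  # pre-merge steps carry the scripted 1 um per 300 s; the merged colony
  # is stationary afterwards
  tt <- tr$tracks
  pre <- tt$velocity_um_s[tt$frame <= 4 & !is.na(tt$velocity_um_s)]
  post <- tt$velocity_um_s[tt$frame > 5 & !is.na(tt$velocity_um_s)]
  expect_equal(max(abs(pre - 1 / 300)), 0, tolerance = 1e-12)
  expect_true(all(post == 0))
})

test_that("volume-weighted means follow the weighting identity", {
  # two colonies, V1 = 2 V2, velocities 1 and 4 -> weighted mean 2
  V2 <- 100; V1 <- 200
  tr <- list(tracks = tibble::tibble(
    frame = c(1L, 1L), track_id = 1:2, x_um = 0, y_um = 0,
    area_um2 = 1, diameter_um = c(10, 20), volume_um3 = c(V1, V2),
    velocity_um_s = c(1, 4), event_flag = ""),
    events = tibble::tibble())
  ts <- weighted_timeseries(tr)
  expect_equal(ts$weighted_mean_velocity, 2)
  # identical volumes reduce to the arithmetic mean
  tr$tracks$volume_um3 <- c(5, 5)
  expect_equal(weighted_timeseries(tr)$weighted_mean_velocity, 2.5)
})

test_that("frames without valid velocities report NA, not zero", {
  tr <- list(tracks = tibble::tibble(
    frame = 0L, track_id = 1L, x_um = 0, y_um = 0, area_um2 = 1,
    diameter_um = 15, volume_um3 = 10, velocity_um_s = NA_real_,
    event_flag = ""))
  ts <- weighted_timeseries(tr)
  expect_true(is.na(ts$weighted_mean_velocity))
  expect_equal(ts$weighted_mean_D, 15)
})

test_that("the mature-colony table applies the strict pixel threshold", {
  lab1 <- matrix(0L, 120, 120)
  # component of exactly 1000 px^2: excluded
  lab1[1:40, 1:25] <- 1L
  # component of 1600 px^2: included
  lab1[60:99, 60:99] <- 2L
  lab2 <- matrix(0L, 120, 120)
  lab2[30:89, 30:89] <- 1L     # 3600 px^2
  ct <- cccp_table(lab1, lab2, pixel_size = 1.037)
  expect_equal(nrow(ct$colonies[ct$colonies$timepoint == 1, ]), 1)
  expect_equal(ct$colonies$area_px2[ct$colonies$timepoint == 1], 1600)
  # the 1000 px^2 cutoff corresponds to D ~ 37 um at 1.037 um/px
  D_cut <- 2 * sqrt(1000 * 1.037^2 / pi)
  expect_equal(D_cut, 37, tolerance = 0.01)
})

test_that("merging between timepoints lowers counts and raises median size", {
  lab1 <- matrix(0L, 200, 200)
  lab1[10:59, 10:59] <- 1L; lab1[100:149, 100:149] <- 2L
  lab1[10:59, 120:169] <- 3L
  lab2 <- matrix(0L, 200, 200)
  lab2[10:80, 10:80] <- 1L     # two merged into one larger
  lab2[100:149, 100:149] <- 2L
  ct <- cccp_table(lab1, lab2, pixel_size = 1)
  s <- ct$summary
  expect_lt(s$n[s$timepoint == 2], s$n[s$timepoint == 1])
  expect_gt(s$median_D[s$timepoint == 2], s$median_D[s$timepoint == 1])
})
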