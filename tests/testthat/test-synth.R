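test_that("generators are bit-reproducible under a fixed seed", {
  s <- scene_spec(n_colonies = 3, frames = 4, seed = 5)
  g1 <- gen_timelapse(s); g2 <- gen_timelapse(s)
  expect_identical(g1$frames, g2$frames)
  expect_identical(g1$truth, g2$truth)
  v1 <- gen_velocity_samples(100, seed = 9)
  v2 <- gen_velocity_samples(100, seed = 9)
  expect_identical(v1, v2)
  c1 <- gen_cell_field(30, seed = 2)$cells
  c2 <- gen_cell_field(30, seed = 2)$cells
  expect_identical(c1, c2)
  expect_false(identical(gen_velocity_samples(100, seed = 10), v1))
})

test_that("velocity samples match the measured moments after truncation", {
  v <- gen_velocity_samples(1e5, seed = 11)
  expect_true(all(v >= 0))
  expect_equal(mean(v), 0.031, tolerance = 0.001 / 0.031)
  expect_equal(sd(v), 0.021, tolerance = 0.002 / 0.021)
  expect_equal(gen_velocity_samples(5, sd = 0), rep(0.031, 5))
})

test_that("noiseless base-cell image at D = 50 renders the fitted count", {
  g <- gen_basecell_image(50, noise = "none", seed = 3, snr = 0)
  expect_equal(g$n_true, 41L)
  expect_equal(nrow(g$coordinates), 41)
  # spots are confined to the base circle of diameter 0.48 D
  c0 <- (dim(g$image) + 1) / 2
  r <- sqrt((g$coordinates$x_px - c0[1])^2 + (g$coordinates$y_px - c0[2])^2)
  expect_true(all(r <= 0.48 * 50 / 2 / 0.5 + 1e-9))
  # constant-density hypothesis with coefficient 0.05 at D = 10: 5 spots
  nA <- 0.05 / (pi * 0.24^2)
  gA <- gen_basecell_image(10, law = scaling_model("hypothesis_A", n = nA),
                           noise = "none", seed = 3, snr = 0)
  expect_equal(gA$n_true, 5L)
})

test_that("cell fields carry the requested orientation structure", {
  al <- gen_cell_field(40, model = "aligned", seed = 6)
  st <- orientation_stats(al$cells, search_radius = 15)
  expect_true(all(st$mean_rel_angle < 1e-12))
  rn <- gen_cell_field(400, model = "random", field = 120, seed = 8)
  st2 <- orientation_stats(rn$cells, search_radius = 15)
  # uniform relative acute angles average 45 degrees
  expect_equal(mean(st2$mean_rel_angle), 45, tolerance = 0.08)
  cl <- gen_cell_field(120, model = "clustered", seed = 9)
  st3 <- orientation_stats(cl$cells, search_radius = 10)
  expect_lt(mean(st3$mean_rel_angle), 30)
})

test_that("a static two-colony scene closes the loop with the tracker", {
  s <- scene_spec(n_colonies = 2, frames = 5, growth_rate = 0,
                  speed_anchor = 0, speed_sd = 0, snr = 0, seed = 12)
  g <- gen_timelapse(s)
  labels <- lapply(g$frames, segment_frame)
  recs <- dplyr::bind_rows(lapply(seq_along(labels), function(f)
    morphometrics(labels[[f]], s$pixel_size, roi_diameter = Inf, frame = f - 1L)))
  tr <- link_tracks(recs, labels, frame_interval = s$frame_interval)
  expect_equal(dplyr::n_distinct(tr$tracks$track_id), 2)
  expect_equal(nrow(tr$events), 0)
  v <- tr$tracks$velocity_um_s
  expect_true(all(v[!is.na(v)] < 1e-9))
})

test_that("a scripted merge closes the loop with the event log", {
  s <- scene_spec(n_colonies = 2, frames = 8, growth_rate = 0,
                  speed_anchor = 0, speed_sd = 0, snr = 0, seed = 23,
                  diameter_range = c(30, 40), img_size = 200,
                  merge_schedule = list(list(frame = 4, ids = c(1, 2))))
  g <- gen_timelapse(s)
  expect_equal(length(g$events), 1)
  labels <- lapply(g$frames, segment_frame)
  recs <- dplyr::bind_rows(lapply(seq_along(labels), function(f)
    morphometrics(labels[[f]], s$pixel_size, roi_diameter = Inf, frame = f - 1L)))
  tr <- link_tracks(recs, labels, frame_interval = s$frame_interval)
  expect_equal(nrow(tr$events), 1)
  expect_equal(tr$events$type, "merge")
  expect_equal(tr$events$frame, 4)
})

test_that("an impossible merge schedule is a spec error", {
  s <- scene_spec(n_colonies = 2, frames = 8, seed = 1, snr = 0,
                  merge_schedule = list(list(frame = 2, ids = c(1, 2)),
                                        list(frame = 4, ids = c(1, 2))))
  expect_error(gen_timelapse(s), "consumed")
})
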