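test_that("a blank frame yields an empty mask", {
  lab <- segment_frame(matrix(0.5, 64, 64))
  expect_true(all(lab == 0))
})

test_that("three separated dark disks are recovered with accurate areas", {
  fx <- three_disk_frame()
  lab <- segment_frame(fx$image)
  expect_equal(max(lab), 3)
  rec <- morphometrics(lab, pixel_size = 1, roi_diameter = Inf)
  expect_equal(nrow(rec), 3)
  truth_areas <- sort(vapply(fx$disks, function(d) sum(
    outer((seq_len(200) - d[1])^2, (seq_len(200) - d[2])^2, `+`) <= d[3]^2),
    numeric(1)))
  expect_equal(sort(rec$area_um2), truth_areas, tolerance = 0.05)
})

test_that("inverted contrast yields the same component count (dual mask)", {
  fx <- three_disk_frame()
  lab1 <- segment_frame(fx$image)
  lab2 <- segment_frame(1 - fx$image)
  expect_equal(max(lab1), max(lab2))
})

test_that("segmentation survives noise at the default synthetic SNR", {
  set.seed(9)
  fx <- three_disk_frame()
  noisy <- pmin(pmax(fx$image + matrix(rnorm(200 * 200, 0, 0.6 / 8), 200), 0), 1)
  lab <- segment_frame(noisy)
  rec <- morphometrics(lab, pixel_size = 1, roi_diameter = Inf)
  expect_equal(nrow(rec), 3)
})

test_that("labelling uses 8-connectivity", {
  m <- matrix(0, 8, 8)
  m[2, 2] <- 1; m[3, 3] <- 1    # touch only diagonally
  lab <- zorbkit:::label8(m > 0)
  expect_equal(max(lab), 1)
})

test_that("non-2D input is a format error", {
  expect_error(segment_frame(array(0.5, c(4, 4, 3))), "2D")
})

test_that("morphometric identities and filters hold", {
  # one small component: area pi -> D = 2, dropped by the 10 um filter
  m <- matrix(0L, 40, 40); m[20:21, 20:21] <- 1L
  rec <- morphometrics(m, pixel_size = 1, roi_diameter = Inf)
  expect_equal(nrow(rec), 0)
  # a large disk: check D and V identities on the records
  fx <- three_disk_frame()
  lab <- segment_frame(fx$image)
  rec <- morphometrics(lab, pixel_size = 1, roi_diameter = Inf)
  expect_equal(rec$diameter_um, 2 * sqrt(rec$area_um2 / pi), tolerance = 1e-9)
  expect_equal(rec$volume_um3, (4 / 3) * pi * (rec$diameter_um / 2)^3,
               tolerance = 1e-9)
  # closed-form volume check: area 625 pi -> D 50 -> V = (4/3) pi 25^3
  D <- 2 * sqrt(625 * pi / pi)
  expect_equal(D, 50)
  expect_equal((4 / 3) * pi * (D / 2)^3, 65449.8, tolerance = 1e-5)
})

test_that("records outside the circular ROI are excluded", {
  m <- matrix(0L, 100, 100)
  m[5:25, 5:25] <- 1L          # corner component
  m[45:65, 45:65] <- 2L        # central component
  rec_all <- morphometrics(m, pixel_size = 1, roi_diameter = Inf)
  expect_equal(nrow(rec_all), 2)
  rec_roi <- morphometrics(m, pixel_size = 1, roi_diameter = 50)
  expect_equal(nrow(rec_roi), 1)
})

test_that("missing pixel size is a configuration error", {
  expect_error(morphometrics(matrix(0L, 4, 4), pixel_size = NULL), "pixel_size")
})
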