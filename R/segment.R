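# Dual-mask microcolony segmentation and per-frame morphometrics.

as_img <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x)) rlang::abort("expected a single-channel 2D image")
  x
}

# rolling-ball style background estimate via grayscale morphology with a
# disc element: closing for dark objects on a light background, opening
# for bright objects on a dark background
background_subtract <- function(img, radius = 50, light_background = TRUE) {
  img <- as_img(img)
  k <- EBImage::makeBrush(2 * min(radius, floor((min(dim(img)) - 1) / 2)) + 1, "disc")
  if (light_background) {
    bg <- EBImage::imageData(EBImage::closing(EBImage::Image(img), k))
    out <- img - bg + mean(bg)
  } else {
    bg <- EBImage::imageData(EBImage::opening(EBImage::Image(img), k))
    out <- img - bg
  }
  pmin(pmax(out, 0), 1)
}

gaussian_mean_filter <- function(img, sigma = 2, mean_size = 3) {
  g <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma))
  EBImage::imageData(EBImage::filter2(
    EBImage::Image(g), matrix(1 / mean_size^2, mean_size, mean_size)))
}

# 8-connectivity labelling: EBImage::bwlabel plus a union-find pass that
# merges labels touching diagonally
label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  parent <- seq_len(nlab)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- findp(i); rj <- findp(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  nr <- nrow(lab); nc <- ncol(lab)
  for (sh in list(c(1, 1), c(1, -1))) {
    a <- lab[seq_len(nr - 1), , drop = FALSE]
    if (sh[2] == 1) {
      a <- lab[seq_len(nr - 1), seq_len(nc - 1), drop = FALSE]
      b <- lab[seq_len(nr - 1) + 1, seq_len(nc - 1) + 1, drop = FALSE]
    } else {
      a <- lab[seq_len(nr - 1), seq_len(nc - 1) + 1, drop = FALSE]
      b <- lab[seq_len(nr - 1) + 1, seq_len(nc - 1), drop = FALSE]
    }
    touch <- which(a > 0 & b > 0 & a != b)
    if (length(touch)) {
      pairs <- unique(cbind(a[touch], b[touch]))
      for (r in seq_len(nrow(pairs))) unite(pairs[r, 1], pairs[r, 2])
    }
  }
  roots <- vapply(seq_len(nlab), findp, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment one time-lapse frame into a microcolony label mask
#'
#' Combines two binarization paths with an OR so both contrast polarities
#' are caught: (A) gamma adjustment (0.7), inversion, background
#' subtraction, Gaussian-then-mean filtering and Otsu thresholding;
#' (B) background subtraction, inversion, the same filtering and
#' thresholding.  Connected components are labelled with 8-connectivity.
#'
#' @param image Numeric matrix in `[0, 1]` (grayscale frame).
#' @param gamma Gamma of path A (default 0.7).
#' @param sigma Gaussian sigma in pixels (default 2).
#' @param mean_size Mean-filter window (default 3).
#' @param bg_radius Background structuring-element radius in pixels
#'   (default 50).
#' @param threshold Optional fixed threshold overriding Otsu.
#' @param min_size Minimum component size in pixels (despeckle), default 9.
#' @return An integer label matrix (0 = background).
#' @export
segment_frame <- function(image, gamma = 0.7, sigma = 2, mean_size = 3,
                          bg_radius = 50, threshold = NULL, min_size = 9) {
  img <- as_img(image)
  rng <- range(img)
  if (diff(rng) < 1e-12) return(matrix(0L, nrow(img), ncol(img)))
  img <- (img - rng[1]) / diff(rng)
  # canonical polarity: colonies are the minority class and dark; a
  # bright-minority image is inverted before the two paths run
  m0 <- img > EBImage::otsu(EBImage::Image(img))
  if (mean(m0) < 0.5) img <- 1 - img
  th_of <- function(x) if (is.null(threshold)) EBImage::otsu(EBImage::Image(x)) else threshold
  # path A: dark colonies on light background
  a <- img^gamma
  a <- 1 - a
  a <- background_subtract(a, bg_radius, light_background = FALSE)
  a <- gaussian_mean_filter(a, sigma, mean_size)
  mask_a <- a > th_of(a)
  # path B: background first (light background), then inversion
  b <- background_subtract(img, bg_radius, light_background = TRUE)
  b <- 1 - b
  b <- gaussian_mean_filter(b, sigma, mean_size)
  mask_b <- b > th_of(b)
  lab <- label8(mask_a | mask_b)
  if (max(lab) > 0 && min_size > 1) {
    sizes <- tabulate(lab[lab > 0], max(lab))
    keep <- which(sizes >= min_size)
    lab[] <- match(lab, keep, nomatch = 0L)
  }
  lab
}

#' Morphometrics of a labelled mask
#'
#' Computes per-component centroid, area, equivalent diameter
#' `D = 2 sqrt(area / pi)` and spherical-equivalent volume
#' `V = (4/3) pi (D/2)^3`.  Components below the minimum diameter are
#' dropped (single cells average 6.7 um, so colonies below 10 um are
#' filtered), as are components whose centroid falls outside the circular
#' region of interest.
#'
#' @param labels Integer label matrix from [segment_frame()].
#' @param pixel_size Pixel size (um/px); required.
#' @param min_diameter Minimum equivalent diameter (um), default 10.
#' @param roi_diameter Region-of-interest diameter (um), default 1840
#'   (the inner region of a 2 mm drop); `Inf` disables the ROI filter.
#' @param roi_center ROI centre in um (default the image centre).
#' @param frame Frame index stored in the output (0-based).
#' @return A tibble with columns `frame, label, x_um, y_um, area_um2,
#'   diameter_um, volume_um3, inside_roi`.
#' @export
morphometrics <- function(labels, pixel_size, min_diameter = 10,
                          roi_diameter = 1840, roi_center = NULL, frame = 0L) {
  if (missing(pixel_size) || is.null(pixel_size)) {
    rlang::abort("`pixel_size` (um/px) is required")
  }
  nlab <- max(labels)
  if (nlab == 0) {
    return(tibble::tibble(frame = integer(), label = integer(), x_um = numeric(),
                          y_um = numeric(), area_um2 = numeric(),
                          diameter_um = numeric(), volume_um3 = numeric(),
                          inside_roi = logical()))
  }
  idx <- which(labels > 0, arr.ind = TRUE)
  lv <- labels[labels > 0]
  area_px <- tabulate(lv, nlab)
  cx <- vapply(split(idx[, 1], lv), mean, numeric(1))
  cy <- vapply(split(idx[, 2], lv), mean, numeric(1))
  # pixel centres, origin at the top-left pixel centre
  x_um <- (cx - 1) * pixel_size
  y_um <- (cy - 1) * pixel_size
  area_um2 <- area_px * pixel_size^2
  D <- 2 * sqrt(area_um2 / pi)
  V <- (4 / 3) * pi * (D / 2)^3
  if (is.null(roi_center)) {
    roi_center <- (dim(labels) - 1) / 2 * pixel_size
  }
  inside <- sqrt((x_um - roi_center[1])^2 + (y_um - roi_center[2])^2) <=
    roi_diameter / 2
  out <- tibble::tibble(frame = as.integer(frame), label = seq_len(nlab),
                        x_um = x_um, y_um = y_um, area_um2 = area_um2,
                        diameter_um = D, volume_um3 = V, inside_roi = inside)
  out[out$diameter_um >= min_diameter & out$inside_roi, ]
}
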