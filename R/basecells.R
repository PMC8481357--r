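# Base-cell counting (bright substrate-proximal poles under a microcolony)
# and the N(D) power-law fit.

# percentile contrast stretch: the low and high quantiles bracketing the
# saturated fraction map to 0 and 1.  The high end is not clipped - on
# sparse images clipping would fuse neighbouring peaks into one plateau
# and destroy the maxima structure the prominence test needs.
enhance_contrast <- function(img, saturated = 0.03) {
  q <- stats::quantile(img, c(saturated / 2, 1 - saturated / 2), names = FALSE)
  if (diff(q) < 1e-12) return(img * 0)
  out <- pmax((img - q[1]) / (q[2] - q[1]), 0)
  out / max(out)
}

# grayscale reconstruction by iterative geodesic dilation (marker under mask)
gray_reconstruct <- function(marker, mask, max_iter = 500) {
  k <- EBImage::makeBrush(3, "box")
  rec <- pmin(marker, mask)
  for (it in seq_len(max_iter)) {
    nxt <- pmin(EBImage::imageData(EBImage::dilate(EBImage::Image(rec), k)), mask)
    if (max(abs(nxt - rec)) < 1e-9) return(nxt)
    rec <- nxt
  }
  rec
}

#' Count base cells in a colony-base image
#'
#' Pipeline: rolling-ball style background subtraction, percentile contrast
#' enhancement saturating 3 % of pixels, then local-maxima picking with a
#' prominence threshold (h-maxima transform: a maximum counts only if it
#' stands at least `prominence` above the ridge connecting it to any higher
#' region; two peaks closer than their connecting ridge allows collapse to
#' one, mirroring interactive maxima picking).  Detection is restricted to
#' the base region of the colony, the inner circle of diameter
#' `d = d_over_D * D`.
#'
#' @param image Numeric matrix in `[0, 1]`; bright dots are base cells.
#' @param prominence Required prominence (in enhanced-intensity units);
#'   there is no default because the appropriate value depends on the
#'   image contrast.
#' @param D Colony diameter (um); with `pixel_size` defines the base ROI.
#'   Omit (with `roi = FALSE`) to search the whole image.
#' @param pixel_size Pixel size (um/px), default 1.
#' @param d_over_D Base-to-colony diameter ratio (default 0.48).
#' @param bg_radius Rolling-ball radius in px (default 50).
#' @param saturated Saturated pixel fraction of the contrast step
#'   (default 0.03).
#' @param light_background Set `TRUE` for bright-field images where the
#'   dots sit on a light background (default `FALSE`: bright dots on dark).
#' @param roi Restrict to the base circle (default `TRUE` when `D` given).
#' @return A list: `n` (count) and `coordinates` tibble (`x_px`, `y_px`,
#'   pixel indices of each accepted maximum).
#' @export
count_base_cells <- function(image, prominence, D = NULL, pixel_size = 1,
                             d_over_D = 0.48, bg_radius = 50,
                             saturated = 0.03, light_background = FALSE,
                             roi = !is.null(D)) {
  if (missing(prominence) || is.null(prominence)) {
    rlang::abort("`prominence` must be supplied (it is image-dependent)")
  }
  img <- as_img(image)
  if (max(img) - min(img) < 1e-12) {
    return(list(n = 0L, coordinates = tibble::tibble(x_px = integer(),
                                                     y_px = integer())))
  }
  if (light_background) img <- max(img) - img
  img0 <- background_subtract(img, bg_radius, light_background = FALSE)
  img <- enhance_contrast(img0, saturated)
  # h-maxima: maxima of the reconstruction of (img - h) under img
  rec <- gray_reconstruct(img - prominence, img)
  k <- EBImage::makeBrush(3, "box")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(rec), k))
  # a peak lower than the prominence itself cannot stand out by it
  regmax <- rec >= dil - 1e-12 & img >= prominence
  # one detection per connected plateau, located at the brightest pixel
  lab <- label8(regmax)
  nlab <- max(lab)
  if (nlab == 0) {
    return(list(n = 0L, coordinates = tibble::tibble(x_px = integer(),
                                                     y_px = integer())))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  # localize on the un-stretched image (contrast clipping flattens peak tops)
  vals <- img0[lab > 0]
  best <- vapply(split(seq_along(lv), lv), function(s) s[which.max(vals[s])],
                 integer(1))
  coords <- tibble::tibble(x_px = as.integer(idx[best, 1]),
                           y_px = as.integer(idx[best, 2]))
  if (roi && !is.null(D)) {
    c0 <- (dim(img) + 1) / 2
    r_px <- d_over_D * D / 2 / pixel_size
    keep <- sqrt((coords$x_px - c0[1])^2 + (coords$y_px - c0[2])^2) <= r_px
    coords <- coords[keep, ]
  }
  list(n = nrow(coords), coordinates = coords)
}

#' Fit the base-cell power law N = a D^b
#'
#' Ordinary least squares on the log-transformed data (the conventional
#' spreadsheet "power fit"); `a = exp(intercept)`, `b = slope`.  A
#' nonlinear least-squares variant on the original scale is available for
#' comparison.
#'
#' @param D,N Positive diameters and counts (>= 3 points).
#' @param method `"loglog"` (default) or `"nls"`.
#' @return An object of class `power_law_fit` with coefficients `a`, `b`
#'   and their standard errors; supports [tidy()] and [glance()].
#' @export
fit_power_law <- function(D, N, method = c("loglog", "nls")) {
  method <- match.arg(method)
  if (length(D) < 3) rlang::abort("need at least 3 points")
  if (any(D <= 0) || any(N <= 0)) rlang::abort("D and N must be > 0")
  if (method == "loglog") {
    fit <- stats::lm(log(N) ~ log(D))
    sm <- summary(fit)$coefficients
    a <- exp(sm[1, 1]); b <- sm[2, 1]
    se_a <- a * sm[1, 2]; se_b <- sm[2, 2]
    r2 <- summary(fit)$r.squared
  } else {
    start <- fit_power_law(D, N, "loglog")
    fit <- stats::nls(N ~ a * D^b, start = list(a = start$a, b = start$b))
    sm <- summary(fit)$coefficients
    a <- sm[1, 1]; b <- sm[2, 1]; se_a <- sm[1, 2]; se_b <- sm[2, 2]
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((N - mean(N))^2)
  }
  structure(list(a = a, b = b, se_a = se_a, se_b = se_b, r_squared = r2,
                 n = length(D), method = method, fit = fit,
                 data = tibble::tibble(D = D, N = N)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> N = %.4g * D^%.4g  (se_b %.3g, n = %d, %s)\n",
              x$a, x$b, x$se_b, x$n, x$method))
  invisible(x)
}

#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"),
                 estimate = c(x$a, x$b),
                 std.error = c(x$se_a, x$se_b))
}

#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n, method = x$method)
}
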