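# Neighbour-weighted relative orientation of rod-shaped cells.

#' Distance-weighted mean relative orientation per cell
#'
#' For every cell, neighbours within the search radius contribute the acute
#' angle between the two orientations (in degrees, 0-90), weighted by
#' `1 - distance / search_radius`.  Cells without neighbours are omitted
#' from the result.
#'
#' @param cells Tibble with columns `x`, `y` (um) and `angle` (degrees in
#'   `[0, 180)`).
#' @param search_radius Neighbourhood radius (um), default 9.8.
#' @return A tibble with `cell` (row index), `mean_rel_angle` (degrees),
#'   `n_neighbors`, `weight_sum`.
#' @export
orientation_stats <- function(cells, search_radius = 9.8) {
  stopifnot(all(c("x", "y", "angle") %in% names(cells)))
  if (any(cells$angle < 0 | cells$angle >= 180)) {
    rlang::abort("angles must be in [0, 180) degrees")
  }
  n <- nrow(cells)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    d <- sqrt((cells$x - cells$x[i])^2 + (cells$y - cells$y[i])^2)
    nb <- which(d <= search_radius & seq_len(n) != i)
    if (!length(nb)) next
    rel <- abs(cells$angle[nb] - cells$angle[i]) %% 180
    rel <- ifelse(rel > 90, 180 - rel, rel)
    w <- 1 - d[nb] / search_radius
    out[[i]] <- tibble::tibble(cell = i,
                               mean_rel_angle = sum(rel * w) / sum(w),
                               n_neighbors = length(nb),
                               weight_sum = sum(w))
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(cell = integer(), mean_rel_angle = numeric(),
                          n_neighbors = integer(), weight_sum = numeric())
  }
  res
}
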