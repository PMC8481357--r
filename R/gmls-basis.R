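#' Monomial exponents of the 2D polynomial space of a given total order
#'
#' @param order Total polynomial order (non-negative integer).
#' @return A tibble with integer columns `i`, `j`, one row per monomial
#'   `x^i * y^j` with `i + j <= order`, ordered by total degree.
#' @keywords internal
monomial_exponents <- function(order) {
  stopifnot(is.numeric(order), length(order) == 1, order >= 0)
  ex <- expand.grid(i = 0:order, j = 0:order)
  ex <- ex[ex$i + ex$j <= order, , drop = FALSE]
  ex <- ex[order(ex$i + ex$j, ex$i), , drop = FALSE]
  tibble::tibble(i = as.integer(ex$i), j = as.integer(ex$j))
}

#' Polynomial basis for GMLS reconstruction
#'
#' Builds either the scalar monomial basis of a given total order, or a
#' spanning set of 2D vector polynomials whose divergence is identically
#' zero.  The divergence-free basis is constructed by assembling the exact
#' divergence operator on the full vector-monomial basis (coefficient
#' arithmetic, no numerical differentiation) and extracting a null-space
#' basis, so it is order-generic and its elements can be checked
#' symbolically.
#'
#' @param order Total polynomial order, `>= 0`.
#' @param kind `"scalar"` or `"divergence_free_vector"`.
#' @return For `"scalar"`, an object of class `gmls_basis` holding the
#'   monomial exponent table.  For `"divergence_free_vector"`, a
#'   `gmls_basis` whose `elements` is a list of coefficient matrices, one
#'   per basis element; each matrix has one row per monomial (matching
#'   `exponents`) and two columns (the u- and v-components).
#' @examples
#' polynomial_basis(2, "scalar")            # 6 monomials
#' b <- polynomial_basis(2, "divergence_free_vector")
#' length(b$elements)                        # 9
#' @export
polynomial_basis <- function(order, kind = c("scalar", "divergence_free_vector")) {
  if (!is.numeric(order) || length(order) != 1 || order < 0 || order != round(order)) {
    rlang::abort("`order` must be a single non-negative integer.")
  }
  kind <- match.arg(kind)
  ex <- monomial_exponents(order)
  if (kind == "scalar") {
    out <- list(kind = kind, order = order, exponents = ex, dim = nrow(ex))
    class(out) <- "gmls_basis"
    return(out)
  }
  # vector monomials: (m, 0) and (0, m) for each scalar monomial m
  nm <- nrow(ex)
  # divergence of x^i y^j e_x is i x^(i-1) y^j; of e_y analogous.
  # target space: polynomials of order-1 (or empty when order = 0)
  exd <- monomial_exponents(max(order - 1, 0))
  ndiv <- if (order == 0) 0L else nrow(exd)
  D <- matrix(0, nrow = max(ndiv, 1), ncol = 2 * nm)
  if (order > 0) {
    row_of <- function(i, j) which(exd$i == i & exd$j == j)
    for (k in seq_len(nm)) {
      i <- ex$i[k]; j <- ex$j[k]
      if (i >= 1) D[row_of(i - 1L, j), k] <- i
      if (j >= 1) D[row_of(i, j - 1L), nm + k] <- j
    }
  }
  ns <- if (order == 0) diag(2 * nm) else {
    qrD <- qr(t(D))
    rank <- qrD$rank
    qr.Q(qrD, complete = TRUE)[, seq(rank + 1, 2 * nm), drop = FALSE]
  }
  elements <- lapply(seq_len(ncol(ns)), function(k) {
    m <- cbind(u = ns[seq_len(nm), k], v = ns[nm + seq_len(nm), k])
    m[abs(m) < 1e-14] <- 0
    m
  })
  out <- list(kind = kind, order = order, exponents = ex,
              dim = length(elements), elements = elements)
  class(out) <- "gmls_basis"
  out
}

#' Divergence of a vector polynomial, by coefficient arithmetic
#'
#' @param element A coefficient matrix as stored in the `elements` field of a
#'   divergence-free `gmls_basis`: one row per monomial, columns `u`, `v`.
#' @param exponents Monomial exponent table matching the rows of `element`.
#' @return A tibble with the monomial exponents and coefficient of the
#'   divergence polynomial; all coefficients are 0 for a divergence-free
#'   element.
#' @keywords internal
poly_divergence <- function(element, exponents) {
  terms <- list()
  for (k in seq_len(nrow(exponents))) {
    i <- exponents$i[k]; j <- exponents$j[k]
    if (i >= 1 && element[k, 1] != 0) {
      terms[[length(terms) + 1]] <- c(i - 1L, j, i * element[k, 1])
    }
    if (j >= 1 && element[k, 2] != 0) {
      terms[[length(terms) + 1]] <- c(i, j - 1L, j * element[k, 2])
    }
  }
  if (!length(terms)) {
    return(tibble::tibble(i = integer(), j = integer(), coef = numeric()))
  }
  tb <- do.call(rbind, terms)
  out <- stats::aggregate(tb[, 3], by = list(i = tb[, 1], j = tb[, 2]), FUN = sum)
  tibble::tibble(i = as.integer(out$i), j = as.integer(out$j), coef = out$x)
}

#' @export
print.gmls_basis <- function(x, ...) {
  cat(sprintf("<gmls_basis> kind=%s order=%d dim=%d\n", x$kind, x$order, x$dim))
  invisible(x)
}
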