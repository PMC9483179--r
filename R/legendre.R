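#' Legendre polynomial basis for lactation-curve regressions
#'
#' Test-day models regress trait trajectories on Legendre polynomials of
#' standardized days in milk (DIM). A basis of `order` m has `order + 1`
#' functions; the normalized form scales the m-th polynomial by
#' sqrt((2m + 1) / 2) so the basis is orthonormal on \[-1, 1\].
#'
#' @param order Highest polynomial degree (non-negative integer). The usual
#'   choice for full-lactation models is 5.
#' @param dim_min,dim_max DIM range covered by the basis (defaults 5 and 305).
#' @param normalized Scale polynomials to be orthonormal on \[-1, 1\]?
#' @return An object of class `legendre_basis`.
#' @export
legendre_basis <- function(order = 5L, dim_min = 5L, dim_max = 305L,
                           normalized = TRUE) {
  order <- as.integer(order)
  if (is.na(order) || order < 0L) stop("'order' must be a non-negative integer")
  if (dim_max <= dim_min) stop("'dim_max' must exceed 'dim_min'")
  structure(
    list(order = order, dim_min = dim_min, dim_max = dim_max,
         normalized = isTRUE(normalized)),
    class = "legendre_basis")
}

#' @export
print.legendre_basis <- function(x, ...) {
  cat(sprintf("Legendre basis: order %d (%s), DIM %d-%d\n", x$order,
              if (x$normalized) "normalized" else "raw", x$dim_min, x$dim_max))
  invisible(x)
}

#' Map days in milk onto the standardized interval \[-1, 1\]
#'
#' @param dim Integer vector of days in milk.
#' @param basis A [legendre_basis()].
#' @return Numeric vector of standardized values.
#' @export
standardize_dim <- function(dim, basis) {
  if (any(dim < basis$dim_min | dim > basis$dim_max)) {
    stop(sprintf("dim outside basis range [%d, %d]", basis$dim_min, basis$dim_max))
  }
  2 * (dim - basis$dim_min) / (basis$dim_max - basis$dim_min) - 1
}

#' Evaluate the basis at given days in milk
#'
#' Uses the three-term recurrence
#' (m + 1) P_{m+1}(x) = (2m + 1) x P_m(x) - m P_{m-1}(x).
#'
#' @param dim Integer vector of days in milk.
#' @param basis A [legendre_basis()].
#' @return Matrix with one row per element of `dim` and `order + 1` columns.
#' @export
legendre_matrix <- function(dim, basis) {
  x <- standardize_dim(dim, basis)
  k <- basis$order + 1L
  phi <- matrix(0, length(x), k)
  phi[, 1] <- 1
  if (k >= 2L) phi[, 2] <- x
  if (k >= 3L) {
    for (m in 1L:(k - 2L)) {
      phi[, m + 2L] <- ((2 * m + 1) * x * phi[, m + 1L] - m * phi[, m]) / (m + 1)
    }
  }
  if (basis$normalized) {
    phi <- sweep(phi, 2L, sqrt((2 * seq_len(k) - 1) / 2), `*`)
  }
  colnames(phi) <- paste0("leg", seq_len(k) - 1L)
  phi
}

#' Evaluate the basis at a single day in milk
#'
#' @inheritParams legendre_matrix
#' @return Numeric vector of length `order + 1`.
#' @export
legendre_row <- function(dim, basis) {
  stopifnot(length(dim) == 1L)
  drop(legendre_matrix(dim, basis))
}
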