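#' Restricted cubic spline basis
#'
#' Natural (restricted) cubic spline basis in Harrell's parameterization:
#' \code{k} knots yield \code{k - 1} columns, the first being the untransformed
#' (linear) term and the remaining \code{k - 2} the nonlinear terms, each
#' normalized by the squared knot range so coefficients are on comparable
#' scales.  The resulting spline is linear beyond the boundary knots and the
#' nonlinear columns vanish for \code{x} at or below the first knot.
#'
#' @param x numeric vector of evaluation points.
#' @param knots strictly increasing numeric vector of at least 3 knots.
#' @return numeric matrix with \code{length(x)} rows and
#'   \code{length(knots) - 1} columns, named \code{"lin"},
#'   \code{"nl1"}, \code{"nl2"}, ...
#' @examples
#' B <- rcs_basis(30:84, c(32, 40, 55, 70, 77, 82))
#' ncol(B)  # 5
#' @export
rcs_basis <- function(x, knots) {
  if (!is.numeric(knots) || length(knots) < 3L)
    stop("need at least 3 knots")
  if (any(diff(knots) <= 0))
    stop("knots must be strictly increasing")
  k <- length(knots)
  tk <- knots[k]
  tk1 <- knots[k - 1L]
  norm <- (knots[k] - knots[1L])^2
  cube <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), k - 1L)
  B[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    B[, j + 1L] <- (cube(x - knots[j]) -
                      cube(x - tk1) * (tk - knots[j]) / (tk - tk1) +
                      cube(x - tk) * (tk1 - knots[j]) / (tk - tk1)) / norm
  }
  colnames(B) <- c("lin", if (k > 2L) paste0("nl", seq_len(k - 2L)))
  B
}
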