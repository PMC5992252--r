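#' Equally spaced B-spline basis over an age grid
#'
#' Builds the design matrix used by every smooth component in the package:
#' B-splines of a given degree on equally spaced knots covering the age grid.
#' Rows sum to one (partition of unity), so a constant log-rate is always in
#' the span regardless of the smoothing weight.
#'
#' @param ages Numeric vector, the evaluation grid (typically integer single
#'   ages such as `10:90`).
#' @param knot_spacing Distance in years between adjacent knots. Default 2.
#' @param degree Spline degree; `3` (cubic) by default, `0` gives piecewise
#'   constant indicator columns.
#'
#' @return An object of class `spline_basis`: a list with elements `ages`,
#'   `degree`, `knots` (full knot sequence) and `B`, the
#'   `length(ages) x n_coef` design matrix.
#' @examples
#' bas <- bspline_basis(10:90, knot_spacing = 2)
#' ncol(bas$B)           # 43 columns for 40 interior intervals, cubic
#' range(rowSums(bas$B)) # partition of unity
#' @export
bspline_basis <- function(ages, knot_spacing = 2, degree = 3) {
  stopifnot(is.numeric(ages), length(ages) >= degree + 2)
  if (knot_spacing <= 0) abort("`knot_spacing` must be positive.")
  span <- max(ages) - min(ages)
  if (knot_spacing > span) {
    abort("`knot_spacing` exceeds the span of the age grid.")
  }
  h <- knot_spacing
  # breakpoints tile [min, max]; extend the top if the span is not a multiple
  n_int <- ceiling(span / h - 1e-9)
  breaks <- min(ages) + h * (0:n_int)
  knots <- if (degree > 0) {
    c(min(ages) - h * seq_len(degree), breaks,
      max(breaks) + h * seq_len(degree))
  } else {
    c(breaks, max(breaks) + h) # right-open top interval for indicators
  }
  knots <- sort(knots)
  B <- splines::splineDesign(knots, x = ages, ord = degree + 1,
                             outer.ok = FALSE)
  structure(
    list(ages = ages, degree = degree, knot_spacing = h,
         knots = knots, B = B),
    class = "spline_basis"
  )
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf(
    "<spline_basis> degree %d, %d columns on %d ages [%s, %s], knot spacing %g\n",
    x$degree, ncol(x$B), length(x$ages), min(x$ages), max(x$ages),
    x$knot_spacing))
  invisible(x)
}

# order-d difference matrix on n coefficients
difference_matrix <- function(n, order = 2) {
  if (order < 1 || order > 3) abort("difference `order` must be 1, 2 or 3.")
  diff(diag(n), differences = order)
}

#' Smoothness and shape penalty specification
#'
#' Bundles the quadratic roughness penalty and the optional shape constraint
#' applied to one smooth exponential component. Shape constraints are imposed
#' as iteratively reweighted asymmetric penalties on coefficient differences:
#' nonnegative first differences force a nondecreasing curve (senescence),
#' nonpositive second differences force log-concavity (hump).
#'
#' @param lambda Positive smoothing weight for the difference penalty.
#' @param order Difference order of the roughness penalty (1, 2 or 3).
#' @param shape One of `"none"`, `"monotone_increasing"`, `"log_concave"`.
#' @param shape_weight Weight of the asymmetric shape penalty; violations
#'   shrink as the weight grows. Default `1e6`.
#' @return An object of class `penalty_bundle`.
#' @examples
#' penalty_bundle(lambda = 100, shape = "monotone_increasing")
#' @export
penalty_bundle <- function(lambda = 100, order = 2, shape = c(
                             "none", "monotone_increasing", "log_concave"),
                           shape_weight = 1e6) {
  shape <- match.arg(shape)
  if (!is.numeric(lambda) || lambda <= 0) abort("`lambda` must be positive.")
  if (shape_weight <= 0) abort("`shape_weight` must be positive.")
  if (!order %in% 1:3) abort("`order` must be 1, 2 or 3.")
  structure(list(lambda = lambda, order = order, shape = shape,
                 shape_weight = shape_weight),
            class = "penalty_bundle")
}

#' @export
print.penalty_bundle <- function(x, ...) {
  cat(sprintf("<penalty_bundle> lambda %g, difference order %d, shape %s\n",
              x$lambda, x$order, x$shape))
  invisible(x)
}

#' Active-set shape penalty matrix for the current coefficients
#'
#' Returns the quadratic penalty that pushes the currently violated
#' coefficient differences back towards the feasible cone. For a monotone
#' increasing constraint the penalty is `weight * t(D1) V D1` where `V`
#' flags negative first differences of `beta`; for log-concavity it is
#' `weight * t(D2) V D2` with `V` flagging positive second differences.
#' When no difference violates the constraint the zero matrix is returned
#' and the constraint is inactive.
#'
#' @param beta Current coefficient vector.
#' @param shape `"none"`, `"monotone_increasing"` or `"log_concave"`.
#' @param weight Penalty weight (default `1e6`).
#' @return A symmetric positive semidefinite `length(beta)` square matrix,
#'   with attribute `"n_active"` giving the number of flagged differences.
#' @examples
#' shape_violation_penalty(c(0, -1, 0), "monotone_increasing")
#' @export
shape_violation_penalty <- function(beta, shape, weight = 1e6) {
  n <- length(beta)
  known <- c("none", "monotone_increasing", "log_concave")
  if (!is.character(shape) || length(shape) != 1 || !shape %in% known) {
    abort(sprintf("unknown shape tag %s", paste(deparse(shape), collapse = "")))
  }
  zero <- matrix(0, n, n)
  if (shape == "none") {
    attr(zero, "n_active") <- 0L
    return(zero)
  }
  if (shape == "monotone_increasing") {
    D <- difference_matrix(n, 1)
    v <- as.numeric(drop(D %*% beta) < 0)
  } else {
    D <- difference_matrix(n, 2)
    v <- as.numeric(drop(D %*% beta) > 0)
  }
  P <- weight * crossprod(D * sqrt(v))
  attr(P, "n_active") <- sum(v)
  P
}

# asymmetric penalty value 0.5 * w * sum(violating differences^2)
shape_penalty_value <- function(beta, shape, weight) {
  if (shape == "none") return(0)
  if (shape == "monotone_increasing") {
    d <- drop(difference_matrix(length(beta), 1) %*% beta)
    0.5 * weight * sum(pmin(d, 0)^2)
  } else {
    d <- drop(difference_matrix(length(beta), 2) %*% beta)
    0.5 * weight * sum(pmax(d, 0)^2)
  }
}

# largest residual violation of the shape constraint on a coefficient vector
shape_violation_size <- function(beta, shape) {
  if (shape == "none") return(0)
  if (shape == "monotone_increasing") {
    max(c(0, -drop(difference_matrix(length(beta), 1) %*% beta)))
  } else {
    max(c(0, drop(difference_matrix(length(beta), 2) %*% beta)))
  }
}
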