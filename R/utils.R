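# small numerical helpers shared across modules

#' Error function and its inverse
#'
#' `erf(x) = 2*pnorm(x*sqrt(2)) - 1`; `erfinv` is its exact inverse via
#' `qnorm`.  Exposed because the erf CV map is one of the package's
#' benchmark coordinate transformations.
#'
#' @param x numeric vector.
#' @return numeric vector.
#' @export
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' @rdname erf
#' @export
erfinv <- function(x) stats::qnorm((x + 1) / 2) / sqrt(2)

# coerce a point (vector) or set of points to an n x d matrix
as_points <- function(x, dim) {
  if (is.null(dim(x))) {
    if (length(x) %% dim != 0L)
      stop("point length ", length(x), " is not a multiple of dimension ", dim)
    x <- matrix(x, ncol = dim, byrow = TRUE)
  }
  if (ncol(x) != dim)
    stop("points have ", ncol(x), " columns, expected ", dim)
  if (!all(is.finite(x))) stop("non-finite coordinates in input points")
  x
}

# central-difference jacobian of f: R^din -> R^dout at a single point
num_jacobian <- function(f, x, step = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    e <- numeric(length(x)); e[j] <- step
    J[, j] <- (f(x + e) - f(x - e)) / (2 * step)
  }
  J
}

# trapezoid cumulative integral of y over uniform or non-uniform x
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# condition constructors: all package errors carry class "riemcv_error"
riemcv_error <- function(msg, class, ...) {
  structure(
    class = c(class, "riemcv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
}

stop_domain <- function(msg, ...) stop(riemcv_error(msg, "riemcv_domain_error", ...))
stop_degenerate <- function(msg, ...) stop(riemcv_error(msg, "riemcv_degenerate_metric", ...))

#' Format a numeric vector for reproducible text output
#'
#' Fixed `%.15g` formatting so that identical numbers always serialize to
#' identical bytes in CSV outputs.
#' @param x numeric vector.
#' @return character vector.
#' @keywords internal
fmt_num <- function(x) sprintf("%.15g", x)
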