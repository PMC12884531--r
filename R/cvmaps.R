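#' Collective-variable maps with Jacobians
#'
#' A `cv_map` is a differentiable map from configuration space to CV
#' space together with its Jacobian, an optional inverse, and optional
#' per-output periodicity.  `forward` is vectorized over rows of a point
#' matrix; `jacobian` takes a single point (numeric vector) and returns
#' the `dim_out x dim_in` matrix of partial derivatives.
#'
#' @param dim_in,dim_out input/output dimensions.
#' @param forward function, `n x dim_in` matrix -> `n x dim_out` matrix.
#' @param jacobian function, length-`dim_in` vector -> `dim_out x dim_in`
#'   matrix.
#' @param inverse optional function, `n x dim_out` -> `n x dim_in`.
#' @param periodicity optional numeric vector of output periods.
#' @param name identifier.
#' @return an object of class `cv_map`.
#' @export
cv_map <- function(dim_in, dim_out, forward, jacobian, inverse = NULL,
                   periodicity = NULL, name = "custom") {
  structure(list(dim_in = as.integer(dim_in), dim_out = as.integer(dim_out),
                 forward = forward, jacobian = jacobian, inverse = inverse,
                 periodicity = periodicity, name = name),
            class = "cv_map")
}

#' @export
print.cv_map <- function(x, ...) {
  cat("<cv_map>", x$name, " R^", x$dim_in, " -> R^", x$dim_out,
      if (!is.null(x$inverse)) " (invertible)", "\n", sep = "")
  invisible(x)
}

#' Evaluate a CV map and its Jacobian at a point
#'
#' @param map a [cv_map()].
#' @param point numeric vector in the map's domain.
#' @return list with `values` (length `dim_out`) and `jacobian`
#'   (`dim_out x dim_in` matrix).
#' @export
eval_cv <- function(map, point) {
  if (!all(is.finite(point))) stop_domain("non-finite input point")
  p <- as_points(point, map$dim_in)
  list(values = as.numeric(map$forward(p)), jacobian = map$jacobian(point))
}

#' Built-in CV maps
#'
#' * `cv_identity(dim)`: the identity map.
#' * `cv_scale(c)`: 1D linear stretching `xi = c*x`.
#' * `cv_erf1d()`: `xi = erf(x)`, the map that flattens the conventional
#'   PMF of V = x^2 at beta = 1.
#' * `cv_logpolar()`: `X = log(sqrt(x^2+y^2))`, `Y = atan2(y, x)` with
#'   `Y` in `(-pi, pi]` (period `2*pi`); a deliberately curved CV space
#'   whose induced metric is `exp(2X) * I`.  The origin is a singular
#'   point: points with radius below `1e-12` raise a domain error.
#'
#' @param dim dimension of the identity map.
#' @param factor scale factor of the linear map.
#' @return a [cv_map()].
#' @export
cv_identity <- function(dim = 1L) {
  cv_map(dim, dim,
         forward = function(p) p,
         jacobian = function(x) diag(nrow = dim),
         inverse = function(z) z,
         name = "identity")
}

#' @rdname cv_identity
#' @export
cv_scale <- function(factor) {
  stopifnot(is.finite(factor), factor != 0)
  cv_map(1L, 1L,
         forward = function(p) p * factor,
         jacobian = function(x) matrix(factor),
         inverse = function(z) z / factor,
         name = paste0("scale:", factor))
}

#' @rdname cv_identity
#' @export
cv_erf1d <- function() {
  cv_map(1L, 1L,
         forward = function(p) matrix(erf(p[, 1]), ncol = 1),
         jacobian = function(x) matrix(2 / sqrt(pi) * exp(-x^2)),
         inverse = function(z) matrix(erfinv(z[, 1]), ncol = 1),
         name = "erf1d")
}

#' @rdname cv_identity
#' @export
cv_logpolar <- function() {
  guard <- 1e-12
  forward <- function(p) {
    r2 <- p[, 1]^2 + p[, 2]^2
    if (any(r2 < guard^2))
      stop_domain("log-polar map is singular at the origin")
    cbind(log(sqrt(r2)), atan2(p[, 2], p[, 1]), deparse.level = 0)
  }
  jacobian <- function(x) {
    r2 <- x[1]^2 + x[2]^2
    if (r2 < guard^2)
      stop_domain("log-polar map is singular at the origin")
    rbind(c(x[1], x[2]), c(-x[2], x[1])) / r2
  }
  inverse <- function(z) {
    cbind(exp(z[, 1]) * cos(z[, 2]), exp(z[, 1]) * sin(z[, 2]),
          deparse.level = 0)
  }
  cv_map(2L, 2L, forward, jacobian, inverse,
         periodicity = c(NA_real_, 2 * pi), name = "logpolar")
}

#' Look up a built-in CV map by name
#'
#' Recognized ids: `"identity"`, `"erf1d"`, `"logpolar"`, and
#' `"scale:<c>"` with a numeric factor.
#'
#' @param id character id.
#' @param dim dimension for the identity map.
#' @return a [cv_map()].
#' @export
cv_map_by_name <- function(id, dim = 1L) {
  if (startsWith(id, "scale:")) {
    f <- suppressWarnings(as.numeric(sub("^scale:", "", id)))
    if (!is.finite(f)) stop_domain(paste0("bad scale factor in '", id, "'"))
    return(cv_scale(f))
  }
  switch(id,
         identity = cv_identity(dim),
         erf1d = cv_erf1d(),
         logpolar = cv_logpolar(),
         stop_domain(paste0("unknown CV map id: '", id, "'")))
}

#' Tabulated monotone 1D CV map
#'
#' Builds an invertible 1D map from a monotone table of `(x, zeta)`
#' pairs, interpolated by a monotonicity-preserving (Hyman-filtered)
#' cubic spline in both directions.  The Jacobian is the spline
#' derivative, so round-trip checks through the PMF relations exercise
#' genuine interpolation error rather than an algebraic identity.
#'
#' @param x strictly increasing configuration values.
#' @param zeta strictly increasing CV values, same length as `x`.
#' @param name identifier.
#' @return a [cv_map()] with a `domain` attribute (range of `x`).
#' @export
cv_tabulated <- function(x, zeta, name = "tabulated") {
  stopifnot(length(x) == length(zeta), length(x) >= 4)
  if (any(diff(x) <= 0) || any(diff(zeta) <= 0))
    stop_domain("tabulated map must be strictly increasing")
  fwd <- stats::splinefun(x, zeta, method = "hyman")
  inv <- stats::splinefun(zeta, x, method = "hyman")
  m <- cv_map(1L, 1L,
              forward = function(p) matrix(fwd(p[, 1]), ncol = 1),
              jacobian = function(xx) matrix(fwd(xx, deriv = 1)),
              inverse = function(z) matrix(inv(z[, 1]), ncol = 1),
              name = name)
  attr(m, "domain") <- range(x)
  attr(m, "cv_range") <- range(zeta)
  m
}

#' Verify a map's Jacobian against central differences
#'
#' Test helper: maximum relative deviation between the declared Jacobian
#' and a central-difference Jacobian of `forward` over a set of probe
#' points.
#'
#' @param map a [cv_map()].
#' @param points matrix of probe points (rows).
#' @param step finite-difference step.
#' @return maximum relative error (scalar).
#' @export
check_jacobian <- function(map, points, step = 1e-6) {
  points <- as_points(points, map$dim_in)
  worst <- 0
  for (i in seq_len(nrow(points))) {
    x <- points[i, ]
    J <- map$jacobian(x)
    Jn <- num_jacobian(function(v) as.numeric(map$forward(as_points(v, map$dim_in))),
                       x, step)
    worst <- max(worst, max(abs(J - Jn)) / max(abs(J), 1e-12))
  }
  worst
}
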