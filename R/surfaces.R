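#' Analytic potential energy surfaces
#'
#' A `potential_surface` bundles an energy function and its analytic
#' gradient over a 1D or 2D configuration space.  Energy is vectorized
#' over the rows of a point matrix; a bare numeric vector is interpreted
#' as a single point.
#'
#' @param dim integer, 1 or 2.
#' @param energy function mapping an `n x dim` matrix to a length-`n`
#'   numeric vector of energies.
#' @param gradient function mapping an `n x dim` matrix to an `n x dim`
#'   matrix of energy gradients.
#' @param params named list of surface parameters (kept for provenance).
#' @param name identifier used in file headers and config lookup.
#' @param periodicity optional numeric vector of per-dimension periods.
#' @return an object of class `potential_surface`.
#' @seealso [quadratic_1d()], [muller_brown()], [synthetic_dipeptide()]
#' @export
potential_surface <- function(dim, energy, gradient, params = list(),
                              name = "custom", periodicity = NULL) {
  stopifnot(dim %in% c(1L, 2L), is.function(energy), is.function(gradient))
  structure(list(dim = as.integer(dim), energy = energy, gradient = gradient,
                 params = params, name = name, periodicity = periodicity),
            class = "potential_surface")
}

#' @export
print.potential_surface <- function(x, ...) {
  cat("<potential_surface>", x$name, " dim =", x$dim, "\n")
  invisible(x)
}

#' Evaluate a surface's energy or gradient
#'
#' @param surface a [potential_surface()].
#' @param points an `n x dim` matrix, or a numeric vector for one point.
#' @return `surface_energy`: numeric vector of length `n`.
#'   `surface_gradient`: an `n x dim` matrix.
#' @export
surface_energy <- function(surface, points) {
  p <- as_points(points, surface$dim)
  surface$energy(p)
}

#' @rdname surface_energy
#' @export
surface_gradient <- function(surface, points) {
  p <- as_points(points, surface$dim)
  surface$gradient(p)
}

#' One-dimensional quadratic benchmark potential V(x) = x^2
#'
#' The reference system for the PMF-invariance demonstrations: in thermal
#' equilibrium at beta = 1 its Boltzmann density is a Gaussian with
#' variance 1/2, and the conventional PMF along the erf CV is exactly
#' flat.
#'
#' @return a [potential_surface()] with `dim = 1`.
#' @export
quadratic_1d <- function() {
  potential_surface(
    1L,
    energy = function(p) p[, 1]^2,
    gradient = function(p) matrix(2 * p[, 1], ncol = 1),
    name = "quadratic1d"
  )
}

#' The Mueller-Brown potential
#'
#' Sum of four anisotropic Gaussians, the standard 2D test surface for
#' path-finding and rate methods:
#' \deqn{V(x,y) = \alpha \sum_{i=1}^4 A_i \exp[a_i (x-x_{0i})^2 +
#'   b_i (x-x_{0i})(y-y_{0i}) + c_i (y-y_{0i})^2]}
#' with parameter tuples (A, a, b, c, x0, y0) equal to
#' (-200, -1, 0, -10, 1, 0), (-100, -1, 0, -10, 0, 0.5),
#' (-170, -6.5, 11, -6.5, -0.5, 1.5) and (15, 0.7, 0.6, 0.7, -1, 1),
#' and overall scale `alpha` (default 0.1, energies then in kcal/mol).
#' The gradient is analytic (closed-form partials of the exponentials),
#' as it is called inside tight simulation and string-method loops.
#'
#' @param alpha overall scaling factor.
#' @return a [potential_surface()] with `dim = 2`.
#' @export
muller_brown <- function(alpha = 0.1) {
  A <- c(-200, -100, -170, 15)
  a <- c(-1, -1, -6.5, 0.7)
  b <- c(0, 0, 11, 0.6)
  cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1)
  y0 <- c(0, 0.5, 1.5, 1)
  energy <- function(p) {
    v <- numeric(nrow(p))
    for (i in 1:4) {
      dx <- p[, 1] - x0[i]; dy <- p[, 2] - y0[i]
      v <- v + A[i] * exp(a[i] * dx^2 + b[i] * dx * dy + cc[i] * dy^2)
    }
    alpha * v
  }
  gradient <- function(p) {
    gx <- numeric(nrow(p)); gy <- numeric(nrow(p))
    for (i in 1:4) {
      dx <- p[, 1] - x0[i]; dy <- p[, 2] - y0[i]
      e <- A[i] * exp(a[i] * dx^2 + b[i] * dx * dy + cc[i] * dy^2)
      gx <- gx + e * (2 * a[i] * dx + b[i] * dy)
      gy <- gy + e * (b[i] * dx + 2 * cc[i] * dy)
    }
    alpha * cbind(gx, gy, deparse.level = 0)
  }
  potential_surface(2L, energy, gradient,
                    params = list(A = A, a = a, b = b, c = cc,
                                  x0 = x0, y0 = y0, alpha = alpha),
                    name = "muller_brown")
}

#' Mueller-Brown energy at a single point
#'
#' Convenience scalar accessor for the [muller_brown()] surface.
#'
#' @param point length-2 numeric vector (x, y).
#' @param alpha overall scaling factor.
#' @return scalar energy.
#' @export
muller_brown_energy <- function(point, alpha = 0.1) {
  if (!all(is.finite(point))) stop_domain("non-finite input point")
  surface_energy(muller_brown(alpha), point)
}

#' Synthetic periodic two-well surface
#'
#' A fully periodic 2D surface with two metastable wells separated along
#' the first angle, emulating the topology of a dihedral-angle free
#' energy landscape (two basins joined by one low channel, with the
#' antipodal channel strongly suppressed).  Energies are in units of
#' kBT at beta = 1:
#' \deqn{V(\phi,\psi) = \Delta (1-\cos 2\phi)/2 + c (1-\sin\phi)^2/2 +
#'   k (1-\cos\psi)/2.}
#' The wells sit near phi = 0.3 and pi - 0.3, the low channel passes
#' phi = pi/2 (barrier about 1.4 kBT above the wells at the defaults,
#' low enough that an equilibrium trajectory of a thousand time units
#' crosses a few hundred times)
#' and the phi = 3*pi/2 channel is higher by `2*c`, so essentially all
#' transitions use the low channel.  This surface is synthetic: it
#' stands in for molecular-dynamics data that the package does not
#' require, and its defaults define the package's reference study
#' conditions for likelihood-based rate estimation.
#'
#' @param barrier double-well amplitude Delta (kBT).
#' @param asym amplitude c of the channel-asymmetry term (kBT).
#' @param k_psi stiffness of the transverse angle (kBT).
#' @return a [potential_surface()] with `dim = 2` and period `2*pi` in
#'   both dimensions.
#' @export
synthetic_dipeptide <- function(barrier = 2.2, asym = 2.5, k_psi = 8) {
  energy <- function(p) {
    barrier * (1 - cos(2 * p[, 1])) / 2 +
      asym * (1 - sin(p[, 1]))^2 / 2 +
      k_psi * (1 - cos(p[, 2])) / 2
  }
  gradient <- function(p) {
    cbind(barrier * sin(2 * p[, 1]) -
            asym * (1 - sin(p[, 1])) * cos(p[, 1]),
          k_psi * sin(p[, 2]) / 2, deparse.level = 0)
  }
  potential_surface(2L, energy, gradient,
                    params = list(barrier = barrier, asym = asym, k_psi = k_psi),
                    name = "synthetic_dipeptide",
                    periodicity = c(2 * pi, 2 * pi))
}

#' Look up a built-in surface by name
#'
#' Recognized ids: `"quadratic1d"`, `"muller_brown"` (optional `alpha`),
#' `"synthetic_dipeptide"`.
#'
#' @param id character id.
#' @param ... parameters forwarded to the surface constructor.
#' @return a [potential_surface()].
#' @export
surface_by_name <- function(id, ...) {
  switch(id,
         quadratic1d = quadratic_1d(),
         muller_brown = muller_brown(...),
         synthetic_dipeptide = synthetic_dipeptide(...),
         stop_domain(paste0("unknown surface id: '", id, "'")))
}

#' Locate the minima of a surface by local descent
#'
#' BFGS descent from a starting point, used to relax string endpoints
#' into their basins.
#'
#' @param surface a [potential_surface()].
#' @param start numeric starting point.
#' @return list with `par` (the minimum) and `value` (its energy).
#' @export
relax_to_minimum <- function(surface, start) {
  fn <- function(x) surface_energy(surface, x)
  gr <- function(x) as.numeric(surface_gradient(surface, x))
  res <- stats::optim(start, fn, gr, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  list(par = res$par, value = res$value)
}
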