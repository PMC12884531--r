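#' Metric fields on CV space
#'
#' A `metric_field` evaluates a position-dependent metric tensor: either
#' a full `d x d` symmetric positive-definite matrix `g(zeta)` or a 1D
#' scalar metric `h(r)` along a path.  An optional analytic derivative
#' (`dg`) is used by [christoffel_drift()] in place of finite
#' differences.
#'
#' @param evaluator function: point -> `d x d` matrix (representation
#'   `"matrix"`) or scalar (representation `"scalar"`).
#' @param dim dimension of the space the metric lives on.
#' @param representation `"matrix"` or `"scalar"`.
#' @param g0 reference constant, the metric (determinant) at a declared
#'   reference point; must be positive.
#' @param dg optional analytic derivative: for `"matrix"`, function
#'   point -> `d x d x d` array with `dg[i,j,k] = d g_ij / d zeta_k`;
#'   for `"scalar"`, function r -> dh/dr.
#' @param name identifier.
#' @return an object of class `metric_field`.
#' @export
metric_field <- function(evaluator, dim, representation = c("matrix", "scalar"),
                         g0 = 1, dg = NULL, name = "custom") {
  representation <- match.arg(representation)
  if (!is.finite(g0) || g0 <= 0) stop_degenerate("reference constant g0 must be > 0")
  structure(list(evaluator = evaluator, dim = as.integer(dim),
                 representation = representation, g0 = g0, dg = dg,
                 name = name),
            class = "metric_field")
}

#' @export
print.metric_field <- function(x, ...) {
  cat("<metric_field>", x$name, " dim =", x$dim, " (", x$representation, ")\n")
  invisible(x)
}

#' Evaluate a metric field, with SPD validation
#'
#' @param metric a [metric_field()].
#' @param point evaluation point.
#' @return `d x d` matrix (or scalar for the 1D representation).
#' @export
metric_eval <- function(metric, point) {
  g <- metric$evaluator(point)
  if (metric$representation == "scalar") {
    if (!is.finite(g) || g <= 0)
      stop_degenerate("scalar metric must be positive and finite")
    return(g)
  }
  g <- (g + t(g)) / 2
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  if (any(!is.finite(ev)) || min(ev) <= 0)
    stop_degenerate("metric is not symmetric positive definite at the point")
  g
}

#' Built-in metric fields
#'
#' * `metric_euclidean(dim)`: constant identity metric.
#' * `metric_logpolar()`: the metric `exp(2X) * I` induced on the
#'   log-polar plane by the Euclidean (x, y) geometry, with analytic
#'   derivatives registered.
#' * `metric_exp2r()`: the 1D scalar metric `h(r) = exp(2r)` used as a
#'   Christoffel benchmark.
#'
#' @param dim dimension.
#' @return a [metric_field()].
#' @export
metric_euclidean <- function(dim = 2L) {
  metric_field(function(p) diag(nrow = dim), dim, "matrix",
               dg = function(p) array(0, c(dim, dim, dim)),
               name = "euclidean")
}

#' @rdname metric_euclidean
#' @export
metric_logpolar <- function() {
  metric_field(
    function(p) exp(2 * p[1]) * diag(2),
    2L, "matrix",
    dg = function(p) {
      d <- array(0, c(2, 2, 2))
      d[, , 1] <- 2 * exp(2 * p[1]) * diag(2)  # only the X-derivative is nonzero
      d
    },
    name = "logpolar_induced")
}

#' @rdname metric_euclidean
#' @export
metric_exp2r <- function() {
  metric_field(function(r) exp(2 * r), 1L, "scalar",
               dg = function(r) 2 * exp(2 * r), name = "exp2r")
}

#' Look up a built-in metric by name
#'
#' Recognized ids: `"euclidean"`, `"logpolar"` (the induced
#' `exp(2X) * I` metric), `"exp2r"`.
#'
#' @param id character id.
#' @param dim dimension for the Euclidean metric.
#' @return a [metric_field()].
#' @export
metric_by_name <- function(id, dim = 2L) {
  switch(id,
         euclidean = metric_euclidean(dim),
         logpolar = metric_logpolar(),
         exp2r = metric_exp2r(),
         stop_domain(paste0("unknown metric id: '", id, "'")))
}

#' Pointwise inverse metric induced by a CV map
#'
#' The inverse metric on CV space has entries
#' `g^{-1}_ij = grad(xi_i) . grad(xi_j)`, i.e. `J %*% t(J)` with `J` the
#' CV Jacobian.  This is the pointwise version; the ensemble-averaged
#' (bin-conditional) version is assembled by [histogram_pmf()] by
#' averaging this output over the samples in a bin.
#'
#' @param map a [cv_map()].
#' @param point configuration-space point.
#' @return `dim_out x dim_out` SPD matrix.
#' @export
induced_metric_inverse <- function(map, point) {
  J <- eval_cv(map, point)$jacobian
  gi <- J %*% t(J)
  if (!all(is.finite(gi)) || det(gi) <= .Machine$double.eps^2)
    stop_degenerate("rank-deficient Jacobian: induced metric is degenerate")
  gi
}

#' Metric field induced by an invertible CV map
#'
#' Evaluates `g(zeta) = solve(J J^T)` at `x = inverse(zeta)`; requires
#' the map to carry an inverse.
#'
#' @param map an invertible [cv_map()].
#' @return a [metric_field()] on the CV space.
#' @export
induced_metric_field <- function(map) {
  if (is.null(map$inverse)) stop_domain("map has no inverse; cannot induce a CV-space metric")
  metric_field(function(zeta) {
    x <- as.numeric(map$inverse(as_points(zeta, map$dim_out)))
    solve(induced_metric_inverse(map, x))
  }, map$dim_out, "matrix", name = paste0("induced:", map$name))
}

# dg array (d x d x d) by central differences of the evaluator
metric_dg_numeric <- function(metric, point, step = 1e-4) {
  d <- metric$dim
  out <- array(0, c(d, d, d))
  for (k in seq_len(d)) {
    e <- numeric(d); e[k] <- step
    gp <- metric_eval(metric, point + e)
    gm <- metric_eval(metric, point - e)
    out[, , k] <- (gp - gm) / (2 * step)
  }
  out
}

#' Christoffel drift of diffusion on a curved CV space
#'
#' The spurious-drift correction of overdamped Langevin dynamics on a
#' Riemannian CV space: `b_i = -D * g^{jk} Gamma^i_{jk}`, with
#' Christoffel symbols
#' `Gamma^i_{jk} = g^{il} (d_j g_{lk} + d_k g_{lj} - d_l g_{jk}) / 2`.
#' Metric derivatives come from a registered analytic `dg` when the
#' metric carries one, otherwise from central differences with step
#' `step` (default `1e-4` in CV units).
#'
#' For the 1D scalar representation the drift reduces to
#' `b = -D h'(r) / (2 h(r)^2)`.
#'
#' @param metric a [metric_field()].
#' @param point evaluation point.
#' @param D diffusion constant.
#' @param step finite-difference step for metric derivatives.
#' @return drift vector (length `dim`).
#' @export
christoffel_drift <- function(metric, point, D, step = 1e-4) {
  if (metric$representation == "scalar") {
    h <- metric_eval(metric, point)
    dh <- if (!is.null(metric$dg)) metric$dg(point) else
      (metric_eval(metric, point + step) - metric_eval(metric, point - step)) / (2 * step)
    return(-D * dh / (2 * h^2))
  }
  d <- metric$dim
  g <- metric_eval(metric, point)
  ginv <- solve(g)
  dg <- if (!is.null(metric$dg)) metric$dg(point) else
    metric_dg_numeric(metric, point, step)
  b <- numeric(d)
  for (i in seq_len(d)) {
    # Gamma^i_{jk} contracted with g^{jk}
    acc <- 0
    for (j in seq_len(d)) for (k in seq_len(d)) {
      gam <- 0
      for (l in seq_len(d))
        gam <- gam + ginv[i, l] * (dg[l, k, j] + dg[l, j, k] - dg[j, k, l]) / 2
      acc <- acc + ginv[j, k] * gam
    }
    b[i] <- -D * acc
  }
  b
}
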