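#' Discretized transition paths
#'
#' An ordered set of bin centers along a transition path, with a
#' normalized path parameter `r` in `[0, 1]`, uniform spacing
#' `delta_r = 1/(n_bins - 1)`, and the 1D metric along the path at the
#' nodes (`h_nodes`) and at the bond midpoints (`h_mid`), so that the
#' metric arc element is `delta_s = sqrt(h) * delta_r`.
#'
#' @param centers `n_bins x dim` matrix of CV points, ordered from state
#'   A to state B.
#' @param r path parameter per center (strictly increasing, uniform).
#' @param h_nodes positive metric values at the centers.
#' @param h_mid positive metric values at bond midpoints (length
#'   `n_bins - 1`); by default the inverse-square-root interpolation
#'   `1/sqrt(h_mid) = (1/sqrt(h_n) + 1/sqrt(h_{n+1})) / 2`.
#' @param periodicity optional per-dimension period for bin assignment.
#' @param metric_id identifier of the metric used, for file headers.
#' @return an object of class `discretized_path`.
#' @export
discretized_path <- function(centers, r = NULL, h_nodes = NULL,
                             h_mid = NULL, periodicity = NULL,
                             metric_id = "euclidean") {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 1)
  n <- nrow(centers)
  if (n < 2) stop_domain("a path needs at least 2 centers")
  if (is.null(r)) r <- seq(0, 1, length.out = n)
  dr <- diff(r)
  if (any(dr <= 0) || max(abs(dr - dr[1])) > 1e-12)
    stop_domain("path parameter r must be strictly increasing and uniform")
  if (is.null(h_nodes)) h_nodes <- rep(1, n)
  if (any(h_nodes <= 0)) stop_degenerate("h must be positive along the path")
  if (is.null(h_mid)) h_mid <- interp_h_mid(h_nodes)
  if (any(h_mid <= 0)) stop_degenerate("h must be positive along the path")
  structure(list(centers = centers, r = r, delta_r = dr[1],
                 h_nodes = h_nodes, h_mid = h_mid,
                 periodicity = periodicity, metric_id = metric_id),
            class = "discretized_path")
}

# the inverse-square-root midpoint interpolation used throughout the
# rate-matrix machinery: 1/sqrt(h_mid) = mean of 1/sqrt(h) at the nodes
interp_h_mid <- function(h_nodes) {
  a <- 1 / sqrt(h_nodes)
  ((a[-length(a)] + a[-1]) / 2)^-2
}

#' @export
print.discretized_path <- function(x, ...) {
  cat("<discretized_path> ", nrow(x$centers), " centers, dim = ",
      ncol(x$centers), ", metric = ", x$metric_id, "\n", sep = "")
  invisible(x)
}

# metric length of each segment of a polyline, metric evaluated at
# segment midpoints (2nd order)
segment_lengths <- function(points, metric) {
  m <- nrow(points)
  dz <- points[-1, , drop = FALSE] - points[-m, , drop = FALSE]
  mid <- (points[-1, , drop = FALSE] + points[-m, , drop = FALSE]) / 2
  if (identical(metric, "euclidean") || is.null(metric)) {
    return(sqrt(rowSums(dz^2)))
  }
  stopifnot(inherits(metric, "metric_field"))
  vapply(seq_len(m - 1), function(i) {
    g <- metric_eval(metric, mid[i, ])
    if (metric$representation == "scalar") sqrt(g) * sqrt(sum(dz[i, ]^2))
    else sqrt(drop(dz[i, ] %*% g %*% dz[i, ]))
  }, numeric(1))
}

# scalar h of a matrix metric along a curve: squared metric length of
# the Euclidean-unit tangent, t' g t / (t' t)
tangent_h <- function(centers, metric) {
  n <- nrow(centers)
  tan <- centers[c(2:n, n), , drop = FALSE] - centers[c(1, 1:(n - 1)), , drop = FALSE]
  vapply(seq_len(n), function(i) {
    g <- metric_eval(metric, centers[i, ])
    if (metric$representation == "scalar") return(g)
    drop(tan[i, ] %*% g %*% tan[i, ]) / sum(tan[i, ]^2)
  }, numeric(1))
}

#' Reparameterize a polyline by (metric) arc length
#'
#' Computes the cumulative length of a polyline in CV space under a
#' metric (segment length `sqrt(dz' g dz)` with `g` at the segment
#' midpoint) and returns `n_bins` centers equally spaced in that
#' length, with `r` normalized to `[0, 1]`.
#'
#' The `h` fields of the returned path are populated as follows: when
#' no second metric is requested, `h = L^2` (the squared total length)
#' at every node, so that `delta_s = sqrt(h) * delta_r` recovers the
#' true spacing; when `h_metric` is supplied, `h` is that metric
#' evaluated along the path — for a matrix metric, the squared metric
#' norm of the Euclidean-unit tangent (e.g. the conformal factor
#' `exp(2X)` for the log-polar metric).
#'
#' @param points polyline vertices (`m x dim` matrix) ordered A to B.
#' @param metric `"euclidean"` or a [metric_field()] used for spacing.
#' @param n_bins number of output centers (>= 2).
#' @param h_metric optional second [metric_field()] whose scalar
#'   restriction along the path populates `h_nodes` / `h_mid`.
#' @param smooth if TRUE, interpolate the polyline with natural cubic
#'   splines in cumulative length (resampled densely) before spacing;
#'   recommended when the input is a coarse string-method path.
#' @param periodicity forwarded to the [discretized_path()].
#' @return a [discretized_path()].
#' @export
reparameterize <- function(points, metric = "euclidean", n_bins,
                           h_metric = NULL, smooth = FALSE,
                           periodicity = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  points <- points[c(TRUE, rowSums(abs(diff(points))) > 0), , drop = FALSE]
  if (nrow(points) < 2) stop_domain("zero-length path")
  stopifnot(n_bins >= 2)
  if (smooth && nrow(points) > 3) {
    s0 <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
    dense <- seq(0, max(s0), length.out = max(40 * nrow(points), 4000))
    points <- vapply(seq_len(ncol(points)),
                     function(j) stats::splinefun(s0, points[, j],
                                                  method = "natural")(dense),
                     numeric(length(dense)))
  }
  seg <- segment_lengths(points, metric)
  cs <- c(0, cumsum(seg))
  L <- cs[length(cs)]
  if (L <= 0) stop_domain("zero-length path")
  targets <- seq(0, L, length.out = n_bins)
  centers <- vapply(seq_len(ncol(points)),
                    function(j) stats::approx(cs, points[, j], xout = targets,
                                              ties = "ordered")$y,
                    numeric(n_bins))
  if (n_bins == 1) centers <- matrix(centers, ncol = ncol(points))
  metric_id <- if (identical(metric, "euclidean")) "euclidean" else metric$name
  if (is.null(h_metric)) {
    h_nodes <- rep(L^2, n_bins)
    h_mid <- rep(L^2, n_bins - 1)
  } else {
    h_nodes <- tangent_h(centers, h_metric)
    h_mid <- interp_h_mid(h_nodes)
    metric_id <- paste0(metric_id, "+h:", h_metric$name)
  }
  p <- discretized_path(centers, seq(0, 1, length.out = n_bins),
                        h_nodes, h_mid, periodicity, metric_id)
  attr(p, "total_length") <- L
  p
}

#' Minimum free energy path by a zero-temperature string method
#'
#' Finds a path satisfying the invariant MFEP condition — tangent
#' everywhere parallel to the invariant gradient `g^{-1} grad(A)` — by
#' alternating steepest-descent moves of the interior images with
#' equal-arc-length re-spacing ([reparameterize()] under the same
#' metric).  Endpoints are first relaxed to their local minima; if both
#' relax to the same minimum the path is degenerate and an error of
#' class `riemcv_distinct_minima` is raised.  Images move with a fixed
#' step `gamma = gamma_scale * L / max|g^{-1} grad A|` (no line
#' search, so the iteration is deterministic).
#'
#' @param surface a [potential_surface()] providing `A` and its gradient.
#' @param metric `"euclidean"` or a [metric_field()].
#' @param endpoints 2-row matrix (or list of two points) near the two
#'   basins.
#' @param n_images number of string images.
#' @param tol convergence threshold on the maximum image displacement
#'   per iteration.
#' @param max_iter iteration cap; exceeding it raises an error of class
#'   `riemcv_string_not_converged` carrying the last path and residual.
#' @param gamma_scale dimensionless step-size factor.
#' @return a converged [discretized_path()] with attributes
#'   `iterations`, `residual` (max displacement of the final iteration)
#'   and `perp_residual` (max norm of the invariant-gradient component
#'   perpendicular to the path tangent at interior images).
#' @export
string_mfep <- function(surface, metric = "euclidean", endpoints,
                        n_images = 20L, tol = 1e-8, max_iter = 50000L,
                        gamma_scale = 0.01) {
  if (is.list(endpoints)) endpoints <- do.call(rbind, endpoints)
  stopifnot(nrow(endpoints) == 2, n_images >= 3)
  d <- surface$dim
  e1 <- relax_to_minimum(surface, endpoints[1, ])
  e2 <- relax_to_minimum(surface, endpoints[2, ])
  if (sqrt(sum((e1$par - e2$par)^2)) < 1e-6)
    stop(riemcv_error("endpoints relax to the same minimum: degenerate path",
                      "riemcv_distinct_minima"))
  t0 <- seq(0, 1, length.out = n_images)
  path <- outer(1 - t0, e1$par) + outer(t0, e2$par)
  inv_grad <- function(p) {
    g <- surface$gradient(p)
    if (identical(metric, "euclidean")) return(g)
    t(vapply(seq_len(nrow(p)), function(i)
      as.numeric(solve(metric_eval(metric, p[i, ]), g[i, ])), numeric(d)))
  }
  res <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    w <- inv_grad(path)
    mg <- max(sqrt(rowSums(w^2)))
    if (mg == 0) { res <- 0; break }  # flat potential: already converged
    L <- sum(segment_lengths(path, metric))
    gam <- gamma_scale * L / mg
    moved <- path
    moved[2:(n_images - 1), ] <- path[2:(n_images - 1), ] -
      gam * w[2:(n_images - 1), ]
    newp <- reparameterize(moved, metric, n_images)$centers
    res <- max(sqrt(rowSums((newp - path)^2)))
    path <- newp
    if (res < tol) break
  }
  out <- reparameterize(path, metric, n_images)
  attr(out, "iterations") <- it
  attr(out, "residual") <- res
  # invariant-gradient component perpendicular to the tangent
  w <- inv_grad(path)
  tanv <- path[c(2:n_images, n_images), ] - path[c(1, 1:(n_images - 1)), ]
  tanv <- tanv / sqrt(rowSums(tanv^2))
  perp <- w - tanv * rowSums(w * tanv)
  attr(out, "perp_residual") <- max(sqrt(rowSums(perp^2))[2:(n_images - 1)])
  if (it >= max_iter && res >= tol)
    stop(riemcv_error(
      sprintf("string method did not converge in %d iterations (residual %g)",
              max_iter, res),
      "riemcv_string_not_converged", path = out, residual = res))
  out
}

#' Assign CV points to path bins
#'
#' Nearest-center assignment (Euclidean in CV coordinates, with
#' per-dimension minimum-image wrapping when the path declares a
#' periodicity).  Ties break toward the lower index.  This realizes the
#' Voronoi-cell binning used to turn trajectories into transition
#' counts along a path.
#'
#' @param points `n x dim` matrix of CV points (or vector for one).
#' @param path a [discretized_path()].
#' @return integer vector of 1-based center indices.
#' @export
assign_bins <- function(points, path) {
  centers <- path$centers
  points <- as_points(points, ncol(centers))
  per <- path$periodicity
  d2 <- matrix(0, nrow(points), nrow(centers))
  for (k in seq_len(ncol(centers))) {
    diffk <- outer(points[, k], centers[, k], `-`)
    if (!is.null(per) && is.finite(per[k]))
      diffk <- diffk - per[k] * round(diffk / per[k])
    d2 <- d2 + diffk^2
  }
  max.col(-d2, ties.method = "first")
}

#' Path file I/O
#'
#' CSV columns `index, r, cv1..cvd, h_node`; header lines record the
#' metric id, number of bins and normalization.  Midpoint `h` values
#' are reconstructed by the inverse-square-root interpolation on read.
#'
#' @param path a [discretized_path()].
#' @param file path to write/read.
#' @return the file path (writer, invisibly) or a [discretized_path()]
#'   (reader).
#' @export
write_path_csv <- function(path, file) {
  d <- data.frame(index = seq_len(nrow(path$centers)) - 1L)
  d$r <- path$r
  for (j in seq_len(ncol(path$centers)))
    d[[paste0("cv", j)]] <- path$centers[, j]
  d$h_node <- path$h_nodes
  hdr <- c(sprintf("# metric: %s", path$metric_id),
           sprintf("# n_bins: %d", nrow(path$centers)),
           "# normalization: r in [0,1]",
           if (!is.null(path$periodicity))
             sprintf("# periodicity: %s",
                     paste(fmt_num(path$periodicity), collapse = " ")))
  write_table_csv(d, file, hdr)
}

#' @rdname write_path_csv
#' @export
read_path_csv <- function(file) {
  d <- read_table_csv(file)
  hdr <- parse_header(attr(d, "header"))
  centers <- as.matrix(d[, grepl("^cv", names(d)), drop = FALSE])
  per <- if ("periodicity" %in% names(hdr)) {
    tok <- strsplit(hdr[["periodicity"]], " ")[[1]]
    ifelse(tok == "NA", NA_real_, suppressWarnings(as.numeric(tok)))
  } else NULL
  discretized_path(unname(centers), d$r, d$h_node, periodicity = per,
                   metric_id = unname(hdr["metric"]))
}
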