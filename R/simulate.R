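#' Configure an overdamped Langevin simulation
#'
#' Bundles everything [simulate_overdamped()] needs.  In Euclidean mode
#' (no metric) the dynamics are
#' `dx = -beta*D*grad(V) dt + sqrt(2*D) dW`.  With a metric the
#' Riemannian form is used: invariant gradient `g^{-1} grad(A)`,
#' Christoffel drift `b`, and noise covariance `2*D*dt*g^{-1}`.
#'
#' @param surface a [potential_surface()] (its energy is interpreted as
#'   the free energy `A` on the CV space being simulated).
#' @param metric optional [metric_field()] (matrix representation) for
#'   Riemannian dynamics.
#' @param D diffusion constant (length^2 / time).
#' @param beta inverse temperature.
#' @param dt time step.
#' @param n_steps number of integration steps.
#' @param x0 initial point.
#' @param seed integer RNG seed (recorded in outputs).
#' @param bounds optional `dim x 2` matrix of (lower, upper) bounds; a
#'   step leaving the box aborts the run with the offending step index.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(surface, metric = NULL, D = 1, beta = 1,
                              dt = 1e-3, n_steps = 1000L, x0,
                              seed = 1L, bounds = NULL) {
  stopifnot(dt > 0, D >= 0, n_steps >= 1)
  structure(list(surface = surface, metric = metric, D = D, beta = beta,
                 dt = dt, n_steps = as.integer(n_steps),
                 x0 = as.numeric(x0), seed = as.integer(seed),
                 bounds = bounds),
            class = "simulation_config")
}

#' Overdamped Langevin simulation on a (possibly curved) CV space
#'
#' Explicit Euler-Maruyama integration of
#' \deqn{d\zeta = -(\beta D\, g^{-1}\nabla A + b)\,dt + \sqrt{2D}\,dW}
#' with all coefficients frozen at the step's start point (Ito
#' convention).  Euclidean mode (`metric = NULL`) uses `b = 0` and
#' identity noise covariance; Riemannian mode draws Gaussian increments
#' with covariance `2*D*dt*g^{-1}` and adds the Christoffel drift from
#' [christoffel_drift()].  Identical seeds give bit-identical
#' trajectories, and a constant identity metric reproduces the Euclidean
#' trajectory exactly.
#'
#' @param config a [simulation_config()].
#' @return an object of class `trajectory`: list with `times` (length
#'   `n_steps + 1`), `points` (`(n_steps+1) x dim` matrix including the
#'   initial point), and `config`.
#' @export
simulate_overdamped <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  d <- config$surface$dim
  n <- config$n_steps
  x <- matrix(NA_real_, n + 1L, d)
  x[1, ] <- config$x0
  set.seed(config$seed)
  z <- matrix(stats::rnorm(n * d), n, d)
  dt <- config$dt; D <- config$D; beta <- config$beta
  sgrad <- config$surface$gradient
  gradfun <- function(p) sgrad(matrix(p, nrow = 1))[1, ]
  bounds <- config$bounds
  amp <- sqrt(2 * D * dt)
  cur <- config$x0
  if (is.null(config$metric)) {
    for (i in seq_len(n)) {
      cur <- cur - beta * D * gradfun(cur) * dt + amp * z[i, ]
      if (!is.null(bounds) &&
          (any(cur < bounds[, 1]) || any(cur > bounds[, 2])))
        stop_domain(paste0("trajectory left the bounding box at step ", i))
      x[i + 1L, ] <- cur
    }
  } else {
    metric <- config$metric
    for (i in seq_len(n)) {
      g <- metric_eval(metric, cur)
      ginv <- solve(g)
      b <- christoffel_drift(metric, cur, D)
      drift <- -beta * D * as.numeric(ginv %*% gradfun(cur)) + b
      L <- t(chol(2 * D * dt * ginv))
      cur <- cur + drift * dt + as.numeric(L %*% z[i, ])
      if (!is.null(bounds) &&
          (any(cur < bounds[, 1]) || any(cur > bounds[, 2])))
        stop_domain(paste0("trajectory left the bounding box at step ", i))
      x[i + 1L, ] <- cur
    }
  }
  structure(list(times = seq(0, n) * dt, points = x, config = config),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", nrow(x$points) - 1L, " steps, dim = ",
      ncol(x$points), ", dt = ", x$config$dt, ", seed = ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Count lagged transitions between bins
#'
#' Harvests (origin, destination) bin pairs at a fixed lag from a bin
#' index series.  Sliding mode emits one pair for every time origin
#' (maximal data, statistically dependent pairs); strided mode uses
#' non-overlapping origins `1, 1+lag, 1+2*lag, ...`.
#'
#' @param bin_series integer vector of 1-based bin indices over time.
#' @param n_bins number of bins.
#' @param lag_steps lag expressed in series steps (>= 1).
#' @param mode `"sliding"` or `"strided"`.
#' @param dt time per series step, so that `lag = lag_steps * dt` in
#'   time units.
#' @return an object of class `transition_counts`: list with `n_bins`,
#'   `lag` (time units), `lag_steps`, `mode`, and `counts`, an
#'   `n_bins x n_bins` integer matrix with `counts[j, i]` the number of
#'   observed `i -> j` transitions.
#' @export
harvest_transitions <- function(bin_series, n_bins, lag_steps,
                                mode = c("sliding", "strided"), dt = 1) {
  mode <- match.arg(mode)
  lag_steps <- as.integer(lag_steps)
  stopifnot(lag_steps >= 1, length(bin_series) > lag_steps)
  b <- as.integer(bin_series)
  if (any(b < 1L | b > n_bins))
    stop_domain("bin index outside [1, n_bins] in series")
  L <- length(b)
  origins <- if (mode == "sliding") seq_len(L - lag_steps)
             else seq(1L, L - lag_steps, by = lag_steps)
  i <- b[origins]; j <- b[origins + lag_steps]
  cnt <- tabulate(j + (i - 1L) * n_bins, nbins = n_bins * n_bins)
  counts <- matrix(cnt, n_bins, n_bins)
  structure(list(n_bins = as.integer(n_bins), lag = lag_steps * dt,
                 lag_steps = lag_steps, mode = mode, counts = counts),
            class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("<transition_counts> ", sum(x$counts), " pairs over ", x$n_bins,
      " bins at lag ", x$lag, " (", x$mode, ")\n", sep = "")
  invisible(x)
}

#' Trajectory and transition-count file I/O
#'
#' Trajectories are CSV with columns `time, cv1[, cv2]` and `#`-prefixed
#' header lines recording `seed, dt, D, beta`.  Transition counts are
#' CSV triplets `i, j, count` (1-based bin indices, `count` of `i -> j`
#' transitions) with header fields `n_bins` and `lag`.
#'
#' @param traj a `trajectory`.
#' @param file path.
#' @return the path (writers, invisibly) or the reconstructed object
#'   (readers).
#' @export
write_trajectory <- function(traj, file) {
  cfg <- traj$config
  d <- as.data.frame(traj$points)
  names(d) <- paste0("cv", seq_len(ncol(d)))
  d <- cbind(time = traj$times, d)
  hdr <- sprintf("# %s: %s", c("seed", "dt", "D", "beta"),
                 fmt_num(c(cfg$seed, cfg$dt, cfg$D, cfg$beta)))
  write_table_csv(d, file, hdr)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  d <- read_table_csv(file)
  hdr <- parse_header(attr(d, "header"))
  pts <- as.matrix(d[, grepl("^cv", names(d)), drop = FALSE])
  structure(list(times = d$time, points = unname(pts),
                 config = list(seed = as.integer(hdr["seed"]),
                               dt = as.numeric(hdr["dt"]),
                               D = as.numeric(hdr["D"]),
                               beta = as.numeric(hdr["beta"]))),
            class = "trajectory")
}

#' @rdname write_trajectory
#' @param counts a `transition_counts`.
#' @export
write_counts_csv <- function(counts, file) {
  nz <- which(counts$counts > 0L, arr.ind = TRUE)
  d <- data.frame(i = nz[, 2], j = nz[, 1],
                  count = counts$counts[nz])
  d <- d[order(d$i, d$j), , drop = FALSE]
  hdr <- sprintf("# %s: %s", c("n_bins", "lag", "lag_steps", "mode"),
                 c(counts$n_bins, fmt_num(counts$lag), counts$lag_steps,
                   counts$mode))
  write_table_csv(d, file, hdr)
}

#' @rdname write_trajectory
#' @export
read_counts_csv <- function(file) {
  d <- read_table_csv(file)
  hdr <- parse_header(attr(d, "header"))
  n <- as.integer(hdr["n_bins"])
  counts <- matrix(0L, n, n)
  counts[cbind(d$j, d$i)] <- as.integer(d$count)
  structure(list(n_bins = n, lag = as.numeric(hdr["lag"]),
                 lag_steps = as.integer(hdr["lag_steps"]),
                 mode = unname(hdr["mode"]), counts = counts),
            class = "transition_counts")
}

parse_header <- function(lines) {
  kv <- strsplit(lines, ": ", fixed = TRUE)
  kv <- kv[vapply(kv, length, 1L) == 2L]
  stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
}
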