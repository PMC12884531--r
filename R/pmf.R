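#' PMF profiles
#'
#' Container for conventional and invariant (Riemannian) potential of
#' mean force values on a CV grid.  The conventional PMF is
#' `-log(marginal density)/beta`; the invariant PMF adds the metric
#' correction `log(g/g0) / (2*beta)`, which makes it unchanged under
#' smooth reparameterization of the CV.
#'
#' Analytic constructors return raw (unshifted) values; the histogram
#' constructor shifts both profiles by one common constant so the
#' conventional minimum is 0 (a PMF is defined up to an additive
#' constant, and a common shift preserves the per-bin identity
#' `invariant - conventional = log(g/g0)/(2*beta)` exactly).
#'
#' @param grid bin centers: numeric vector (1D) or `n x d` matrix.
#' @param conventional conventional PMF values.
#' @param invariant invariant PMF values.
#' @param beta inverse temperature.
#' @param metric_det per-bin metric determinant `g`, or NULL.
#' @param g0 reference metric constant.
#' @param mask logical: TRUE where the bin holds valid values.
#' @param counts optional per-bin sample counts.
#' @return an object of class `pmf_profile`.
#' @export
pmf_profile <- function(grid, conventional, invariant, beta,
                        metric_det = NULL, g0 = 1, mask = NULL,
                        counts = NULL) {
  n <- if (is.matrix(grid)) nrow(grid) else length(grid)
  if (is.null(mask)) mask <- rep(TRUE, n)
  structure(list(grid = grid, conventional = conventional,
                 invariant = invariant, beta = beta,
                 metric_det = metric_det, g0 = g0, mask = mask,
                 counts = counts),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  n <- if (is.matrix(x$grid)) nrow(x$grid) else length(x$grid)
  cat("<pmf_profile> ", n, " bins (", sum(x$mask), " valid), beta = ",
      x$beta, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.pmf_profile <- function(x, ...) {
  g <- x$grid
  if (!is.matrix(g)) g <- matrix(g, ncol = 1)
  d <- data.frame(bin_index = seq_len(nrow(g)) - 1L)
  for (j in seq_len(ncol(g)))
    d[[if (ncol(g) == 1) "zeta" else paste0("zeta", j)]] <- g[, j]
  d$count <- if (is.null(x$counts)) NA_integer_ else x$counts
  d$A_conventional <- x$conventional
  d$A_invariant <- x$invariant
  d$g_det <- if (is.null(x$metric_det)) NA_real_ else x$metric_det
  d$mask <- as.integer(x$mask)
  d
}

# validate a strictly monotone-increasing 1D map on a zeta grid
check_monotone_1d <- function(map, zeta_grid) {
  if (map$dim_in != 1L || map$dim_out != 1L)
    stop_domain("a 1D -> 1D CV map is required")
  if (is.null(map$inverse))
    stop(riemcv_error("CV map has no inverse on the grid", "riemcv_invalid_cv"))
  x <- map$inverse(matrix(zeta_grid, ncol = 1))[, 1]
  xp <- vapply(x, function(xx) map$jacobian(xx)[1, 1], numeric(1))
  if (any(!is.finite(xp)) || any(xp <= 0))
    stop(riemcv_error("CV map is not strictly increasing on the grid",
                      "riemcv_invalid_cv"))
  list(x = x, xi_prime = xp)
}

#' Conventional 1D PMF along a monotone CV
#'
#' For a 1D system with potential `V(x)` at inverse temperature `beta`,
#' the conventional PMF along a strictly increasing CV `xi(x)` with
#' inverse `eta` is
#' \deqn{\tilde A(\zeta) = V(\eta(\zeta)) - \beta^{-1}\log \eta'(\zeta)
#'     = V(x) + \beta^{-1}\log \xi'(x)|_{x=\eta(\zeta)}.}
#' The second (log-derivative) term is what makes the conventional PMF
#' depend on the parameterization of the CV.
#'
#' @param surface a 1D [potential_surface()].
#' @param map a monotone, invertible 1D [cv_map()].
#' @param zeta_grid CV values at which to evaluate the profile.
#' @param beta inverse temperature.
#' @return a [pmf_profile()] with both conventional and invariant values
#'   and the pointwise metric determinant `g = xi'(x)^-2` (so `g0 = 1`
#'   corresponds to unit stretching).
#' @export
conventional_pmf_1d <- function(surface, map, zeta_grid, beta = 1) {
  stopifnot(surface$dim == 1L)
  mm <- check_monotone_1d(map, zeta_grid)
  V <- surface_energy(surface, matrix(mm$x, ncol = 1))
  conv <- V + log(mm$xi_prime) / beta
  pmf_profile(zeta_grid, conventional = conv, invariant = V, beta = beta,
              metric_det = mm$xi_prime^-2, g0 = 1)
}

#' Invariant 1D PMF along a monotone CV
#'
#' The invariant PMF is the potential pulled back through the inverse
#' map, `A(zeta) = V(eta(zeta))`; its projection onto configuration
#' space, `A(xi(x)) = V(x)`, is identical for every monotone CV.
#'
#' @inheritParams conventional_pmf_1d
#' @return a [pmf_profile()] (same content as [conventional_pmf_1d()];
#'   the invariant values are the pulled-back potential).
#' @export
invariant_pmf_1d <- function(surface, map, zeta_grid, beta = 1) {
  conventional_pmf_1d(surface, map, zeta_grid, beta)
}

#' Design a CV that realizes a target conventional PMF
#'
#' Constructs a monotone CV `xi(x)` whose conventional PMF (at
#' `beta = 1`) equals a target profile `Atilde(zeta)`.  The defining
#' relation `Atilde(zeta) = V(eta(zeta)) - log eta'(zeta)` is solved as
#' the equivalent ODE in the configuration variable,
#' \deqn{d\zeta/dx = \exp(\tilde A(\zeta) - V(x)),}
#' integrated outward from `x0` (where `zeta(x0) = zeta0`) with an
#' adaptive solver (lsodar, rel/abs tolerance 1e-8/1e-12).  The
#' x-domain form is numerically benign where the inverse map `eta`
#' diverges: there `zeta(x)` merely saturates, so the tabulation keeps
#' resolution right up to the edge of the realizable CV interval.
#' Integration stops (by root detection) once `zeta` leaves the
#' requested grid (plus a small margin) or `|x - x0|` reaches
#' `eta_max`.  Most targets are realizable only on a finite CV
#' interval — the right-hand side collapses once `V` outgrows the
#' target — and when the requested grid is not fully covered a warning
#' of class `riemcv_domain_truncation` reports the reachable interval.
#'
#' @param target function `zeta -> Atilde(zeta)`, the desired
#'   conventional PMF.
#' @param surface a 1D [potential_surface()].
#' @param zeta0,x0 initial condition `zeta(x0) = zeta0`.
#' @param zeta_grid requested CV grid.
#' @param eta_max half-width of the configuration-space integration
#'   window around `x0`.
#' @return a tabulated [cv_map()] (see [cv_tabulated()]) whose `domain`
#'   attribute records the covered `x` range; attribute `reachable`
#'   records the realized CV interval.
#' @export
design_cv_for_pmf <- function(target, surface, zeta0 = 0, x0 = 0,
                              zeta_grid, eta_max = 8) {
  stopifnot(surface$dim == 1L)
  margin <- 0.02 * diff(range(zeta_grid))
  zlo <- min(zeta_grid) - margin; zhi <- max(zeta_grid) + margin
  rhs <- function(x, y, parms) {
    list(exp(target(y) - surface_energy(surface, matrix(x, ncol = 1))))
  }
  root <- function(x, y, parms) (y[1] - zlo) * (zhi - y[1])
  solve_branch <- function(xs) {
    out <- deSolve::lsodar(y = c(zeta = zeta0), times = c(x0, xs),
                           func = rhs, rootfunc = root,
                           rtol = 1e-8, atol = 1e-12)
    out <- out[-1, , drop = FALSE]  # drop the duplicated x0 row
    out[is.finite(out[, 2]), , drop = FALSE]
  }
  nx <- 2000L
  fw <- solve_branch(seq(x0, x0 + eta_max, length.out = nx + 1)[-1])
  bw <- solve_branch(seq(x0, x0 - eta_max, length.out = nx + 1)[-1])
  x <- c(rev(bw[, 1]), x0, fw[, 1])
  zeta <- c(rev(bw[, 2]), zeta0, fw[, 2])
  # drop saturated tails whose CV increments fall below resolution
  keep_lo <- 1L; keep_hi <- length(x)
  eps <- 1e-12 * diff(range(zeta))
  while (keep_hi - keep_lo > 3 && zeta[keep_lo + 1] - zeta[keep_lo] < eps)
    keep_lo <- keep_lo + 1L
  while (keep_hi - keep_lo > 3 && zeta[keep_hi] - zeta[keep_hi - 1] < eps)
    keep_hi <- keep_hi - 1L
  x <- x[keep_lo:keep_hi]; zeta <- zeta[keep_lo:keep_hi]
  if (length(zeta) < 4 || diff(range(zeta)) < 10 * eps)
    stop_domain(sprintf(
      "CV-design ODE collapses immediately; reachable interval [%g, %g]",
      min(zeta), max(zeta)))
  m <- cv_tabulated(x, zeta, name = "designed_cv")
  attr(m, "reachable") <- range(zeta)
  if (min(zeta) > min(zeta_grid) + 1e-9 || max(zeta) < max(zeta_grid) - 1e-9)
    warning(structure(
      class = c("riemcv_domain_truncation", "warning", "condition"),
      list(message = sprintf(
        "target PMF realizable only on [%g, %g] of the requested grid",
        min(zeta), max(zeta)), call = sys.call(-1))))
  m
}

#' Histogram PMF with metric correction
#'
#' Estimates conventional and invariant PMFs from CV samples.  The
#' conventional estimate is `-log(count / (N * binvolume)) / beta`.  The
#' per-bin metric follows the bin-conditional ensemble average of the CV
#' Jacobian: in 1D, `g^{-1/2} = <sqrt(det(J J^T))>_bin` and
#' `g = <.>^-2`; in d > 1 dimensions the inverse-metric matrix entries
#' `<grad xi_i . grad xi_j>` are averaged per bin and `g` is the inverse
#' of the determinant of that average.  The invariant PMF is then
#' `A = Atilde + log(g/g0) / (2*beta)`.  Empty bins are masked.  Bins
#' are half-open `[lo, hi)` with the rightmost bin closed.
#'
#' @param samples CV samples: numeric vector (1D) or `n x d` matrix.
#' @param jac per-sample Jacobian information: in 1D a numeric vector of
#'   `sqrt(det(J J^T))` (i.e. `|xi'(x)|`); in d dimensions an
#'   `n x d x d` array of the matrices `J J^T`.  Use 1 (or identity
#'   matrices) for an identity CV.
#' @param breaks bin breaks: numeric vector (1D) or list of per-dimension
#'   break vectors.
#' @param beta inverse temperature.
#' @param g0_bin index of the reference bin defining `g0` (default: the
#'   most populated bin); must be non-empty.
#' @return a [pmf_profile()] with counts, per-bin `g`, and mask;
#'   attribute `degenerate` is TRUE when all samples fall in one bin.
#' @export
histogram_pmf <- function(samples, jac = NULL, breaks, beta = 1,
                          g0_bin = NULL) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  n <- nrow(samples); d <- ncol(samples)
  if (n < 1) stop_domain("at least one sample is required")
  if (!is.list(breaks)) breaks <- list(breaks)
  stopifnot(length(breaks) == d)
  if (is.null(jac)) jac <- if (d == 1) rep(1, n) else
    array(diag(d), c(d, d, n))  # filled below if needed
  # per-dimension bin index, half-open [lo, hi), rightmost closed
  idx <- matrix(0L, n, d)
  nb <- integer(d)
  for (j in seq_len(d)) {
    nb[j] <- length(breaks[[j]]) - 1L
    ij <- findInterval(samples[, j], breaks[[j]], rightmost.closed = TRUE)
    ij[ij < 1L | ij > nb[j]] <- NA_integer_
    idx[, j] <- ij
  }
  keep <- stats::complete.cases(idx)
  flat <- rep(1L, n)
  mult <- 1L
  for (j in seq_len(d)) {
    flat <- flat + (idx[, j] - 1L) * mult
    mult <- mult * nb[j]
  }
  flat[!keep] <- NA_integer_
  ntot <- prod(nb)
  counts <- tabulate(flat[keep], nbins = ntot)
  # bin centers and volumes
  centers1 <- lapply(breaks, function(b) (b[-1] + b[-length(b)]) / 2)
  widths1 <- lapply(breaks, diff)
  grid_idx <- as.matrix(expand.grid(lapply(nb, seq_len)))
  centers <- sapply(seq_len(d), function(j) centers1[[j]][grid_idx[, j]])
  if (d == 1) centers <- as.numeric(centers) else centers <- matrix(centers, ncol = d)
  vol <- rep(1, ntot)
  for (j in seq_len(d)) vol <- vol * widths1[[j]][grid_idx[, j]]
  mask <- counts > 0L
  N <- sum(counts)
  conv <- rep(NA_real_, ntot)
  conv[mask] <- -log(counts[mask] / (N * vol[mask])) / beta
  # bin-conditional metric
  gdet <- rep(NA_real_, ntot)
  if (d == 1) {
    js <- as.numeric(jac)
    stopifnot(length(js) == n)
    sums <- rowsum(js[keep], flat[keep])
    gih <- rep(NA_real_, ntot)
    gih[as.integer(rownames(sums))] <- sums[, 1] / counts[as.integer(rownames(sums))]
    gdet <- gih^-2
  } else {
    stopifnot(length(dim(jac)) == 3)
    for (b in which(mask)) {
      sel <- which(flat == b)
      avg <- matrix(0, d, d)
      for (s in sel) avg <- avg + jac[, , s]
      avg <- avg / length(sel)
      gdet[b] <- 1 / det(avg)
    }
  }
  if (is.null(g0_bin)) g0_bin <- which.max(counts)
  if (!mask[g0_bin]) stop_domain("reference bin for g0 is empty")
  g0 <- gdet[g0_bin]
  inv <- conv + log(gdet / g0) / (2 * beta)
  shift <- min(conv[mask])
  prof <- pmf_profile(centers, conv - shift, inv - shift, beta,
                      metric_det = gdet, g0 = g0, mask = mask,
                      counts = counts)
  attr(prof, "degenerate") <- sum(mask) == 1L && n > 1L
  prof
}

#' Write / read a PMF profile as CSV
#'
#' Columns: `bin_index, zeta[1..d], count, A_conventional, A_invariant,
#' g_det, mask`, preceded by `#`-prefixed header lines.
#'
#' @param profile a [pmf_profile()].
#' @param file output path.
#' @param header named character vector of extra header fields.
#' @return `file`, invisibly.
#' @export
write_pmf_csv <- function(profile, file, header = character()) {
  d <- as.data.frame(profile)
  hdr <- c(sprintf("# beta: %s", fmt_num(profile$beta)),
           sprintf("# g0: %s", fmt_num(profile$g0)),
           sprintf("# %s: %s", names(header), header))
  write_table_csv(d, file, hdr)
}

# shared CSV writers with deterministic formatting
write_table_csv <- function(d, file, header_lines = character()) {
  num <- vapply(d, is.double, logical(1))
  for (j in which(num)) d[[j]] <- fmt_num(d[[j]])
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  writeLines(paste(names(d), collapse = ","), con)
  writeLines(do.call(paste, c(unname(d), sep = ",")), con)
  invisible(file)
}

read_table_csv <- function(file) {
  lines <- readLines(file)
  hdr <- grepl("^#", lines)
  d <- utils::read.csv(text = lines[!hdr], stringsAsFactors = FALSE)
  attr(d, "header") <- sub("^# *", "", lines[hdr])
  d
}
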