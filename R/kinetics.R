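#' Mean first passage time results
#'
#' @param tau MFPT (time units).
#' @param method `"quadrature"` or `"matrix"`.
#' @param endpoints integer bin indices (A, B) or parameter values.
#' @param provenance free-form provenance string.
#' @return an object of class `mfpt_result` with `tau` and
#'   `rate = 1/tau`.
#' @keywords internal
mfpt_result <- function(tau, method, endpoints, provenance = "") {
  if (!is.finite(tau) || tau <= 0) stop_domain("MFPT must be positive and finite")
  structure(list(tau = tau, rate = 1 / tau, method = method,
                 endpoints = endpoints, provenance = provenance),
            class = "mfpt_result")
}

#' @export
print.mfpt_result <- function(x, ...) {
  cat("<mfpt_result> tau = ", fmt_num(x$tau), " (rate ", fmt_num(x$rate),
      ") by ", x$method, "\n", sep = "")
  invisible(x)
}

#' MFPT by the closed-form double quadrature
#'
#' The mean first passage time of 1D diffusion from a reflective
#' boundary at `r_A` to an absorbing target at `r_B`, with free energy
#' `G(r)` and metric `h(r)` along the path:
#' \deqn{\tau_{A\to B} = \frac{1}{D}\int_{r_A}^{r_B}\! d\rho\,
#'   \sqrt{h(\rho)}\, e^{\beta G(\rho)} \int_{r_A}^{\rho}\! d\sigma\,
#'   \sqrt{h(\sigma)}\, e^{-\beta G(\sigma)}.}
#' The metric enters as `sqrt(h)` in each integral (the metric arc
#' element), so rescaling `h -> c^2 h` rescales `tau -> c^2 tau`.
#' Both integrals use the trapezoid rule on a uniform grid; exponents
#' are shifted by the extreme values of `beta*G` so that barriers of
#' tens of kBT do not overflow.
#'
#' @param G free energy: function of `r`, or vector on the grid.
#' @param h metric: function of `r`, or vector on the grid (default 1).
#' @param beta inverse temperature.
#' @param D diffusion constant.
#' @param r_A,r_B reflective start and absorbing target (`r_A < r_B`).
#' @param grid number of grid points (>= 4) when `G` is a function;
#'   when `G` is a vector its length defines the grid.
#' @return an [mfpt_result] with `method = "quadrature"`.
#' @export
mfpt_quadrature <- function(G, h = NULL, beta, D, r_A = 0, r_B = 1,
                            grid = 2000L) {
  stopifnot(r_A < r_B)
  if (is.function(G)) {
    if (grid < 4) stop_domain("quadrature grid must have at least 4 points")
    r <- seq(r_A, r_B, length.out = grid)
    Gv <- G(r)
    hv <- if (is.null(h)) rep(1, grid) else if (is.function(h)) h(r) else h
  } else {
    Gv <- G
    if (length(Gv) < 4) stop_domain("quadrature grid must have at least 4 points")
    r <- seq(r_A, r_B, length.out = length(Gv))
    hv <- if (is.null(h)) rep(1, length(Gv)) else h
  }
  if (any(!is.finite(Gv)) || any(!is.finite(hv)) || any(hv <= 0))
    stop_domain("non-finite integrand in MFPT quadrature")
  bG <- beta * Gv
  lo <- min(bG); hi <- max(bG)
  sq <- sqrt(hv)
  inner <- cumtrapz(r, sq * exp(-(bG - lo)))      # scaled by e^{lo}
  outerint <- trapz(r, sq * exp(bG - hi) * inner) # scaled by e^{-hi}
  tau <- outerint * exp(hi - lo) / D
  mfpt_result(tau, "quadrature", c(r_A, r_B))
}

#' MFPT by absorbing-boundary linear solve on the rate matrix
#'
#' Makes `bin_B` absorbing and solves the standard first-passage linear
#' system for the mean absorption times: with the generator `R` acting
#' on probabilities (`R[n,m]` the rate `m -> n`), the hitting times
#' satisfy `t(R) tau = -1` on the non-absorbing bins with
#' `tau[bin_B] = 0`.  Used to cross-validate [mfpt_quadrature()] on the
#' same discretization.
#'
#' @param model a `rate_model`.
#' @param bin_A starting bin (1-based).
#' @param bin_B absorbing bin, different from `bin_A`.
#' @return an [mfpt_result] with `method = "matrix"`.
#' @export
mfpt_matrix <- function(model, bin_A, bin_B) {
  N <- model$n_bins
  stopifnot(bin_A %in% seq_len(N), bin_B %in% seq_len(N), bin_A != bin_B)
  Rup <- model$R[cbind(seq_len(N - 1), 2:N)]
  Rdn <- model$R[cbind(2:N, seq_len(N - 1))]
  lo <- min(bin_A, bin_B); hi <- max(bin_A, bin_B)
  if (any(Rup[lo:(hi - 1)] <= 0) || any(Rdn[lo:(hi - 1)] <= 0))
    stop_domain("chain is disconnected between the requested bins")
  gen <- t(model$R)[-bin_B, -bin_B, drop = FALSE]
  tau <- try(solve(gen, rep(-1, N - 1)), silent = TRUE)
  if (inherits(tau, "try-error"))
    stop_domain("singular first-passage system: chain is disconnected")
  idx <- if (bin_A < bin_B) bin_A else bin_A - 1L
  mfpt_result(tau[idx], "matrix", c(bin_A, bin_B))
}
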