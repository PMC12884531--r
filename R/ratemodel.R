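#' Metric-generalized tridiagonal rate matrix
#'
#' Builds the nearest-neighbor generator of the discretized 1D
#' Smoluchowski equation along a path with free energy `G(r)` and
#' metric `h(r)`.  The generator acts on probability column vectors,
#' `dU/dt = R U`, with `R[n, m]` the rate from bin `m` into bin `n`;
#' every column sums to zero and the boundaries are reflective (no rate
#' off the ends of the grid).
#'
#' Scheme `"riemannian"` is the finite-volume discretization of the
#' metric Smoluchowski equation (density per unit `r`, stationary
#' distribution proportional to `sqrt(h) exp(-beta G)`):
#' \deqn{R_{n,n\pm1} = \frac{D}{\delta r^2\sqrt{h_{n\pm1}\,h_{n\pm1/2}}}
#'   \exp\!\big({-\tfrac{\beta}{2}(G_n - G_{n\pm1})}\big)}
#' i.e. the inverse metric factor couples the midpoint to the *source*
#' node; equivalently `R = D/(delta_s_src * delta_s_mid) * exp(...)`
#' with `delta_s = sqrt(h) delta_r`.  This placement is the unique one
#' for which the matrix mean first passage times converge to the
#' closed-form double quadrature and the free-energy/metric recovery
#' ([profiles_from_rates()]) is an exact inverse.
#'
#' Scheme `"midpointD"` is the conventional position-dependent-diffusion
#' form `R_{n,m} = (D_n + D_m) / (2 delta_r^2) * exp(-beta (G_n - G_m)/2)`
#' for `|n - m| = 1`, with per-node diffusion constants `D_nodes` and
#' `h` identically 1; with constant `D_nodes` it coincides exactly with
#' the riemannian scheme at `h = 1`.
#'
#' @param path optional [discretized_path()] providing `h_nodes`,
#'   `h_mid` and `delta_r`.
#' @param G free energy at the nodes (energy units).
#' @param D diffusion constant.
#' @param beta inverse temperature.
#' @param scheme `"riemannian"` or `"midpointD"`.
#' @param D_nodes per-node diffusion constants (midpointD scheme).
#' @param h_nodes,h_mid,delta_r metric and spacing when no path is
#'   given; `h_mid` defaults to the inverse-square-root interpolation.
#' @return an object of class `rate_model`: list with the generator `R`
#'   and all construction inputs.
#' @export
build_rate_matrix <- function(path = NULL, G, D, beta,
                              scheme = c("riemannian", "midpointD"),
                              D_nodes = NULL, h_nodes = NULL,
                              h_mid = NULL, delta_r = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(path)) {
    h_nodes <- path$h_nodes; h_mid <- path$h_mid; delta_r <- path$delta_r
  }
  N <- length(G)
  if (is.null(h_nodes)) h_nodes <- rep(1, N)
  if (is.null(delta_r)) stop_domain("delta_r is required")
  if (!all(is.finite(G)) || !all(is.finite(h_nodes)))
    stop_domain("G and h must be finite")
  if (any(h_nodes <= 0)) stop_degenerate("h must be positive")
  if (is.null(h_mid)) h_mid <- interp_h_mid(h_nodes)
  if (any(h_mid <= 0)) stop_degenerate("h must be positive")
  if (length(h_nodes) != N || length(h_mid) != N - 1)
    stop_domain("mismatched lengths of G and h")
  stopifnot(delta_r > 0, N >= 2)
  up_exp <- exp(-beta * (G[-N] - G[-1]) / 2)   # factor in R[n, n+1]
  dn_exp <- exp(-beta * (G[-1] - G[-N]) / 2)   # factor in R[n+1, n]
  if (scheme == "riemannian") {
    Rup <- D / (delta_r^2 * sqrt(h_nodes[-1] * h_mid)) * up_exp
    Rdn <- D / (delta_r^2 * sqrt(h_nodes[-N] * h_mid)) * dn_exp
  } else {
    if (is.null(D_nodes)) D_nodes <- rep(D, N)
    stopifnot(length(D_nodes) == N)
    Dm <- (D_nodes[-N] + D_nodes[-1]) / 2
    Rup <- Dm / delta_r^2 * up_exp
    Rdn <- Dm / delta_r^2 * dn_exp
  }
  R <- matrix(0, N, N)
  R[cbind(seq_len(N - 1), seq_len(N - 1) + 1L)] <- Rup
  R[cbind(seq_len(N - 1) + 1L, seq_len(N - 1))] <- Rdn
  diag(R) <- -colSums(R)
  structure(list(n_bins = N, R = R, G = G, h_nodes = h_nodes,
                 h_mid = h_mid, D = D, D_nodes = D_nodes, beta = beta,
                 delta_r = delta_r, scheme = scheme),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("<rate_model> ", x$n_bins, " bins (", x$scheme, "), D = ", x$D,
      ", beta = ", x$beta, "\n", sep = "")
  invisible(x)
}

#' Conventional (position-dependent D) inputs for the riemannian builder
#'
#' The conventional bookkeeping describes the same 1D dynamics with a
#' position-dependent diffusion profile `D(r)` and a conventional free
#' energy `A(r)`; the geometric information of the metric is implicit in
#' `D(r)`.  This constructor converts those inputs exactly to the
#' invariant pair — `h = D / D(r)` and
#' `G = A + (d/2) beta^{-1} log h` with `d = cv_dim` the dimension of
#' the ambient CV space whose (conformal) metric determinant `h^d`
#' entered the conventional PMF — and then calls [build_rate_matrix()]
#' with the riemannian scheme.  By construction the resulting generator
#' is *entrywise identical* to the one built directly from
#' `(G, h, D)`: the two analyses are the same model in different
#' bookkeeping.
#'
#' @param path a [discretized_path()] (its `h` fields are replaced by
#'   the converted ones).
#' @param A conventional free energy at the nodes.
#' @param D_nodes position-dependent diffusion profile `D(r)` at the
#'   nodes.
#' @param beta inverse temperature.
#' @param D reference (constant) diffusion coefficient of the
#'   equivalent riemannian model.
#' @param cv_dim dimension of the ambient CV space (2 for a conformal
#'   2D metric such as the log-polar plane).
#' @return a `rate_model` (riemannian scheme) with attribute
#'   `conventional` recording the original inputs.
#' @export
build_rate_matrix_conventional <- function(path, A, D_nodes, beta, D,
                                           cv_dim = 2) {
  if (any(D_nodes <= 0)) stop_degenerate("D(r) must be positive")
  h <- D / D_nodes
  G <- A + (cv_dim / 2) * log(h) / beta
  m <- build_rate_matrix(G = G, D = D, beta = beta, scheme = "riemannian",
                         h_nodes = h, h_mid = interp_h_mid(h),
                         delta_r = path$delta_r)
  attr(m, "conventional") <- list(A = A, D_nodes = D_nodes, cv_dim = cv_dim)
  m
}

# spectral decomposition of the generator via detailed-balance
# symmetrization: R = S_d %*% Sym %*% S_d^-1 with S_d = diag(s),
# s = sqrt(stationary).  Exact for the tridiagonal models built here.
rate_spectral <- function(model) {
  R <- model$R; N <- model$n_bins
  Rup <- R[cbind(seq_len(N - 1), 2:N)]
  Rdn <- R[cbind(2:N, seq_len(N - 1))]
  if (any(Rup <= 0) || any(Rdn <= 0))
    stop_domain("zero off-diagonal rate: chain is disconnected")
  logpi <- c(0, cumsum(log(Rdn / Rup)))
  logpi <- logpi - max(logpi)
  s <- exp(logpi / 2)
  S <- R * outer(1 / s, s)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(s = s, values = e$values, vectors = e$vectors)
}

#' Lag-time propagator of a rate model
#'
#' `P = exp(R * dt_lag)`, computed through the symmetric spectral
#' decomposition that detailed balance guarantees for these tridiagonal
#' generators.  The result is column-stochastic: `P[j, i]` is the
#' probability of being in bin `j` a lag `dt_lag` after being in bin
#' `i`.
#'
#' @param model a `rate_model`.
#' @param dt_lag lag time (>= 0).
#' @return `n_bins x n_bins` column-stochastic matrix.
#' @export
propagate <- function(model, dt_lag) {
  stopifnot(dt_lag >= 0)
  N <- model$n_bins
  if (dt_lag == 0 || all(model$R == 0)) return(diag(N))
  sp <- rate_spectral(model)
  lam <- sp$values * dt_lag
  if (max(lam) > 700)
    stop_domain("propagator overflow: rescale rates or reduce the lag")
  P <- (sp$vectors %*% (exp(lam) * t(sp$vectors))) * outer(sp$s, 1 / sp$s)
  cs <- colSums(P)
  if (max(abs(cs - 1)) > 1e-8)
    stop_domain("propagator is not column-stochastic; the generator is ill-conditioned")
  P / rep(cs, each = N)  # remove residual roundoff so columns sum to 1
}

#' Log-likelihood of lagged transition counts under a rate model
#'
#' The likelihood of independent observations `i -> j` at lag `dt` is
#' the product of propagator elements, so
#' `log L = sum_{i,j} C[j,i] * log P[j,i]` with `P = exp(R * lag)`.
#' Returns `-Inf` (with attribute `zero_probability = TRUE`) when an
#' observed transition has probability zero.
#'
#' @param model a `rate_model`.
#' @param counts a `transition_counts` (see [harvest_transitions()]).
#' @return scalar log-likelihood (<= 0).
#' @export
log_likelihood <- function(model, counts) {
  stopifnot(inherits(counts, "transition_counts"))
  if (counts$n_bins != model$n_bins)
    stop_domain("counts refer to a different number of bins")
  if (counts$lag <= 0) stop_domain("counts must carry a positive lag")
  P <- propagate(model, counts$lag)
  C <- counts$counts
  idx <- C > 0
  if (any(P[idx] <= 0)) {
    out <- -Inf
    attr(out, "zero_probability") <- TRUE
    return(out)
  }
  sum(C[idx] * log(P[idx]))
}

# Loewner matrix of divided differences of exp(lam*t), stable near
# coincident eigenvalues
phi_divided <- function(lam, t) {
  n <- length(lam)
  Li <- matrix(lam * t, n, n)
  Lj <- t(Li)
  dd <- Li - Lj
  small <- abs(dd) < 1e-8
  F <- matrix(0, n, n)
  F[!small] <- (exp(Li[!small]) - exp(Lj[!small])) / dd[!small]
  F[small] <- exp((Li[small] + Lj[small]) / 2) * (1 + dd[small]^2 / 24)
  t * F
}

# log-likelihood and its analytic gradient wrt (G[2..N], log h[1..N])
# for a riemannian-scheme model; gradient via the spectral Frechet
# derivative of the matrix exponential.  lambda_h adds a smoothness
# penalty -lambda_h * sum(diff(log h)^2): with D fixed, the inversion
# R -> (G, h) has a soft direction broken only by the midpoint
# interpolation closure, so the rough component of log h is nearly
# unidentifiable from counts alone and benefits from a smoothness prior
loglik_with_grad <- function(G, u, D, beta, delta_r, counts,
                             lambda_h = 0) {
  N <- length(G)
  h <- exp(u)
  model <- build_rate_matrix(G = G, D = D, beta = beta,
                             h_nodes = h, h_mid = interp_h_mid(h),
                             delta_r = delta_r)
  sp <- rate_spectral(model)
  tlag <- counts$lag
  lam <- sp$values
  expl <- exp(lam * tlag)
  V <- sp$vectors
  P <- (V %*% (expl * t(V))) * outer(sp$s, 1 / sp$s)
  C <- counts$counts
  idx <- C > 0
  if (any(P[idx] <= 0)) return(list(value = -Inf, grad = NULL))
  ll <- sum(C[idx] * log(P[idx]))
  W <- matrix(0, N, N)
  W[idx] <- C[idx] / P[idx]
  # dP = Q (F o (Qinv dR Q)) Qinv with Q = diag(s) V
  Q <- sp$s * V
  Qinv <- t(V) * rep(1 / sp$s, each = N)
  F <- phi_divided(lam, tlag)
  Z <- (t(Q) %*% W %*% t(Qinv)) * F
  K <- t(Qinv) %*% Z %*% t(Q)     # grad = sum K[p,q] dR[p,q]
  iu <- cbind(seq_len(N - 1), 2:N)
  idn <- cbind(2:N, seq_len(N - 1))
  Rup <- model$R[iu]; Rdn <- model$R[idn]
  cup <- Rup * (K[iu] - K[cbind(2:N, 2:N)])
  cdn <- Rdn * (K[idn] - K[cbind(seq_len(N - 1), seq_len(N - 1))])
  # G derivatives: d log Rup_n = beta/2 * (dG_{n+1} - dG_n); Rdn opposite
  gG <- numeric(N)
  bonds <- seq_len(N - 1)
  gG[bonds] <- gG[bonds] + (-beta / 2) * cup + (beta / 2) * cdn
  gG[bonds + 1] <- gG[bonds + 1] + (beta / 2) * cup + (-beta / 2) * cdn
  # log h derivatives
  a <- 1 / sqrt(h)
  wlo <- a[-N] / (a[-N] + a[-1])   # weight of node n in the midpoint
  whi <- a[-1] / (a[-N] + a[-1])
  gU <- numeric(N)
  gU[bonds] <- gU[bonds] + cup * (-wlo / 2) + cdn * (-1 / 2 - wlo / 2)
  gU[bonds + 1] <- gU[bonds + 1] + cup * (-1 / 2 - whi / 2) + cdn * (-whi / 2)
  if (lambda_h > 0) {
    du <- diff(u)
    ll <- ll - lambda_h * sum(du^2)
    gU[bonds] <- gU[bonds] + 2 * lambda_h * du
    gU[bonds + 1] <- gU[bonds + 1] - 2 * lambda_h * du
  }
  list(value = ll, grad = c(gG[-1], gU), model = model)
}

#' Maximum-likelihood estimation of free energy and metric profiles
#'
#' Maximizes the transition likelihood of [log_likelihood()] over the
#' node free energies `G` and log metric values `log h` of a
#' riemannian-scheme rate model, with gauges `G[1] = 0` and `D` fixed
#' (the metric carries the scale).  Optimization uses L-BFGS-B with the
#' analytic likelihood gradient (spectral Frechet derivative of the
#' matrix exponential).  `G` is initialized from the empirical
#' stationary counts, `h` from 1.  The fit is deterministic given the
#' data and options.
#'
#' @param counts a `transition_counts` with a positive lag.
#' @param path a [discretized_path()] with matching bin count (supplies
#'   `delta_r`).
#' @param beta inverse temperature.
#' @param D fixed diffusion constant.
#' @param options list: `max_iter` (default 1000), `factr` (L-BFGS-B
#'   tolerance, default 1e7), `init` (optional list with `G`, `log_h`),
#'   `lambda_h` (default 0): weight of a smoothness penalty
#'   `lambda_h * sum(diff(log h)^2)` subtracted from the log-likelihood.
#'   With `D` fixed, the decomposition of rates into (G, h) has a soft
#'   direction that the data constrain only weakly, so the rough
#'   component of `log h` is noisy at realistic sample sizes; a weight
#'   around `1/(2*s^2)` encodes a prior per-bond variation of `s` in
#'   `log h` (e.g. 100 for ~7% variation) and suppresses that noise
#'   without biasing smooth profiles.
#' @return an object of class `fit_result`: list with `model` (the
#'   maximizing `rate_model`), `loglik`, `n_obs`, `convergence`
#'   (iterations, message, gradient norm) and `unidentifiable`
#'   (indices of bins never visited by the data, whose parameters are
#'   not constrained).
#' @export
fit_rate_model <- function(counts, path, beta, D, options = list()) {
  N <- counts$n_bins
  if (!is.null(path) && nrow(path$centers) != N)
    stop_domain("path and counts disagree on the number of bins")
  if (sum(counts$counts) == 0) stop_domain("empty transition counts")
  delta_r <- path$delta_r
  max_iter <- options$max_iter %||% 1000L
  factr <- options$factr %||% 1e7
  lambda_h <- options$lambda_h %||% 0
  visits <- colSums(counts$counts) + rowSums(counts$counts)
  unident <- which(visits == 0)
  pops <- pmax(colSums(counts$counts), 0.5)
  G0 <- -log(pops / max(pops)) / beta
  if (!is.null(options$init)) {
    G0 <- options$init$G %||% G0
    u0 <- options$init$log_h %||% rep(0, N)
  } else u0 <- rep(0, N)
  th0 <- c(G0[-1] - G0[1], u0)
  unpack <- function(th) list(G = c(0, th[seq_len(N - 1)]),
                              u = th[N:(2 * N - 1)])
  fn <- function(th) {
    p <- unpack(th)
    v <- loglik_with_grad(p$G, p$u, D, beta, delta_r, counts, lambda_h)$value
    if (!is.finite(v)) 1e12 else -v  # keep L-BFGS-B alive off-support
  }
  gr <- function(th) {
    p <- unpack(th)
    g <- loglik_with_grad(p$G, p$u, D, beta, delta_r, counts, lambda_h)$grad
    if (is.null(g)) numeric(length(th)) else -g
  }
  opt <- stats::optim(th0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = factr))
  if (opt$convergence == 1L)
    stop_domain(paste0("likelihood fit did not converge in ", max_iter,
                       " iterations"))
  p <- unpack(opt$par)
  final <- loglik_with_grad(p$G, p$u, D, beta, delta_r, counts, lambda_h)
  structure(list(model = final$model, loglik = final$value,
                 n_obs = sum(counts$counts),
                 convergence = list(iterations = opt$counts[["function"]],
                                    code = opt$convergence,
                                    message = opt$message,
                                    grad_norm = sqrt(sum(final$grad^2))),
                 unidentifiable = unident),
            class = "fit_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> logL = ", fmt_num(x$loglik), " from ", x$n_obs,
      " observations (", x$convergence$iterations, " evaluations)\n",
      sep = "")
  invisible(x)
}

#' Recover free energy and metric profiles from a rate matrix
#'
#' Inverts the riemannian-scheme construction of [build_rate_matrix()].
#' From detailed balance the free-energy differences follow from rate
#' ratios (`Delta G = -kBT log(R_up/R_dn)` up to the metric term), and
#' the midpoint metric follows from rate products:
#' \deqn{h_{n+1/2} = \frac{D^2}{\delta r^4\,\sqrt{h_n h_{n+1}}\,
#'    R_{n,n+1} R_{n+1,n}}.}
#'
#' Mode `"pairwise"` iterates this relation to self-consistency: node
#' values are re-interpolated from midpoints (inverse-square-root
#' average) and midpoints re-evaluated until the node metric changes by
#' less than `tol` (relative); `G` is then accumulated from the rate
#' ratios using the converged metric.  Accuracy is limited by the
#' node-from-midpoint interpolation, second order in the per-bond
#' variation of `log h`.
#'
#' Mode `"joint"` solves the exact inverse problem by marching along
#' the chain: given `h[1] = h0` (the scale gauge; with `D` fixed the
#' inversion has exactly a one-parameter family of solutions indexed by
#' `h0`), each bond's rate product determines `h[n+1]` through a
#' monotone scalar equation solved by safeguarded Newton, and the rate
#' ratio then fixes `G[n+1]`.  Rebuilding a rate matrix from the joint
#' profiles reproduces the input entrywise to machine accuracy.
#'
#' @param model a `rate_model`, or a raw square generator matrix.
#' @param beta,D,delta_r model parameters (taken from `model` when it
#'   is a `rate_model`).
#' @param mode `"joint"` (exact inverse) or `"pairwise"` (Eq.-by-Eq.
#'   fixed point).
#' @param h0 scale gauge: value assigned to `h[1]` (joint mode).
#' @param tol relative convergence tolerance of the pairwise fixed
#'   point.
#' @param max_iter pairwise iteration cap.
#' @return list with `G` (gauge `G[1] = 0`), `h_nodes`, `h_mid`,
#'   `mode`, and `db_residual`, the per-bond residual of the constant-h
#'   detailed-balance relation `log(R_up/R_dn) - beta*(G[n+1]-G[n])`
#'   (equal to `log(h_n/h_{n+1})/2`; zero only for constant metric).
#' @export
profiles_from_rates <- function(model, beta = NULL, D = NULL,
                                delta_r = NULL,
                                mode = c("joint", "pairwise"),
                                h0 = 1, tol = 1e-10, max_iter = 10000L) {
  mode <- match.arg(mode)
  if (inherits(model, "rate_model")) {
    R <- model$R
    beta <- beta %||% model$beta
    D <- D %||% model$D
    delta_r <- delta_r %||% model$delta_r
  } else R <- model
  if (is.null(beta) || is.null(D) || is.null(delta_r))
    stop_domain("beta, D and delta_r are required with a raw matrix")
  N <- nrow(R)
  iu <- cbind(seq_len(N - 1), 2:N)
  idn <- cbind(2:N, seq_len(N - 1))
  Rup <- R[iu]; Rdn <- R[idn]
  if (any(Rup <= 0) || any(Rdn <= 0))
    stop_domain("all nearest-neighbor rates must be strictly positive")
  lp <- log(Rup * Rdn)          # product equation per bond
  lr <- log(Rup / Rdn)          # ratio equation per bond
  c0 <- 2 * log(D) - 4 * log(delta_r)
  if (mode == "pairwise") {
    # node values from midpoints: interior inverse-sqrt average,
    # second-order linear extrapolation at the two ends
    nodes_from_mids <- function(a_mid) {
      if (N == 2) return(c(a_mid[1], a_mid[1]))
      lo <- max(1.5 * a_mid[1] - 0.5 * a_mid[2], 0.5 * a_mid[1])
      hi <- max(1.5 * a_mid[N - 1] - 0.5 * a_mid[N - 2], 0.5 * a_mid[N - 1])
      c(lo, (a_mid[-1] + a_mid[-(N - 1)]) / 2, hi)
    }
    # slowly-varying initialization: h^2 = D^2/(dr^4 Rup Rdn)
    h_bond <- exp((c0 - lp) / 2)
    a_nodes <- nodes_from_mids(1 / sqrt(h_bond))
    for (k in seq_len(max_iter)) {
      h_nodes <- a_nodes^-2
      # exact product relation given current nodes
      h_mid <- exp(c0 - lp) / sqrt(h_nodes[-N] * h_nodes[-1])
      a_new <- nodes_from_mids(1 / sqrt(h_mid))
      delta <- max(abs(a_new - a_nodes) / a_nodes)
      a_nodes <- a_new
      if (delta < tol) break
    }
    h_nodes <- a_nodes^-2
    h_mid <- exp(c0 - lp) / sqrt(h_nodes[-N] * h_nodes[-1])
  } else {
    h_nodes <- numeric(N); h_nodes[1] <- h0
    for (n in seq_len(N - 1)) {
      an <- 1 / sqrt(h_nodes[n])
      rhs <- c0 - lp[n] - log(h_nodes[n]) / 2
      # solve x = log h_{n+1}:  x/2 + log h_mid(x) = rhs,
      #   log h_mid = -2 log((an + e^{-x/2})/2); monotone in x
      f <- function(x) x / 2 - 2 * log((an + exp(-x / 2)) / 2) - rhs
      x <- log(h_nodes[n])
      for (k in 1:100) {
        ax <- exp(-x / 2)
        fx <- x / 2 - 2 * log((an + ax) / 2) - rhs
        dfx <- 1 / 2 + ax / (2 * (an + ax))
        step <- fx / dfx
        x <- x - step
        if (abs(step) < 1e-14) break
      }
      if (!is.finite(x))
        stop_domain(paste0("joint inversion failed at bond ", n))
      h_nodes[n + 1] <- exp(x)
    }
    h_mid <- exp(c0 - lp) / sqrt(h_nodes[-N] * h_nodes[-1])
  }
  # exact ratio identity: log(Rup/Rdn) = beta dG + log(h_n/h_{n+1})/2
  dG <- (lr - log(h_nodes[-N] / h_nodes[-1]) / 2) / beta
  G <- c(0, cumsum(dG))
  list(G = G, h_nodes = h_nodes, h_mid = h_mid, mode = mode,
       db_residual = lr - beta * dG)
}

#' Metropolis sampling of the rate-model posterior
#'
#' Optional Bayesian companion to [fit_rate_model()]: random-walk
#' Metropolis over `(G[2..N], log h[1..N])` with flat priors, so the
#' posterior is proportional to the transition likelihood.  Reports
#' posterior means and central credible intervals.
#'
#' @param counts a `transition_counts`.
#' @param path a [discretized_path()].
#' @param beta,D model parameters (gauges as in [fit_rate_model()]).
#' @param n_iter number of Metropolis sweeps.
#' @param step proposal standard deviation.
#' @param seed RNG seed.
#' @param init optional starting parameter vector (defaults to the MLE).
#' @return list with `G_mean`, `log_h_mean`, `G_ci`, `log_h_ci` (95%),
#'   `acceptance`, and the raw `samples` matrix.
#' @export
sample_rate_posterior <- function(counts, path, beta, D, n_iter = 2000L,
                                  step = 0.05, seed = 1L, init = NULL) {
  N <- counts$n_bins
  delta_r <- path$delta_r
  if (is.null(init)) {
    fit <- fit_rate_model(counts, path, beta, D)
    init <- c(fit$model$G[-1], log(fit$model$h_nodes))
  }
  ll <- function(th) {
    G <- c(0, th[seq_len(N - 1)]); u <- th[N:(2 * N - 1)]
    loglik_with_grad(G, u, D, beta, delta_r, counts)$value
  }
  set.seed(seed)
  th <- init; cur <- ll(th)
  samples <- matrix(NA_real_, n_iter, length(th))
  acc <- 0L
  for (k in seq_len(n_iter)) {
    prop <- th + stats::rnorm(length(th), sd = step)
    lp <- ll(prop)
    if (is.finite(lp) && log(stats::runif(1)) < lp - cur) {
      th <- prop; cur <- lp; acc <- acc + 1L
    }
    samples[k, ] <- th
  }
  keep <- samples[-seq_len(n_iter %/% 4), , drop = FALSE]  # burn-in
  qs <- apply(keep, 2, stats::quantile, probs = c(0.025, 0.975))
  mu <- colMeans(keep)
  list(G_mean = c(0, mu[seq_len(N - 1)]),
       log_h_mean = mu[N:(2 * N - 1)],
       G_ci = cbind(0, qs[, seq_len(N - 1), drop = FALSE]),
       log_h_ci = qs[, N:(2 * N - 1), drop = FALSE],
       acceptance = acc / n_iter, samples = samples)
}

#' Rate matrix and profile file I/O
#'
#' Rate matrices are CSV triplets `(n, m, R_nm)` (1-based, nonzero
#' entries); profiles are CSV with columns
#' `bin, r, G, h_node, h_mid, D_eff` where `D_eff = D / h_node`.
#'
#' @param model a `rate_model`.
#' @param file path.
#' @return the path, invisibly.
#' @export
write_rate_csv <- function(model, file) {
  nz <- which(model$R != 0, arr.ind = TRUE)
  d <- data.frame(n = nz[, 1], m = nz[, 2], R_nm = model$R[nz])
  d <- d[order(d$n, d$m), , drop = FALSE]
  hdr <- sprintf("# %s: %s", c("n_bins", "D", "beta", "delta_r", "scheme"),
                 c(model$n_bins, fmt_num(model$D), fmt_num(model$beta),
                   fmt_num(model$delta_r), model$scheme))
  write_table_csv(d, file, hdr)
}

#' @rdname write_rate_csv
#' @param path a [discretized_path()] aligned with the model.
#' @export
write_profile_csv <- function(model, path, file) {
  N <- model$n_bins
  d <- data.frame(bin = seq_len(N) - 1L, r = path$r, G = model$G,
                  h_node = model$h_nodes,
                  h_mid = c(model$h_mid, NA_real_),
                  D_eff = model$D / model$h_nodes)
  hdr <- sprintf("# %s: %s", c("n_bins", "D", "beta", "delta_r"),
                 c(N, fmt_num(model$D), fmt_num(model$beta),
                   fmt_num(model$delta_r)))
  write_table_csv(d, file, hdr)
}
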