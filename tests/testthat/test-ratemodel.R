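test_that("two-bin flat model is the symmetric hop generator", {
  m <- build_rate_matrix(G = c(0, 0), D = 1, beta = 1,
                         h_nodes = c(1, 1), delta_r = 1)
  expect_equal(m$R, rbind(c(-1, 1), c(1, -1)))
})

test_that("generator structure: zero column sums, reflective ends, db ratios", {
  m <- random_smooth_model()
  expect_lt(max(abs(colSums(m$R))), 1e-12)
  N <- m$n_bins
  expect_true(all(m$R[cbind(1:(N - 1), 2:N)] > 0))
  expect_true(all(abs(m$R[abs(row(m$R) - col(m$R)) > 1]) == 0))
  # with h = 1 the rate ratios recover free-energy differences exactly
  mc <- build_rate_matrix(G = c(0, 1, 0.5), D = 1, beta = 2,
                          h_nodes = rep(1, 3), delta_r = 0.5)
  up <- mc$R[cbind(1:2, 2:3)]; dn <- mc$R[cbind(2:3, 1:2)]
  expect_equal(log(up / dn) / 2, diff(c(0, 1, 0.5)), tolerance = 1e-14)
  # printed detailed balance R_nm exp(-beta G_m) = R_mn exp(-beta G_n)
  expect_equal(up * exp(-2 * c(1, 0.5)), dn * exp(-2 * c(0, 1)),
               tolerance = 1e-14)
  expect_error(build_rate_matrix(G = c(0, 1), D = 1, beta = 1,
                                 h_nodes = c(1, -1), delta_r = 1),
               class = "riemcv_degenerate_metric")
  expect_error(build_rate_matrix(G = c(0, 1, 2), D = 1, beta = 1,
                                 h_nodes = c(1, 1), delta_r = 1),
               class = "riemcv_domain_error")
})

test_that("midpointD scheme with constant D coincides with the riemannian scheme", {
  G <- c(0, 0.7, 0.2, -0.4)
  a <- build_rate_matrix(G = G, D = 1.3, beta = 0.8, h_nodes = rep(1, 4),
                         delta_r = 0.25)
  b <- build_rate_matrix(G = G, D = 1.3, beta = 0.8, scheme = "midpointD",
                         D_nodes = rep(1.3, 4), delta_r = 0.25)
  expect_equal(a$R, b$R, tolerance = 1e-15)
})

test_that("conventional bookkeeping builds an identical generator", {
  # position-dependent D(r) = D/h with the matching conventional free
  # energy is the same model as constant D with metric h
  n <- 30
  r <- seq(0, 1, length.out = n)
  X <- 0.4 * sin(2 * pi * r)
  h <- exp(2 * X)
  V <- cos(2 * pi * r)
  path <- discretized_path(matrix(r, ncol = 1), h_nodes = h)
  beta <- 1 / 0.596
  direct <- build_rate_matrix(path, G = V, D = 0.596, beta = beta)
  conv <- build_rate_matrix_conventional(
    path, A = V - 2 * 0.596 * X, D_nodes = 0.596 * exp(-2 * X),
    beta = beta, D = 0.596, cv_dim = 2)
  expect_equal(conv$R, direct$R, tolerance = 1e-12)
  expect_equal(conv$G, direct$G, tolerance = 1e-12)
  # identical propagators and MFPTs follow entrywise
  expect_equal(propagate(conv, 0.01), propagate(direct, 0.01),
               tolerance = 1e-12)
  expect_equal(mfpt_matrix(conv, 1, n)$tau, mfpt_matrix(direct, 1, n)$tau,
               tolerance = 1e-12)
})

test_that("propagator is the matrix exponential of the generator", {
  m <- build_rate_matrix(G = c(0, 0), D = 1, beta = 1, h_nodes = c(1, 1),
                         delta_r = 1)  # symmetric 2-state, hop rate k = 1
  expect_equal(propagate(m, 0), diag(2))
  for (t in c(0.1, 0.5, 2)) {
    P <- propagate(m, t)
    expect_equal(P[1, 1], (1 + exp(-2 * t)) / 2, tolerance = 1e-12)
    expect_equal(colSums(P), c(1, 1), tolerance = 1e-10)
  }
  # long-time limit: every column approaches the stationary vector
  ms <- random_smooth_model(n = 12)
  Pinf <- propagate(ms, 50 / max(abs(diag(ms$R))) * ms$n_bins)
  expect_lt(max(abs(Pinf - Pinf[, 1])), 1e-10)
  expect_true(all(Pinf >= -1e-12 & Pinf <= 1 + 1e-12))
  # stationary vector is proportional to sqrt(h) exp(-beta G)
  pi_ref <- sqrt(ms$h_nodes) * exp(-ms$G)
  expect_equal(Pinf[, 1], pi_ref / sum(pi_ref), tolerance = 1e-9)
})

test_that("log-likelihood sums counts against log propagator entries", {
  m0 <- build_rate_matrix(G = c(0, 0), D = 0, beta = 1, h_nodes = c(1, 1),
                          delta_r = 1)
  one <- structure(list(n_bins = 2L, lag = 1, lag_steps = 1L,
                        mode = "sliding",
                        counts = matrix(c(1L, 0L, 0L, 0L), 2)),
                   class = "transition_counts")
  # R = 0: propagator is the identity, a stay observation has logL = 0
  expect_equal(log_likelihood(m0, one), 0)
  # an impossible observation under R = 0 flags zero probability as -Inf
  imp <- one; imp$counts <- matrix(c(0L, 1L, 0L, 0L), 2)
  expect_identical(unname(log_likelihood(m0, imp)[1]), -Inf)
  # closed-form 2-state check: exp(-2 k dt) = 0.5
  k <- 1; dt <- log(2) / (2 * k)
  m <- build_rate_matrix(G = c(0, 0), D = k, beta = 1, h_nodes = c(1, 1),
                         delta_r = 1)
  cts <- structure(list(n_bins = 2L, lag = dt, lag_steps = 1L,
                        mode = "sliding",
                        counts = matrix(c(7L, 3L, 0L, 0L), 2)),
                   class = "transition_counts")
  expect_equal(log_likelihood(m, cts), 7 * log(0.75) + 3 * log(0.25),
               tolerance = 1e-12)
  # doubling every count doubles the log-likelihood
  cts2 <- cts; cts2$counts <- 2L * cts$counts
  expect_equal(log_likelihood(m, cts2), 2 * log_likelihood(m, cts),
               tolerance = 1e-12)
})

test_that("likelihood gauges: constant G shift and D/h scaling", {
  m <- random_smooth_model(n = 8)
  cts <- structure(list(n_bins = 8L, lag = 0.05, lag_steps = 1L,
                        mode = "sliding",
                        counts = matrix(5L, 8, 8)),
                   class = "transition_counts")
  base <- log_likelihood(m, cts)
  shifted <- build_rate_matrix(G = m$G + 3.7, D = m$D, beta = m$beta,
                               h_nodes = m$h_nodes, delta_r = m$delta_r)
  expect_equal(log_likelihood(shifted, cts), base, tolerance = 1e-10)
  scaled <- build_rate_matrix(G = m$G, D = 2.5 * m$D, beta = m$beta,
                              h_nodes = 2.5 * m$h_nodes,
                              delta_r = m$delta_r)
  expect_equal(scaled$R, m$R, tolerance = 1e-13)
  expect_equal(log_likelihood(scaled, cts), base, tolerance = 1e-12)
})

test_that("analytic likelihood gradient matches finite differences", {
  m <- random_smooth_model(n = 6, seed = 4)
  set.seed(9)
  C <- matrix(rpois(36, 20), 6, 6)
  cts <- structure(list(n_bins = 6L, lag = 0.08, lag_steps = 1L,
                        mode = "sliding", counts = C),
                   class = "transition_counts")
  G <- m$G; u <- log(m$h_nodes)
  an <- loglik_with_grad(G, u, m$D, m$beta, m$delta_r, cts)
  th <- c(G[-1], u)
  f <- function(th) {
    loglik_with_grad(c(0, th[1:5]), th[6:11], m$D, m$beta, m$delta_r,
                     cts)$value
  }
  num <- vapply(seq_along(th), function(j) {
    e <- numeric(length(th)); e[j] <- 1e-6
    (f(th + e) - f(th - e)) / 2e-6
  }, numeric(1))
  expect_equal(an$grad, num, tolerance = 1e-5)
})

test_that("joint inversion is the exact inverse of the builder", {
  m <- random_smooth_model(n = 50, seed = 11)
  prof <- profiles_from_rates(m, mode = "joint", h0 = m$h_nodes[1])
  expect_rel(prof$G, m$G, 1e-9)
  expect_rel(prof$h_nodes, m$h_nodes, 1e-9)
  rebuilt <- build_rate_matrix(G = prof$G, D = m$D, beta = m$beta,
                               h_nodes = prof$h_nodes,
                               h_mid = prof$h_mid, delta_r = m$delta_r)
  nz <- m$R != 0
  expect_lt(max(abs(rebuilt$R[nz] - m$R[nz]) / abs(m$R[nz])), 1e-9)
  # different h0 values give the same generator back (scale gauge family)
  prof2 <- profiles_from_rates(m, mode = "joint", h0 = 2)
  rebuilt2 <- build_rate_matrix(G = prof2$G, D = m$D, beta = m$beta,
                                h_nodes = prof2$h_nodes,
                                h_mid = prof2$h_mid, delta_r = m$delta_r)
  expect_lt(max(abs(rebuilt2$R[nz] - m$R[nz]) / abs(m$R[nz])), 1e-8)
})

test_that("pairwise inversion recovers slowly-varying profiles", {
  # constant h: the detailed-balance relations are exact
  mc <- build_rate_matrix(G = c(0, 1, 0.5), D = 1, beta = 1,
                          h_nodes = rep(1, 3), delta_r = 1)
  pc <- profiles_from_rates(mc, mode = "pairwise")
  expect_equal(pc$G, c(0, 1, 0.5), tolerance = 1e-10)
  expect_equal(pc$h_nodes, rep(1, 3), tolerance = 1e-10)
  # under h_n = h_{n+1} = 1 the midpoint relation reduces to
  # h_mid = D^2 / (dr^4 Rup Rdn)
  up <- mc$R[cbind(1:2, 2:3)]; dn <- mc$R[cbind(2:3, 1:2)]
  expect_equal(pc$h_mid, 1 / (up * dn), tolerance = 1e-10)
  # smooth h with |d log h| < 0.02 per bond: recovery to 1e-3
  m <- random_smooth_model(n = 50, seed = 11, amp_h = 0.14)
  expect_lt(max(abs(diff(log(m$h_nodes)))), 0.02)
  p <- profiles_from_rates(m, mode = "pairwise")
  expect_lt(max(abs(p$G - m$G)), 1e-3 * max(abs(m$G)))
  expect_lt(max(abs(p$h_nodes / m$h_nodes - 1)), 1e-3)
  # detailed-balance residual is reported, first order in dlog h
  expect_lt(max(abs(p$db_residual - log(m$h_nodes[-50] / m$h_nodes[-1]) / 2)),
            2e-4)
})

test_that("maximum-likelihood fit recovers the generating profiles", {
  truth <- random_smooth_model(n = 10, seed = 21, amp_h = 0.3)
  # exact expected counts from the propagator at a finite lag: n pi_i P_ji
  lag <- 0.02
  P <- propagate(truth, lag)
  pi_s <- sqrt(truth$h_nodes) * exp(-truth$G)
  pi_s <- pi_s / sum(pi_s)
  E <- P * rep(pi_s, each = 10) * 1e6
  cts <- structure(list(n_bins = 10L, lag = lag, lag_steps = 1L,
                        mode = "sliding",
                        counts = round(E)),
                   class = "transition_counts")
  path <- discretized_path(matrix(seq(0, 1, length.out = 10), ncol = 1))
  fit <- fit_rate_model(cts, path, beta = truth$beta, D = truth$D)
  expect_lte(fit$loglik, 0)
  expect_equal(length(fit$unidentifiable), 0L)
  expect_lt(sqrt(mean((fit$model$G - truth$G)^2)), 0.05)
  expect_lt(sqrt(mean((log(fit$model$h_nodes) - log(truth$h_nodes))^2)), 0.1)
})

test_that("posterior sampling brackets the maximum-likelihood profiles", {
  truth <- random_smooth_model(n = 5, seed = 2, amp_h = 0.2)
  lag <- 0.05
  P <- propagate(truth, lag)
  pi_s <- sqrt(truth$h_nodes) * exp(-truth$G); pi_s <- pi_s / sum(pi_s)
  cts <- structure(list(n_bins = 5L, lag = lag, lag_steps = 1L,
                        mode = "sliding",
                        counts = round(P * rep(pi_s, each = 5) * 2e5)),
                   class = "transition_counts")
  path <- discretized_path(matrix(seq(0, 1, length.out = 5), ncol = 1))
  post <- sample_rate_posterior(cts, path, beta = 1, D = 1,
                                n_iter = 400L, step = 0.01, seed = 3)
  expect_gt(post$acceptance, 0.05)
  expect_true(all(post$G_ci[1, ] <= post$G_mean + 1e-9))
  expect_lt(max(abs(post$G_mean - truth$G)), 0.2)
})

test_that("rate matrix and profile CSVs round-trip", {
  m <- random_smooth_model(n = 7)
  f <- tempfile(fileext = ".csv")
  write_rate_csv(m, f)
  d <- read_table_csv(f)
  R2 <- matrix(0, 7, 7)
  R2[cbind(d$n, d$m)] <- d$R_nm
  expect_equal(R2, m$R, tolerance = 1e-12)
  unlink(f)
  path <- discretized_path(matrix(seq(0, 1, length.out = 7), ncol = 1),
                           h_nodes = m$h_nodes)
  fp <- tempfile(fileext = ".csv")
  write_profile_csv(m, path, fp)
  dp <- read_table_csv(fp)
  expect_equal(dp$G, m$G, tolerance = 1e-12)
  expect_equal(dp$D_eff, m$D / m$h_nodes, tolerance = 1e-12)
  unlink(fp)
})
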