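# internal helpers exercised directly by the tests
num_jacobian <- riemcv:::num_jacobian
read_table_csv <- riemcv:::read_table_csv
interp_h_mid <- riemcv:::interp_h_mid
loglik_with_grad <- riemcv:::loglik_with_grad
`%||%` <- riemcv:::`%||%`

# shared fixtures, memoized so expensive objects are built once per run
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# converged 20-image Mueller-Brown MFEP (Euclidean metric)
mb_string20 <- function() memo("mb_string20", {
  string_mfep(muller_brown(), "euclidean",
              endpoints = rbind(c(-0.56, 1.44), c(0.62, 0.03)),
              n_images = 20, tol = 1e-8)
})

# independent mountain-pass saddle oracle: lowest level at which the two
# minima connect on a dense grid (flood fill + bisection on the level)
mb_grid_saddle <- function() memo("mb_grid_saddle", {
  surf <- muller_brown()
  nx <- 400; ny <- 400
  xs <- seq(-1.8, 1.2, length.out = nx)
  ys <- seq(-0.5, 2.2, length.out = ny)
  V <- matrix(surface_energy(surf, cbind(rep(xs, ny), rep(ys, each = nx))),
              nx, ny)
  m1 <- relax_to_minimum(surf, c(-0.56, 1.44))$par
  m2 <- relax_to_minimum(surf, c(0.62, 0.03))$par
  i1 <- c(which.min(abs(xs - m1[1])), which.min(abs(ys - m1[2])))
  i2 <- c(which.min(abs(xs - m2[1])), which.min(abs(ys - m2[2])))
  connected <- function(level) {
    open <- V <= level
    if (!open[i1[1], i1[2]] || !open[i2[1], i2[2]]) return(FALSE)
    reach <- matrix(FALSE, nx, ny)
    reach[i1[1], i1[2]] <- TRUE
    repeat {
      grown <- reach
      grown[-1, ] <- grown[-1, ] | reach[-nx, ]
      grown[-nx, ] <- grown[-nx, ] | reach[-1, ]
      grown[, -1] <- grown[, -1] | reach[, -ny]
      grown[, -ny] <- grown[, -ny] | reach[, -1]
      grown <- grown & open
      if (grown[i2[1], i2[2]]) return(TRUE)
      if (all(grown == reach)) return(FALSE)
      reach <- grown
    }
  }
  lo <- max(V[i1[1], i1[2]], V[i2[1], i2[2]]); hi <- 0
  for (k in 1:25) {
    mid <- (lo + hi) / 2
    if (connected(mid)) hi <- mid else lo <- mid
  }
  list(saddle = hi, min1 = m1, min2 = m2,
       E1 = surface_energy(surf, m1), E2 = surface_energy(surf, m2))
})

# the two fine Mueller-Brown analysis paths (1000 bins)
mb_case_paths <- function(n_bins = 1000) memo(paste0("mb_paths", n_bins), {
  coarse <- mb_string20()
  fine_xy <- reparameterize(coarse$centers, "euclidean", n_bins, smooth = TRUE)
  XY <- cv_logpolar()$forward(fine_xy$centers)
  fine_lp <- reparameterize(XY, "euclidean", n_bins,
                            h_metric = metric_logpolar())
  list(xy = fine_xy, lp = fine_lp)
})

# small reference rate model on a smooth random (G, h), fixed seed
random_smooth_model <- function(n = 50, seed = 11, amp_h = 0.14) {
  set.seed(seed)
  r <- seq(0, 1, length.out = n)
  ph <- runif(3, 0, 2 * pi)
  G <- 1.5 * sin(2 * pi * r + ph[1]) + 0.8 * cos(4 * pi * r + ph[2])
  G <- G - G[1]
  h <- exp(amp_h * sin(2 * pi * r + ph[3]))
  build_rate_matrix(G = G, D = 1, beta = 1, h_nodes = h,
                    delta_r = 1 / (n - 1))
}

expect_rel <- function(x, y, tol) {
  testthat::expect_lt(max(abs(x - y)) / max(abs(y), 1e-300), tol)
}

# a 2D bowl with a single minimum, used by the degenerate-endpoints test
quadratic1d_2d <- function() {
  potential_surface(2L, energy = function(p) rowSums(p^2),
                    gradient = function(p) 2 * p, name = "bowl")
}
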