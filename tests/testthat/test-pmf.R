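test_that("conventional 1D PMF reproduces the closed forms", {
  surf <- quadratic_1d()
  zg <- seq(-0.9, 0.9, length.out = 41)
  # identity CV: PMF equals the potential
  p_id <- conventional_pmf_1d(surf, cv_identity(), zg)
  expect_equal(p_id$conventional, zg^2, tolerance = 1e-12)
  # erf CV: PMF is exactly flat at log(2/sqrt(pi))
  p_erf <- conventional_pmf_1d(surf, cv_erf1d(), zg)
  expect_lt(max(p_erf$conventional) - min(p_erf$conventional), 1e-10)
  expect_equal(p_erf$conventional[1], log(2 / sqrt(pi)), tolerance = 1e-10)
  # linear stretching xi = 2x: Atilde = zeta^2/4 + log 2
  p_sc <- conventional_pmf_1d(surf, cv_scale(2), zg)
  expect_equal(p_sc$conventional, zg^2 / 4 + log(2), tolerance = 1e-12)
  # a decreasing map violates the monotonicity precondition
  expect_error(conventional_pmf_1d(surf, cv_scale(-1), zg),
               class = "riemcv_invalid_cv")
})

test_that("invariant PMF projects to V(x) for every monotone CV", {
  surf <- quadratic_1d()
  xg <- seq(-1.5, 1.5, length.out = 61)
  for (map in list(cv_identity(), cv_erf1d(), cv_scale(3))) {
    zeta <- map$forward(matrix(xg, ncol = 1))[, 1]
    prof <- invariant_pmf_1d(surf, map, zeta)
    expect_equal(prof$invariant, xg^2, tolerance = 1e-10)
  }
  # along the CV axis the erf profile is (erfinv(zeta))^2
  zg <- seq(-0.9, 0.9, length.out = 31)
  p <- invariant_pmf_1d(surf, cv_erf1d(), zg)
  expect_equal(p$invariant, erfinv(zg)^2, tolerance = 1e-10)
  # witness of non-invariance: the conventional profiles differ
  expect_gt(max(abs(conventional_pmf_1d(surf, cv_erf1d(), zg)$conventional -
                    conventional_pmf_1d(surf, cv_identity(), zg)$conventional)),
            0.1)
})

test_that("per-bin identity invariant = conventional + log(g/g0)/(2 beta)", {
  surf <- quadratic_1d()
  zg <- seq(-0.8, 0.8, length.out = 33)
  for (beta in c(1, 2.5)) {
    p <- conventional_pmf_1d(surf, cv_erf1d(), zg, beta = beta)
    expect_equal(p$invariant,
                 p$conventional + log(p$metric_det / p$g0) / (2 * beta),
                 tolerance = 1e-12)
  }
})

test_that("CV design ODE recovers the identity and erf maps", {
  surf <- quadratic_1d()
  zg <- seq(-0.95, 0.95, by = 0.01)
  # target Atilde = zeta^2 with eta(0) = 0 gives the identity CV
  m_id <- design_cv_for_pmf(function(z) z^2, surf, 0, 0, zg)
  expect_equal(m_id$forward(matrix(zg, ncol = 1))[, 1], zg, tolerance = 1e-6)
  # flat target log(2/sqrt(pi)) gives back xi = erf
  m_erf <- design_cv_for_pmf(function(z) rep(log(2 / sqrt(pi)), length(z)),
                             surf, 0, 0, zg)
  xs <- seq(-1.3, 1.3, length.out = 101)
  expect_equal(m_erf$forward(matrix(xs, ncol = 1))[, 1], erf(xs),
               tolerance = 1e-6)
})

test_that("designed CVs for -zeta^2 and sin(10 zeta) round-trip through the PMF", {
  surf <- quadratic_1d()
  zg <- seq(-1.2, 1.2, by = 0.002)
  targets <- list(neg = function(z) -z^2, wig = function(z) sin(10 * z))
  for (nm in names(targets)) {
    tgt <- targets[[nm]]
    map <- suppressWarnings(design_cv_for_pmf(tgt, surf, 0, 0, zg, eta_max = 4))
    reach <- attr(map, "reachable")
    sub <- zg[zg > reach[1] + 1e-3 & zg < reach[2] - 1e-3]
    prof <- conventional_pmf_1d(surf, map, sub)
    expect_lt(max(abs(prof$conventional - tgt(sub))), 1e-4)
    # and its invariant profile still projects onto V(x) = x^2
    dom <- attr(map, "domain")
    xs <- seq(dom[1] + 1e-3, dom[2] - 1e-3, length.out = 101)
    zeta <- map$forward(matrix(xs, ncol = 1))[, 1]
    expect_lt(max(abs(invariant_pmf_1d(surf, map, zeta)$invariant - xs^2)),
              1e-6)
  }
  # truncation is reported with the reachable interval
  expect_warning(design_cv_for_pmf(function(z) -z^2, surf, 0, 0,
                                   seq(-3, 3, by = 0.01), eta_max = 4),
                 class = "riemcv_domain_truncation")
})

test_that("histogram PMF matches closed forms on Boltzmann samples", {
  set.seed(101)
  x <- rnorm(1e6, sd = sqrt(0.5))          # Boltzmann density of V = x^2, beta 1
  breaks <- seq(-2.2, 2.2, length.out = 45)
  # identity CV
  p_id <- histogram_pmf(x, jac = rep(1, length(x)), breaks = breaks)
  keep <- p_id$mask & abs(p_id$grid) <= 2
  resid <- p_id$conventional[keep] - p_id$grid[keep]^2
  expect_lt(diff(range(resid)) / 2, 0.05)  # matches zeta^2 up to a constant
  # erf CV: conventional flat, invariant recovers (erfinv z)^2
  z <- erf(x)
  jz <- 2 / sqrt(pi) * exp(-x^2)
  zb <- seq(-0.975, 0.975, length.out = 40)
  p_erf <- histogram_pmf(z, jac = jz, breaks = zb)
  keep <- p_erf$mask & abs(p_erf$grid) <= 0.95
  expect_lt(diff(range(p_erf$conventional[keep])), 0.08)
  inv_ref <- erfinv(p_erf$grid[keep])^2
  resid <- p_erf$invariant[keep] - inv_ref
  expect_lt(diff(range(resid)) / 2, 0.08)  # matches (erfinv z)^2 up to a constant
  # the per-bin identity holds exactly by construction
  expect_equal(p_erf$invariant[keep],
               p_erf$conventional[keep] +
                 log(p_erf$metric_det[keep] / p_erf$g0) / 2,
               tolerance = 1e-12)
})

test_that("histogram PMF edge cases: single sample and degenerate binning", {
  p1 <- histogram_pmf(0.5, jac = 1, breaks = seq(0, 1, by = 0.25))
  expect_equal(sum(p1$mask), 1L)
  expect_equal(p1$conventional[p1$mask], 0)  # min-shifted
  pd <- histogram_pmf(rep(0.51, 10), jac = rep(1, 10),
                      breaks = seq(0, 1, by = 0.25))
  expect_true(attr(pd, "degenerate"))
  expect_error(histogram_pmf(0.5, jac = 1, breaks = seq(0, 1, by = 0.25),
                             g0_bin = 1L),
               class = "riemcv_domain_error")
})

test_that("PMF CSV round-trips through write_pmf_csv", {
  surf <- quadratic_1d()
  p <- conventional_pmf_1d(surf, cv_erf1d(), seq(-0.9, 0.9, by = 0.1))
  f <- tempfile(fileext = ".csv")
  write_pmf_csv(p, f)
  d <- read_table_csv(f)
  expect_equal(d$A_conventional, p$conventional, tolerance = 1e-12)
  expect_equal(d$zeta, p$grid, tolerance = 1e-12)
  unlink(f)
})
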