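test_that("chi*T reaches the equal-population and Curie limits", {
  # T -> infinity: C g^2 <S(S+1)> with <S(S+1)> = 14.75 over the 60 states
  expect_equal(chi_t(exchange_system(-1, 2), g = 2, T_K = 1e6),
               0.125049 * 4 * 14.75, tolerance = 1e-4)
  # deep AF coupling at low T: isolated S = 1/2 Curie constant
  expect_equal(chi_t(exchange_system(-100, 0), g = 2, T_K = 2),
               0.125049 * 4 * 0.75, tolerance = 1e-3)
  # J < 0 fixtures rise with temperature above 50 K
  for (r in c(2.0, 2.9, 3.7)) {
    v <- chi_t(exchange_system(-40, r * 40), g = 2, T_K = seq(52, 290, 2))
    expect_true(all(diff(v) > 0))
  }
})

test_that("chi*T agrees with an independent raw van Vleck sum", {
  set.seed(3)
  for (k in 1:10) {
    J <- stats::runif(1, -60, 20); B <- stats::runif(1, 0, 150)
    g <- stats::runif(1, 1.8, 2.1)
    Tg <- c(20, 77, 150, 290)   # raw sums overflow below ~20 K; the guard
                                # in chi_t is exercised separately
    expect_equal(chi_t(exchange_system(J, B), g, Tg),
                 oracle_chi_t(J, B, g, Tg), tolerance = 1e-12)
  }
  expect_error(chi_t(exchange_system(-1, 1), 2, T_K = c(10, -5)), "> 0")
})

test_that("noiseless self-consistency: the fitter recovers the generating ratio", {
  sys <- exchange_system(J = -40, B = 3.7 * 40)
  tc <- seq(52, 290, by = 2)
  crv <- magnetometry_curve(tc, chi_t(sys, g = 2, T_K = tc), "susceptibility")
  fit <- fit_chi_t(crv, chit_fit_config(g = 2))
  expect_true(fit$converged)
  expect_equal(fit$r, 3.7, tolerance = 1e-3)
})

test_that("fit guards: window restriction, too-few points, degenerate data", {
  tc <- seq(2, 290, by = 2)
  sys <- exchange_system(-40, 148)
  crv <- magnetometry_curve(tc, chi_t(sys, 2, tc), "susceptibility")
  fit <- fit_chi_t(crv, chit_fit_config(T_min = 50, g = 2))
  expect_equal(fit$n_used, sum(tc > 50))          # low-T points excluded
  fit_all <- fit_chi_t(crv, chit_fit_config(T_min = 50, g = 2,
                                            allow_low_T = TRUE))
  expect_equal(fit_all$n_used, length(tc))        # explicit override only
  short <- magnetometry_curve(seq(260, 290, 4), rep(1:2, 4), "susceptibility")
  expect_error(fit_chi_t(short, chit_fit_config(g = 2)), "at least 10")
  flat <- magnetometry_curve(tc, rep(1, length(tc)), "susceptibility")
  expect_error(fit_chi_t(flat, chit_fit_config(g = 2)), "degenerate")
})

test_that("Zeeman magnetization saturates, is isotropic for S = 1/2, and obeys Maxwell consistency", {
  # saturation at g*S
  expect_equal(zeeman_magnetization(zfs_system(3/2, g = 2), H = 7, T_K = 0.01),
               3, tolerance = 1e-6)
  # S = 1/2 has no ZFS: direction-independent
  half <- zfs_system(1/2, g = 2)
  dirs <- list(c(0, 0, 1), c(1, 0, 0), c(1, 1, 1), c(0.3, -0.2, 0.9))
  m <- sapply(dirs, function(u) zeeman_magnetization(half, 3, u, T_K = 2))
  expect_equal(max(m) - min(m), 0, tolerance = 1e-10)
  # anisotropic S = 3/2: expectation operator vs finite-difference -dF/dB
  zfs <- zfs_system(3/2, D = 11, E_over_D = 0.33, g = 2)
  for (u in list(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), c(1, 1, 1))) {
    M_op <- zeeman_magnetization(zfs, H = c(1, 4, 7), direction = u, T_K = 2)
    M_fd <- oracle_moment_fd(zfs, H = c(1, 4, 7), direction = u, T_K = 2)
    expect_equal(M_op, M_fd, tolerance = 1e-6)
  }
  expect_gt(abs(zeeman_magnetization(zfs, 7, c(0, 0, 1), 2) -
                zeeman_magnetization(zfs, 7, c(1, 0, 0), 2)), 0.1) # anisotropy
  # M(0) = 0 and monotone non-decreasing in field
  Hs <- seq(0, 7, by = 0.5)
  M <- zeeman_magnetization(zfs, Hs, c(0.4, 0.5, 0.77), T_K = 2)
  expect_equal(M[1], 0, tolerance = 1e-10)
  expect_true(all(diff(M) >= -1e-10))
})

test_that("powder averaging is bounded by the best orientation and converges", {
  iso <- zfs_system(3/2, g = 2)
  pm_iso <- powder_moment(iso, H = 5, T_K = 2, orientations = 80)
  expect_equal(pm_iso$M_powder, zeeman_magnetization(iso, 5, c(0, 0, 1), 2),
               tolerance = 1e-8)
  expect_equal(pm_iso$M_powder, pm_iso$M_max, tolerance = 1e-8)
  zfs <- zfs_system(3/2, D = 11, E_over_D = 0.33, g = 2)
  pm <- powder_moment(zfs, H = c(1, 4, 7), T_K = 2, orientations = 200)
  expect_true(all(pm$M_powder <= pm$M_max + 1e-12))
  # grid refinement self-convergence < 0.5%
  pm2 <- powder_moment(zfs, H = 7, T_K = 2, orientations = 500)
  expect_equal(powder_moment(zfs, H = 7, T_K = 2, orientations = 200)$M_powder,
               pm2$M_powder, tolerance = 5e-3)
  expect_warning(powder_moment(zfs, H = 7, orientations = 20), "coarse")
})

test_that("mixture responses are convex combinations with molar bookkeeping", {
  tc <- seq(2, 100, 2)
  a <- magnetometry_curve(tc, rep(0.375147, length(tc)), "susceptibility")
  b <- magnetometry_curve(tc, rep(1.875735, length(tc)), "susceptibility")
  expect_equal(mixture_response(list(a, a), c(0.5, 0.5))$chiT_cm3Kmol,
               a$chiT_cm3Kmol)
  expect_equal(mixture_response(list(a, b), c(1, 0))$chiT_cm3Kmol,
               a$chiT_cm3Kmol)
  # 50:50 spin-isomer Curie limits: (0.3751 + 1.8757)/2
  mix <- mixture_response(list(a, b), c(0.5, 0.5))
  expect_equal(mix$chiT_cm3Kmol[1], 1.125441, tolerance = 1e-5)
  other <- magnetometry_curve(tc + 1, rep(1, length(tc)), "susceptibility")
  expect_error(mixture_response(list(a, other), c(0.5, 0.5)), "abscissae")
  expect_error(mixture_response(list(a, b), c(0.7, 0.7)), "sum to 1")
})

test_that("curve containers validate their physical invariants", {
  expect_error(magnetometry_curve(c(2, 2, 4), 1:3, "susceptibility"),
               "strictly increasing")
  expect_error(magnetometry_curve(c(-1, 2), c(1, 1), "susceptibility"), "> 0")
  expect_error(magnetometry_curve(c(1, 2), c(-1, 1), "susceptibility"), ">= 0")
  expect_error(magnetometry_curve(c(1, 2), c(0.5, 1), "magnetization"),
               "T_meas")
})
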