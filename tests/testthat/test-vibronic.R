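test_that("Lambda = 0 surfaces are flat and equal the bare ladder", {
  sys <- exchange_system(-13, 42)
  p <- vibronic_params(sys, Lambda = 0)
  surf <- adiabatic_surfaces(p)
  lad <- hde_energies(sys)
  for (i in seq_len(nrow(lad))) {
    e <- surf$energy[surf$S == lad$S[i] & surf$branch == lad$branch[i]]
    expect_equal(max(abs(e - lad$energy[i])), 0)
  }
  vl <- vibronic_spin_ladder(p)
  expect_equal(vl$ground_S, as.numeric(ground_spin(sys)))
})

test_that("surfaces are mirror-symmetric and split by 2B(S+1/2) at the origin", {
  set.seed(7)
  for (k in 1:20) {
    sys <- exchange_system(stats::runif(1, -300, 100), stats::runif(1, 0, 1500))
    p <- vibronic_params(sys, Lambda = stats::runif(1, 0, 3000))
    surf <- adiabatic_surfaces(p)
    for (br in c("-", "+")) {
      sub <- surf[surf$branch == br, ]
      for (S in unique(sub$S)) {
        e <- sub$energy[sub$S == S]
        expect_equal(e, rev(e))
      }
    }
    S0 <- sys$spins$S_allowed[2]
    at0 <- surf[abs(surf$y) < 1e-12 & surf$S == S0, ]
    expect_equal(at0$energy[at0$branch == "+"] - at0$energy[at0$branch == "-"],
                 2 * sys$B * (S0 + 0.5))
  }
  # worked splitting: B = 1, S = 3/2 -> 4 cm^-1
  p1 <- vibronic_params(exchange_system(0, 1), Lambda = 100)
  s1 <- adiabatic_surfaces(p1)
  a <- s1[abs(s1$y) < 1e-12 & s1$S == 1.5, ]
  expect_equal(a$energy[a$branch == "+"] - a$energy[a$branch == "-"], 4)
})

test_that("B = 0 trapping limit: minima at y = +/-1, depth Lambda/2", {
  p <- vibronic_params(exchange_system(-1, 0), Lambda = 2200)
  surf <- adiabatic_surfaces(p)
  low <- surf[surf$S == 0.5 & surf$branch == "-", ]
  ymin <- low$y[which.min(low$energy)]
  expect_equal(abs(ymin), 1, tolerance = 0.011)   # grid resolution
  e0 <- low$energy[abs(low$y) < 1e-12]
  expect_equal(e0 - min(low$energy), 1100, tolerance = 0.5)
  cl <- classify_ground_surface(p, 0.5)
  expect_equal(cl$topology, "double_well")
  expect_equal(cl$y0, 1)
  expect_equal(cl$barrier, 1100)
  expect_true(cl$localized)
})

test_that("well classification matches the curvature criterion b >= Lambda", {
  # delocalized: no vibronic coupling
  p0 <- vibronic_params(exchange_system(-10, 50), Lambda = 0)
  expect_equal(classify_ground_surface(p0, 0.5)$robin_day, "III")
  # double well below the boundary, single well above
  sysb <- exchange_system(-10, 500)        # b(S=1/2) = 500
  expect_equal(classify_ground_surface(vibronic_params(sysb, 800), 0.5)$topology,
               "double_well")
  expect_equal(classify_ground_surface(vibronic_params(sysb, 400), 0.5)$topology,
               "single_well")
  # exact boundary b = Lambda: single well with quartic-flat bottom
  pb <- vibronic_params(sysb, Lambda = 500)
  expect_equal(classify_ground_surface(pb, 0.5)$topology, "single_well")
  expect_lt(abs(oracle_curvature_at_origin(pb, 0.5, h = 1e-3)), 1e-2)
  # away from the boundary the numeric curvature matches Lambda - Lambda^2/b
  pd <- vibronic_params(sysb, Lambda = 300)
  expect_equal(oracle_curvature_at_origin(pd, 0.5), 300 - 300^2 / 500,
               tolerance = 1e-4)
})

test_that("relaxed minima follow the closed form and the grid agrees", {
  set.seed(11)
  for (k in 1:20) {
    sys <- exchange_system(stats::runif(1, -300, 0), stats::runif(1, 0, 1200))
    L <- stats::runif(1, 1, 2500)
    p <- vibronic_params(sys, L, y = seq(-3, 3, length.out = 4001))
    surf <- adiabatic_surfaces(p)
    vl <- vibronic_spin_ladder(p)
    for (S in sys$spins$S_allowed) {
      b <- sys$B * (S + 0.5)
      relax <- if (b < L) (L - b)^2 / (2 * L) else 0
      closed <- -sys$J * S * (S + 1) - b - relax
      expect_equal(vl$levels$E_relaxed[vl$levels$S == S], closed)
      grid_min <- min(surf$energy[surf$S == S & surf$branch == "-"])
      expect_equal(grid_min, closed, tolerance = 1e-3 * max(1, abs(closed)))
    }
  }
})

test_that("vibronic relaxation destabilizes intermediate spins monotonically", {
  sys <- exchange_system(-40, 160)
  L_grid <- c(0, 300, 900, 1800)
  relaxed <- sapply(L_grid, function(L)
    vibronic_spin_ladder(vibronic_params(sys, L))$levels$E_relaxed)
  # larger Lambda never raises any relaxed level
  expect_true(all(diff(t(relaxed)) <= 1e-9))
  # relaxation magnitude is non-increasing in b = B(S+1/2)
  relax <- relaxed[, 1] - relaxed[, 4]
  expect_true(all(diff(relax) <= 1e-9))
  # B = 0, J < 0: relaxation is S-independent, ground spin stays 1/2
  vl0 <- vibronic_spin_ladder(vibronic_params(exchange_system(-40, 0), 1234))
  expect_equal(vl0$ground_S, 0.5)
  bare0 <- hde_energies(exchange_system(-40, 0))
  shift <- vl0$levels$E_relaxed -
    sapply(vl0$levels$S, function(S) min(bare0$energy[bare0$S == S]))
  expect_equal(shift, rep(-1234 / 2, 5))
})

test_that("chalcogenide-series fixtures reproduce the class II/III contrast", {
  fx <- vibronic_fixtures()
  v1 <- vibronic_spin_ladder(fx$complex1)
  v2 <- vibronic_spin_ladder(fx$complex2)
  v3 <- vibronic_spin_ladder(fx$complex3)
  expect_equal(v1$ground_S, 0.5)
  expect_equal(v3$ground_S, 1.5)
  expect_equal(classify_ground_surface(fx$complex1, v1$ground_S)$robin_day, "II")
  expect_equal(classify_ground_surface(fx$complex3, v3$ground_S)$robin_day, "III")
  # intermediate fixture: condensed low-energy ladder, 1/2 and 3/2 close
  gap2 <- abs(diff(sort(v2$levels$E_relaxed)[1:2]))
  gap1 <- abs(diff(sort(v1$levels$E_relaxed)[1:2]))
  expect_lt(gap2, gap1)
  expect_equal(sort(v2$levels$S[order(v2$levels$E_relaxed)][1:3]),
               c(0.5, 1.5, 2.5))
})

test_that("the alternative printed radical normalization is available but distinct", {
  sys <- exchange_system(-40, 100)
  p <- vibronic_params(sys, Lambda = 1000)
  std <- adiabatic_surfaces(p, form = "standard")
  alt <- adiabatic_surfaces(p, form = "as_printed")
  at0 <- abs(std$y) < 1e-12
  expect_equal(std$energy[at0], alt$energy[at0])   # identical at the origin
  expect_gt(max(abs(std$energy - alt$energy)), 1)  # differ off-origin
})

test_that("invalid vibronic inputs are rejected", {
  sys <- exchange_system(-1, 1)
  expect_error(vibronic_params(sys, Lambda = -5), "Lambda")
  expect_error(vibronic_params(sys, 10, y = seq(-1, 2, 0.5)), "symmetric")
  expect_error(classify_ground_surface(vibronic_params(sys, 10), S = 6),
               "allowed total spin")
})
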