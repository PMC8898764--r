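# Independent brute-force oracles, kept deliberately separate from the
# package implementation paths they check.

# ground spin by exhaustive enumeration of every (S, branch) level
oracle_ground_spin <- function(J, B, spins = local_spin_pair()) {
  S <- spins$S_allowed
  E <- c(-J * S * (S + 1) - B * (S + 0.5),
         -J * S * (S + 1) + B * (S + 0.5))
  Sall <- c(S, S)
  min(Sall[E <= min(E) + 1e-9 * max(1, max(abs(E)))])
}

# van Vleck chi*T from the raw Boltzmann sums, no overflow guard
oracle_chi_t <- function(J, B, g, T_K, spins = local_spin_pair()) {
  S <- rep(spins$S_allowed, each = 2)
  sgn <- rep(c(-1, 1), times = length(spins$S_allowed))
  E <- -J * S * (S + 1) + sgn * B * (S + 0.5)
  kB <- hdespin_constants$kB_cm
  sapply(T_K, function(Tt) {
    w <- (2 * S + 1) * exp(-E / (kB * Tt))
    hdespin_constants$curie_C * g^2 * sum(w * S * (S + 1)) / sum(w)
  })
}

# magnetization from the finite-difference derivative of the free energy
oracle_moment_fd <- function(zfs, H, direction = c(0, 0, 1), T_K = 2,
                             dH = 1e-6) {
  u <- direction / sqrt(sum(direction^2))
  kB <- hdespin_constants$kB_cm
  muB <- hdespin_constants$muB_cm_per_T
  free_energy <- function(h) {
    ev <- eigen(zfs_hamiltonian(zfs, h * u), symmetric = TRUE,
                only.values = TRUE)$values
    e0 <- min(ev)
    e0 - kB * T_K * log(sum(exp(-(ev - e0) / (kB * T_K))))
  }
  sapply(H, function(h)
    -(free_energy(h + dH) - free_energy(h - dH)) / (2 * dH) / muB)
}

# numerical second difference of the lower adiabatic surface at y = 0
oracle_curvature_at_origin <- function(params, S, h = 1e-4) {
  p <- vibronic_params(params$system, params$Lambda, y = c(-h, 0, h))
  surf <- adiabatic_surfaces(p)
  e <- surf$energy[surf$S == S & surf$branch == "-"]
  (e[1] - 2 * e[2] + e[3]) / h^2
}
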