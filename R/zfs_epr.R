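#' Zero-field-split spin system
#'
#' Spin S with axial and rhombic zero-field splitting (ZFS) and an
#' intrinsic g tensor. The ZFS Hamiltonian is
#' H = D [Sz^2 - S(S+1)/3] + E (Sx^2 - Sy^2) with E = eta * D and the
#' rhombicity eta = E/D restricted to the canonical range [0, 1/3] (any
#' tensor can be rotated into it).
#'
#' @param S Total spin quantum number.
#' @param D Axial ZFS parameter, cm^-1, signed.
#' @param E_over_D Rhombicity eta in [0, 1/3].
#' @param g Intrinsic g tensor: one value (isotropic) or three principal
#'   values (gx, gy, gz). Defaults to the free-electron value.
#' @return An object of class `zfs_system`.
#' @examples
#' zfs_system(S = 3/2, D = 11, E_over_D = 0.115, g = 1.925)
#' @export
zfs_system <- function(S, D = 0, E_over_D = 0, g = hdespin_constants$g_e) {
  if (!.is_half_integral(S))
    stop("'S' must be a non-negative integer or half-integer", call. = FALSE)
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D))
    stop("'D' must be a single finite number (cm^-1)", call. = FALSE)
  if (!is.numeric(E_over_D) || length(E_over_D) != 1L ||
      E_over_D < 0 || E_over_D > 1/3 + 1e-12)
    stop("'E_over_D' must lie in the canonical range [0, 1/3]", call. = FALSE)
  if (!length(g) %in% c(1L, 3L) || any(!is.finite(g)) || any(g < 0))
    stop("'g' must be one isotropic value or three principal values, all >= 0",
         call. = FALSE)
  if (length(g) == 1L) g <- rep(g, 3L)
  obj <- list(S = S, D = D, E_over_D = min(E_over_D, 1/3), g = g)
  class(obj) <- "zfs_system"
  obj
}

#' @export
print.zfs_system <- function(x, ...) {
  cat(sprintf("ZFS system: S = %s, D = %g cm^-1, E/D = %g, g = (%s)\n",
              format(x$S), x$D, x$E_over_D,
              paste(format(x$g), collapse = ", ")))
  invisible(x)
}

#' Zero-field-splitting + Zeeman spin Hamiltonian
#'
#' Builds the (2S+1)-dimensional Hermitian matrix
#' H = D[Sz^2 - S(S+1)/3] + E(Sx^2 - Sy^2) +
#' mu_B (gx Bx Sx + gy By Sy + gz Bz Sz), energies in cm^-1, field in
#' tesla. For S = 3/2 the zero-field eigenvalues are the two Kramers
#' doublets at -/+ sqrt(D^2 + 3E^2).
#'
#' @param zfs A [zfs_system()].
#' @param field Applied field vector (Bx, By, Bz) in tesla; default zero.
#' @return Complex Hermitian matrix of dimension 2S+1.
#' @examples
#' H <- zfs_hamiltonian(zfs_system(3/2, D = 11, E_over_D = 0.33))
#' eigen(H, symmetric = TRUE, only.values = TRUE)$values
#' @export
zfs_hamiltonian <- function(zfs, field = c(0, 0, 0)) {
  if (!inherits(zfs, "zfs_system"))
    stop("'zfs' must be a zfs_system", call. = FALSE)
  if (length(field) != 3L || any(!is.finite(field)))
    stop("'field' must be a finite 3-vector in tesla", call. = FALSE)
  sm <- spin_matrices(zfs$S)
  E  <- zfs$E_over_D * zfs$D
  Id <- diag(1 + 0i, sm$n)
  H <- zfs$D * (sm$Sz %*% sm$Sz - (zfs$S * (zfs$S + 1) / 3) * Id) +
       E * (sm$Sx %*% sm$Sx - sm$Sy %*% sm$Sy) +
       .muB * (zfs$g[1] * field[1] * sm$Sx +
               zfs$g[2] * field[2] * sm$Sy +
               zfs$g[3] * field[3] * sm$Sz)
  (H + Conj(t(H))) / 2   # enforce exact Hermiticity against rounding
}

# zero-field doublets: eigenvalues/vectors grouped into Kramers pairs
.zero_field_doublets <- function(zfs) {
  if (abs(2 * zfs$S - round(2 * zfs$S)) > 1e-9 || round(2 * zfs$S) %% 2 == 0)
    stop("Kramers doublets require half-integer S; got S = ",
         format(zfs$S), " (non-Kramers integer spin)", call. = FALSE)
  H0 <- zfs_hamiltonian(zfs)
  eg <- eigen(H0, symmetric = TRUE)
  ord <- order(eg$values)
  vals <- eg$values[ord]
  vecs <- eg$vectors[, ord, drop = FALSE]
  n_doublets <- length(vals) / 2L
  list(
    energies = vapply(seq_len(n_doublets),
                      function(k) mean(vals[c(2 * k - 1, 2 * k)]), 0),
    vectors  = lapply(seq_len(n_doublets),
                      function(k) vecs[, c(2 * k - 1, 2 * k), drop = FALSE])
  )
}

#' Effective g values of a Kramers doublet
#'
#' In the large-|D| limit each zero-field Kramers doublet behaves as a
#' fictitious S' = 1/2 with effective g' values given by the first-order
#' Zeeman splitting of the doublet under a small field along each
#' principal axis: g'_k = 2 g_k s_k, where s_k is the positive eigenvalue
#' of S_k projected onto the doublet. For an axial S = 3/2 system (eta =
#' 0, D > 0) the lower doublet gives the textbook (2g, 2g, g) pattern.
#'
#' @param zfs A [zfs_system()] with half-integer S.
#' @param doublet Doublet index, 1 = lowest zero-field doublet.
#' @param mode `"first_order"` (default): exact B -> 0 limit via projection
#'   of the Zeeman operator onto the isolated doublet. `"finite_field"`:
#'   full-matrix splitting at a small finite field (`B_probe`), which folds
#'   in inter-doublet mixing at finite D.
#' @param B_probe Probe field in tesla for `mode = "finite_field"`.
#' @return An object of class `effective_g`: list with `doublet`,
#'   `g_eff` (named gx/gy/gz, axis frame), `g_sorted` (descending) and the
#'   zero-field doublet `energies` (cm^-1).
#' @examples
#' doublet_effective_g(zfs_system(3/2, D = 11, E_over_D = 0.115, g = 1.925))
#' @export
doublet_effective_g <- function(zfs, doublet = 1L,
                                mode = c("first_order", "finite_field"),
                                B_probe = 1e-4) {
  if (!inherits(zfs, "zfs_system"))
    stop("'zfs' must be a zfs_system", call. = FALSE)
  mode <- match.arg(mode)
  dbl <- .zero_field_doublets(zfs)
  if (doublet < 1L || doublet > length(dbl$energies))
    stop("'doublet' out of range", call. = FALSE)
  sm <- spin_matrices(zfs$S)
  ops <- list(sm$Sx, sm$Sy, sm$Sz)
  if (mode == "first_order") {
    V <- dbl$vectors[[doublet]]
    g_eff <- vapply(1:3, function(k) {
      W <- Conj(t(V)) %*% ops[[k]] %*% V     # 2x2, traceless by Kramers
      s <- max(abs(eigen((W + Conj(t(W))) / 2, symmetric = TRUE,
                         only.values = TRUE)$values))
      2 * zfs$g[k] * s
    }, 0)
  } else {
    g_eff <- vapply(1:3, function(k) {
      fld <- c(0, 0, 0); fld[k] <- B_probe
      ev <- sort(eigen(zfs_hamiltonian(zfs, fld), symmetric = TRUE,
                       only.values = TRUE)$values)
      i <- 2L * doublet
      (ev[i] - ev[i - 1L]) / (.muB * B_probe)
    }, 0)
  }
  names(g_eff) <- c("gx", "gy", "gz")
  out <- list(doublet = doublet, g_eff = g_eff,
              g_sorted = sort(g_eff, decreasing = TRUE),
              energies = dbl$energies, mode = mode)
  class(out) <- "effective_g"
  out
}

#' @export
print.effective_g <- function(x, ...) {
  cat(sprintf("Doublet %d (zero-field energy %.4g cm^-1), %s mode:\n",
              x$doublet, x$energies[x$doublet], x$mode))
  cat(sprintf("  g' = (%s)  [sorted: %s]\n",
              paste(sprintf("%s = %.4f", names(x$g_eff), x$g_eff),
                    collapse = ", "),
              paste(sprintf("%.4f", x$g_sorted), collapse = ", ")))
  invisible(x)
}

#' Rhombogram: effective g' versus rhombicity
#'
#' Tabulates the effective g' values of every Kramers doublet over a grid
#' of E/D, the standard presentation for assigning half-integer-spin EPR
#' signals.
#'
#' @param S Half-integer spin.
#' @param g Intrinsic g (isotropic value or three principal values).
#' @param eta Grid of E/D values in [0, 1/3].
#' @param D Axial ZFS magnitude used for the construction (its value does
#'   not affect the first-order g'; its sign orders the doublets).
#' @return Data frame with columns `eta`, `doublet`, `gx`, `gy`, `gz`.
#' @examples
#' rg <- rhombogram(3/2, g = 2.0023, eta = seq(0, 1/3, length.out = 21))
#' @export
rhombogram <- function(S = 3/2, g = hdespin_constants$g_e,
                       eta = seq(0, 1/3, length.out = 101L), D = 10) {
  if (any(eta < 0 | eta > 1/3 + 1e-12))
    stop("'eta' grid must lie within [0, 1/3]", call. = FALSE)
  rows <- lapply(eta, function(e) {
    zfs <- zfs_system(S, D = D, E_over_D = min(e, 1/3), g = g)
    n_dbl <- (2 * S + 1) / 2
    do.call(rbind, lapply(seq_len(n_dbl), function(d) {
      ge <- doublet_effective_g(zfs, d)$g_eff
      data.frame(eta = e, doublet = d,
                 gx = ge[["gx"]], gy = ge[["gy"]], gz = ge[["gz"]])
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spin nutation frequency
#'
#' Rabi nutation frequency of a driven spin transition,
#' Omega_nut = g1 mu_B B1 / hbar * sqrt(S(S+1)): the sqrt(S(S+1)) scaling
#' lets transient-EPR nutation assign the spin quantum number (e.g. an
#' S = 3/2 centre nutates sqrt(5) times faster than S = 1/2 at the same
#' g1 B1).
#'
#' @param S Spin quantum number.
#' @param g1 g value in the laboratory frame.
#' @param B1 Microwave field amplitude in tesla (>= 0).
#' @return Angular nutation frequency in rad s^-1.
#' @examples
#' nutation_frequency(3/2, 2, 1e-4) / nutation_frequency(1/2, 2, 1e-4) # sqrt(5)
#' @export
nutation_frequency <- function(S, g1 = hdespin_constants$g_e, B1) {
  if (!.is_half_integral(S))
    stop("'S' must be a non-negative integer or half-integer", call. = FALSE)
  if (any(B1 < 0)) stop("'B1' must be >= 0", call. = FALSE)
  muB_J_per_T <- 9.2740100783e-24
  hbar <- 1.054571817e-34
  g1 * muB_J_per_T * B1 / hbar * sqrt(S * (S + 1))
}

#' Ratio of nutation frequencies of two spins
#'
#' Utility for spin-state assignment from relative nutation rates at equal
#' g1 B1: sqrt(S1(S1+1) / S2(S2+1)).
#'
#' @param S1,S2 Spin quantum numbers.
#' @return Dimensionless frequency ratio.
#' @examples
#' nutation_ratio(3/2, 1/2)   # sqrt(5)
#' @export
nutation_ratio <- function(S1, S2) {
  sqrt(S1 * (S1 + 1) / (S2 * (S2 + 1)))
}

#' Boltzmann populations of the zero-field doublets
#'
#' Fractional thermal populations of the zero-field Kramers doublets
#' (degeneracy 2 each). For S = 3/2 the two doublets are separated by
#' 2 sqrt(D^2 + 3E^2); growing population of the upper (Ms = +/-3/2-like)
#' doublet with temperature is what broadens the corresponding EPR signal.
#'
#' @param zfs A [zfs_system()] with half-integer S.
#' @param T_K Temperature(s) in kelvin, > 0.
#' @return Matrix with one row per temperature and one column per doublet
#'   (ordered by zero-field energy), rows summing to 1.
#' @examples
#' doublet_population(zfs_system(3/2, D = 11, E_over_D = 0.33), T_K = 8)
#' @export
doublet_population <- function(zfs, T_K) {
  if (any(!is.finite(T_K)) || any(T_K <= 0))
    stop("'T_K' must be > 0", call. = FALSE)
  en <- .zero_field_doublets(zfs)$energies
  en <- en - min(en)
  pops <- t(vapply(T_K, function(Tt) {
    w <- 2 * exp(-en / (.kB * Tt))    # degeneracy 2 per Kramers doublet
    w / sum(w)
  }, numeric(length(en))))
  colnames(pops) <- paste0("doublet", seq_along(en))
  rownames(pops) <- format(T_K)
  pops
}
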