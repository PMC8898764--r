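#' Magnetometry curve container
#'
#' A typed two-column curve: either molar susceptibility-temperature
#' product chi*T versus temperature, or molar magnetization versus applied
#' field at a fixed measurement temperature.
#'
#' @param abscissa Temperature (K) for susceptibility curves or applied
#'   field (T) for magnetization curves; strictly increasing.
#' @param ordinate chi*T in cm^3 K mol^-1 (>= 0) or M in Bohr magnetons
#'   per molecule.
#' @param kind `"susceptibility"` or `"magnetization"`.
#' @param T_meas Measurement temperature in K (magnetization curves only).
#' @param sigma Optional per-point uncertainty (same units as ordinate).
#' @return Data frame of class `magnetometry_curve` with attributes
#'   `kind` and `T_meas`. Columns are named `T_K`/`chiT_cm3Kmol` or
#'   `H_T`/`M_muB`.
#' @examples
#' magnetometry_curve(seq(2, 290, 2), rep(1, 145), "susceptibility")
#' @export
magnetometry_curve <- function(abscissa, ordinate,
                               kind = c("susceptibility", "magnetization"),
                               T_meas = NULL, sigma = NULL) {
  kind <- match.arg(kind)
  if (length(abscissa) != length(ordinate))
    stop("abscissa and ordinate lengths differ", call. = FALSE)
  if (any(diff(abscissa) <= 0))
    stop("abscissa must be strictly increasing", call. = FALSE)
  if (kind == "susceptibility") {
    if (any(abscissa <= 0)) stop("temperatures must be > 0 K", call. = FALSE)
    if (any(ordinate < 0)) stop("chi*T must be >= 0", call. = FALSE)
    df <- data.frame(T_K = abscissa, chiT_cm3Kmol = ordinate)
  } else {
    if (any(abscissa < 0)) stop("fields must be >= 0 T", call. = FALSE)
    if (is.null(T_meas) || T_meas <= 0)
      stop("magnetization curves need a measurement temperature T_meas > 0",
           call. = FALSE)
    df <- data.frame(H_T = abscissa, M_muB = ordinate)
  }
  if (!is.null(sigma)) {
    if (length(sigma) != nrow(df) || any(sigma < 0))
      stop("'sigma' must be non-negative, one value per point", call. = FALSE)
    df$sigma <- sigma
  }
  attr(df, "kind") <- kind
  attr(df, "T_meas") <- T_meas
  class(df) <- c("magnetometry_curve", "data.frame")
  df
}

#' @export
print.magnetometry_curve <- function(x, ...) {
  kind <- attr(x, "kind")
  cat(sprintf("%s curve, %d points", kind, nrow(x)))
  if (kind == "magnetization")
    cat(sprintf(" at T = %g K", attr(x, "T_meas")))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("... (%d more rows)\n", nrow(x) - 4L))
  invisible(x)
}

#' Van Vleck chi*T over the double-exchange ladder
#'
#' Molar susceptibility-temperature product of the HDE spin ladder,
#' treating each (S, branch) level as an isotropic spin-only paramagnet
#' and Boltzmann-averaging over the full ladder (the Bleaney-Bowers dimer
#' expression generalized to a d5-d6 mixed-valent centre with double
#' exchange):
#' chi*T = C g^2 sum_(S,br) (2S+1) S(S+1) exp(-E/kT) /
#'                sum_(S,br) (2S+1) exp(-E/kT),
#' with C = N_A mu_B^2 / (3 k_B) = 0.125049 cm^3 K mol^-1. The result is
#' invariant under a uniform energy shift of the ladder; Boltzmann weights
#' are computed relative to the ladder minimum so arbitrary J, B scales
#' are overflow-safe.
#'
#' @param system An [exchange_system()].
#' @param g Isotropic electronic g factor shared by all ladder states.
#' @param T_K Temperature grid in kelvin, > 0.
#' @return Numeric vector of chi*T values (cm^3 K mol^-1).
#' @examples
#' chi_t(exchange_system(J = -40, B = 148), g = 2, T_K = c(50, 150, 290))
#' @export
chi_t <- function(system, g = 2, T_K) {
  if (any(!is.finite(T_K)) || any(T_K <= 0))
    stop("'T_K' must be finite and > 0", call. = FALSE)
  ladder <- hde_energies(system)
  E <- ladder$energy - min(ladder$energy)
  mult <- ladder$degeneracy
  SS1 <- ladder$S * (ladder$S + 1)
  vapply(T_K, function(Tt) {
    w <- mult * exp(-E / (.kB * Tt))
    .C0 * g^2 * sum(w * SS1) / sum(w)
  }, 0)
}

#' Fit configuration for chi*T curves
#'
#' @param T_min Minimum temperature (K) included in the fit; data below it
#'   is excluded because the vibronic-free ladder model is unreliable in
#'   the low-temperature regime (default 50 K).
#' @param g Electronic g factor: a fixed value (default 2.0), or NA to fit
#'   it freely.
#' @param r_starts Multi-start grid of initial |B/J| ratios.
#' @param J_start Initial Heisenberg exchange (cm^-1, negative).
#' @param allow_low_T Set TRUE to override the T_min floor deliberately.
#' @param weights Optional per-point weights (after the T_min cut).
#' @return A list of class `chit_fit_config`.
#' @export
chit_fit_config <- function(T_min = 50, g = 2.0,
                            r_starts = seq(0.5, 9.5, by = 1),
                            J_start = -50, allow_low_T = FALSE,
                            weights = NULL) {
  if (T_min < 0) stop("'T_min' must be >= 0", call. = FALSE)
  if (any(r_starts < 0)) stop("'r_starts' must be >= 0", call. = FALSE)
  obj <- list(T_min = T_min, g = g, r_starts = r_starts, J_start = J_start,
              allow_low_T = allow_low_T, weights = weights)
  class(obj) <- "chit_fit_config"
  obj
}

#' Fit the double-exchange susceptibility model to a chi*T curve
#'
#' Weighted least squares of [chi_t()] against measured chi*T, restricted
#' to temperatures above `T_min`. The model is parameterized as (J, r)
#' with B = r|J| because the curve shape over a finite temperature window
#' constrains the ratio r = |B/J| far more robustly than J and B
#' separately; Levenberg-Marquardt refinement is run from a multi-start
#' grid of r values and the best solution is returned together with the
#' residual-norm profile over r.
#'
#' @param curve A susceptibility [magnetometry_curve()].
#' @param config A [chit_fit_config()].
#' @return A list of class `chit_fit` with elements `r` (fitted |B/J|),
#'   `J`, `g`, `se_r` (asymptotic standard error), `rss`, `converged`,
#'   `profile` (data frame r vs rss over the starts), `n_used`, and a
#'   `J_constrained` flag (FALSE when the profile is flat in J).
#' @examples
#' sys <- exchange_system(J = -40, B = 148)
#' tc <- seq(52, 290, 2)
#' crv <- magnetometry_curve(tc, chi_t(sys, 2, tc), "susceptibility")
#' fit_chi_t(crv, chit_fit_config())$r   # recovers 3.7
#' @export
fit_chi_t <- function(curve, config = chit_fit_config()) {
  if (!inherits(curve, "magnetometry_curve") ||
      attr(curve, "kind") != "susceptibility")
    stop("'curve' must be a susceptibility magnetometry_curve", call. = FALSE)
  if (!inherits(config, "chit_fit_config"))
    stop("'config' must be a chit_fit_config", call. = FALSE)
  T_all <- curve$T_K
  keep <- if (config$allow_low_T) rep(TRUE, length(T_all)) else T_all > config$T_min
  Tt <- T_all[keep]
  y  <- curve$chiT_cm3Kmol[keep]
  if (length(Tt) < 10L)
    stop("need at least 10 points above T_min to fit", call. = FALSE)
  if (stats::sd(y) < 1e-12)
    stop("degenerate data: chi*T is constant over the fit window", call. = FALSE)
  w <- config$weights
  if (is.null(w)) w <- rep(1, length(Tt))
  if (length(w) != length(Tt))
    stop("'weights' length must match the points above T_min", call. = FALSE)
  spins <- local_spin_pair()
  fit_g <- is.na(config$g)

  model <- function(par) {
    J <- -abs(par[["J"]]); r <- abs(par[["r"]])
    g <- if (fit_g) abs(par[["g"]]) else config$g
    chi_t(exchange_system(J = J, B = r * abs(J), spins = spins), g = g, T_K = Tt)
  }
  resid_fn <- function(par) sqrt(w) * (y - model(par))

  runs <- lapply(config$r_starts, function(r0) {
    start <- c(J = config$J_start, r = r0)
    if (fit_g) start <- c(start, g = 2)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(fit = fit, r0 = r0, rss = sum(fit$fvec^2))
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs))
    stop("chi*T fit failed to converge from every start", call. = FALSE)
  profile <- data.frame(
    r_start = vapply(runs, `[[`, 0, "r0"),
    r_hat   = vapply(runs, function(x) abs(x$fit$par[["r"]]), 0),
    rss     = vapply(runs, `[[`, 0, "rss"))
  best <- runs[[which.min(profile$rss)]]$fit
  pars <- best$par
  J_hat <- -abs(pars[["J"]]); r_hat <- abs(pars[["r"]])
  g_hat <- if (fit_g) abs(pars[["g"]]) else config$g

  # asymptotic se on r from the Gauss-Newton hessian at the optimum
  se_r <- NA_real_
  cov <- tryCatch({
    dof <- max(length(Tt) - length(pars), 1L)
    chol2inv(chol(best$hessian)) * best$deviance / dof
  }, error = function(e) NULL)
  if (!is.null(cov)) {
    dimnames(cov) <- list(names(pars), names(pars))
    se_r <- sqrt(abs(cov["r", "r"]))
  }
  # J identifiability: relative spread of fitted J across converged starts
  J_hats <- vapply(runs, function(x) -abs(x$fit$par[["J"]]), 0)
  ok <- profile$rss <= min(profile$rss) * (1 + 1e-4)
  J_constrained <- length(unique(round(J_hats[ok], 3))) == 1L

  out <- list(r = r_hat, J = J_hat, g = g_hat, se_r = se_r,
              rss = min(profile$rss),
              converged = best$info %in% 1:4,
              profile = profile, n_used = length(Tt),
              J_constrained = J_constrained)
  class(out) <- "chit_fit"
  if (!out$converged)
    warning("chi*T fit did not report convergence", call. = FALSE)
  if (!J_constrained)
    warning("J is not well constrained by the data; trust the ratio r only",
            call. = FALSE)
  out
}

#' @export
print.chit_fit <- function(x, ...) {
  cat(sprintf("Double-exchange chi*T fit (%d points): |B/J| = %.3f +/- %.3f, J = %.2f cm^-1, g = %.3f\n",
              x$n_used, x$r, x$se_r, x$J, x$g))
  cat(sprintf("  rss = %.4g, converged = %s, J constrained = %s\n",
              x$rss, x$converged, x$J_constrained))
  invisible(x)
}

#' Single-orientation magnetization of a ZFS spin system
#'
#' Thermal-average magnetic moment projected on the applied field,
#' obtained by full diagonalization of the ZFS + Zeeman Hamiltonian and
#' the Hellmann-Feynman expectation of the moment operator
#' m_u = -(gx ux Sx + gy uy Sy + gz uz Sz) (in Bohr magnetons), not by
#' numerical differentiation of the energies.
#'
#' @param zfs A [zfs_system()].
#' @param H Applied field magnitude in tesla (>= 0; vectorized).
#' @param direction Field direction (3-vector, any norm > 0).
#' @param T_K Temperature in kelvin.
#' @return Moment along the field in Bohr magnetons per molecule, one
#'   value per field in `H`.
#' @examples
#' zeeman_magnetization(zfs_system(3/2), H = 7, direction = c(0, 0, 1),
#'                      T_K = 0.01)   # ~3 muB: saturation at g S
#' @export
zeeman_magnetization <- function(zfs, H, direction = c(0, 0, 1), T_K = 2) {
  if (!inherits(zfs, "zfs_system"))
    stop("'zfs' must be a zfs_system", call. = FALSE)
  if (any(H < 0)) stop("'H' must be >= 0", call. = FALSE)
  if (length(T_K) != 1L || T_K <= 0) stop("'T_K' must be > 0", call. = FALSE)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("'direction' must be a nonzero 3-vector", call. = FALSE)
  u <- direction / nrm
  sm <- spin_matrices(zfs$S)
  # moment operator along u, in muB units
  Mop <- -(zfs$g[1] * u[1] * sm$Sx + zfs$g[2] * u[2] * sm$Sy +
           zfs$g[3] * u[3] * sm$Sz)
  vapply(H, function(h) {
    eg <- eigen(zfs_hamiltonian(zfs, h * u), symmetric = TRUE)
    E <- eg$values - min(eg$values)
    w <- exp(-E / (.kB * T_K)); w <- w / sum(w)
    m_i <- vapply(seq_len(sm$n), function(i) {
      v <- eg$vectors[, i]
      Re(Conj(v) %*% Mop %*% v)[1]
    }, 0)
    sum(w * m_i)
  }, 0)
}

#' Fibonacci sphere orientation grid
#'
#' Near-uniform unit vectors on the sphere for powder averaging.
#'
#' @param n Number of orientations (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n = 500L) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Powder-averaged magnetization
#'
#' Orientation average of [zeeman_magnetization()] over a sphere grid,
#' modelling the random crystallite orientations of a powder sample, along
#' with the maximum single-orientation moment (the moment along the main
#' magnetization axis). The powder average can never exceed that maximum.
#'
#' @param zfs A [zfs_system()].
#' @param H Applied field magnitude(s) in tesla.
#' @param T_K Temperature in kelvin.
#' @param orientations Orientation grid: an integer (Fibonacci grid size,
#'   default 500) or an n x 3 matrix of directions.
#' @return A list with `H`, `M_powder`, `M_max` (both in muB per molecule,
#'   per field) and `n_orientations`.
#' @examples
#' pm <- powder_moment(zfs_system(3/2, D = 11, E_over_D = 0.33), H = 7)
#' pm$M_powder <= pm$M_max
#' @export
powder_moment <- function(zfs, H, T_K = 2, orientations = 500L) {
  if (is.numeric(orientations) && length(orientations) == 1L) {
    n <- as.integer(orientations)
    if (n < 50L)
      warning("orientation grid with < 50 points is too coarse for a powder average",
              call. = FALSE)
    grid <- fibonacci_sphere(max(n, 1L))
  } else {
    grid <- as.matrix(orientations)
    if (ncol(grid) != 3L) stop("'orientations' must be n x 3", call. = FALSE)
    if (nrow(grid) < 50L)
      warning("orientation grid with < 50 points is too coarse for a powder average",
              call. = FALSE)
    grid <- grid / sqrt(rowSums(grid^2))
  }
  M <- vapply(seq_len(nrow(grid)), function(i)
    zeeman_magnetization(zfs, H, direction = grid[i, ], T_K = T_K),
    numeric(length(H)))
  M <- matrix(M, nrow = length(H))
  list(H = H,
       M_powder = rowMeans(M),
       M_max = apply(M, 1L, max),
       n_orientations = nrow(grid))
}

#' Weighted mixture of magnetometry responses
#'
#' Pointwise convex combination of curves measured per molecule, modelling
#' a physical mixture of spin isomers (for example a frozen solution
#' containing equal S = 1/2 and S = 3/2 populations of the same complex).
#'
#' @param curves List of [magnetometry_curve()] objects sharing kind and
#'   abscissa.
#' @param weights Non-negative weights summing to 1, one per curve.
#' @return A [magnetometry_curve()] of the same kind.
#' @examples
#' tc <- seq(2, 290, 2)
#' a <- magnetometry_curve(tc, rep(0.3751, length(tc)), "susceptibility")
#' b <- magnetometry_curve(tc, rep(1.8757, length(tc)), "susceptibility")
#' mixture_response(list(a, b), c(0.5, 0.5))
#' @export
mixture_response <- function(curves, weights) {
  if (!is.list(curves) || !length(curves) ||
      !all(vapply(curves, inherits, TRUE, "magnetometry_curve")))
    stop("'curves' must be a list of magnetometry_curve objects", call. = FALSE)
  if (length(weights) != length(curves) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("'weights' must be >= 0 and sum to 1, one per curve", call. = FALSE)
  kinds <- vapply(curves, attr, "", "kind")
  if (length(unique(kinds)) != 1L)
    stop("all curves must share the same kind", call. = FALSE)
  ab <- lapply(curves, function(cv) cv[[1L]])
  if (!all(vapply(ab[-1L], function(a)
        length(a) == length(ab[[1L]]) && max(abs(a - ab[[1L]])) < 1e-9, TRUE)))
    stop("curves have mismatched abscissae", call. = FALSE)
  ord <- Reduce(`+`, Map(function(cv, w) w * cv[[2L]], curves, weights))
  magnetometry_curve(ab[[1L]], ord, kind = kinds[1L],
                     T_meas = attr(curves[[1L]], "T_meas"))
}
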