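#' Local spin pair of a mixed-valent dimer
#'
#' Defines the two site spins of an exchange-coupled dimer. The default
#' (5/2, 2) is the locally high-spin ferric/ferrous pair of a reduced
#' [Fe2Q2]+ cluster; the itinerant electron couples the sites so that the
#' allowed total spins run from |s_a - s_b| to s_a + s_b in unit steps
#' (1/2 ... 9/2 for the default).
#'
#' @param s_a Site spin of the ferric (d5) centre; integer or half-integer.
#' @param s_b Site spin of the ferrous (d6) centre; integer or half-integer.
#' @return An object of class `local_spin_pair` with fields `s_a`, `s_b`
#'   and the vector `S_allowed` of total spin quantum numbers.
#' @examples
#' local_spin_pair()            # Fe3+(5/2)-Fe2+(2)
#' local_spin_pair(1/2, 1)$S_allowed
#' @export
local_spin_pair <- function(s_a = 5/2, s_b = 2) {
  if (!.is_half_integral(s_a))
    stop("'s_a' must be a non-negative integer or half-integer spin", call. = FALSE)
  if (!.is_half_integral(s_b))
    stop("'s_b' must be a non-negative integer or half-integer spin", call. = FALSE)
  obj <- list(s_a = s_a, s_b = s_b,
              S_allowed = seq(abs(s_a - s_b), s_a + s_b, by = 1))
  class(obj) <- "local_spin_pair"
  obj
}

#' @export
print.local_spin_pair <- function(x, ...) {
  cat(sprintf("Local spin pair s_a = %s, s_b = %s; total S = %s\n",
              format(x$s_a), format(x$s_b),
              paste(format(x$S_allowed), collapse = ", ")))
  invisible(x)
}

#' Heisenberg double-exchange system
#'
#' Bundles a local spin pair with the Heisenberg exchange constant J
#' (in the -2J S1.S2 convention; J < 0 antiferromagnetic) and the
#' double-exchange (resonance delocalization) parameter B. The physical
#' spectrum depends only on |B|, so a negative B is absolute-valued with a
#' warning.
#'
#' @param J Heisenberg exchange, cm^-1 (signed).
#' @param B Double-exchange parameter, cm^-1 (>= 0).
#' @param spins A [local_spin_pair()].
#' @return An object of class `exchange_system` with fields `spins`, `J`,
#'   `B`, and `ratio` = |B/J| (Inf when J = 0 and B > 0, NaN when both 0).
#' @examples
#' exchange_system(J = -40, B = 148)   # |B/J| = 3.7
#' @export
exchange_system <- function(J, B, spins = local_spin_pair()) {
  if (!inherits(spins, "local_spin_pair"))
    stop("'spins' must be a local_spin_pair", call. = FALSE)
  if (!is.numeric(J) || length(J) != 1L || !is.finite(J))
    stop("'J' must be a single finite number (cm^-1)", call. = FALSE)
  if (!is.numeric(B) || length(B) != 1L || !is.finite(B))
    stop("'B' must be a single finite number (cm^-1)", call. = FALSE)
  if (B < 0) {
    warning("'B' is a magnitude; taking |B|", call. = FALSE)
    B <- abs(B)
  }
  ratio <- if (J != 0) abs(B / J) else if (B > 0) Inf else NaN
  obj <- list(spins = spins, J = J, B = B, ratio = ratio)
  class(obj) <- "exchange_system"
  obj
}

#' @export
print.exchange_system <- function(x, ...) {
  cat(sprintf("HDE system: J = %g cm^-1, B = %g cm^-1 (|B/J| = %s), spins (%s, %s)\n",
              x$J, x$B, format(x$ratio), format(x$spins$s_a), format(x$spins$s_b)))
  invisible(x)
}

#' Heisenberg double-exchange energy ladder
#'
#' Evaluates the eigenvalues E(S, +/-) = -J S(S+1) +/- B (S + 1/2) for every
#' allowed total spin S of the dimer. Double exchange splits each Heisenberg
#' level into a symmetric/antisymmetric pair separated by 2B(S + 1/2); with
#' B >= 0 the "-" branch lies at or below the "+" branch.
#'
#' @param system An [exchange_system()].
#' @return An object of class `spin_ladder`: a data frame with columns
#'   `S`, `branch` ("-"/"+"), `energy` (cm^-1) and `degeneracy` (2S+1),
#'   ordered by energy, with the generating `system` attached as an
#'   attribute.
#' @examples
#' hde_energies(exchange_system(J = -1, B = 3.7))
#' @export
hde_energies <- function(system) {
  if (!inherits(system, "exchange_system"))
    stop("'system' must be an exchange_system", call. = FALSE)
  S <- system$spins$S_allowed
  ladder <- data.frame(
    S          = rep(S, each = 2L),
    branch     = rep(c("-", "+"), times = length(S)),
    stringsAsFactors = FALSE
  )
  sgn <- ifelse(ladder$branch == "+", 1, -1)
  ladder$energy     <- -system$J * ladder$S * (ladder$S + 1) +
                        sgn * system$B * (ladder$S + 0.5)
  ladder$degeneracy <- 2 * ladder$S + 1
  ladder <- ladder[order(ladder$energy, ladder$S), , drop = FALSE]
  rownames(ladder) <- NULL
  attr(ladder, "system") <- system
  class(ladder) <- c("spin_ladder", "data.frame")
  ladder
}

#' @export
print.spin_ladder <- function(x, ...) {
  sys <- attr(x, "system")
  cat(sprintf("HDE spin ladder (J = %g, B = %g cm^-1): %d levels, %d states\n",
              sys$J, sys$B, nrow(x), sum(x$degeneracy)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Ground spin of the double-exchange ladder
#'
#' Returns the total spin S of the minimum-energy level of the HDE ladder.
#' At an exact level crossing (two spins sharing the minimum energy) the
#' lower spin is reported and the result carries attribute
#' `degenerate = TRUE`, so phase boundaries are assigned reproducibly.
#'
#' @param system An [exchange_system()].
#' @param tol Energy degeneracy tolerance in cm^-1 (relative to the energy
#'   scale of the ladder).
#' @return The ground total spin quantum number (numeric scalar), with
#'   attribute `degenerate` flagging an exact crossing.
#' @examples
#' ground_spin(exchange_system(J = -1, B = 2.0))  # 1/2
#' ground_spin(exchange_system(J = -1, B = 3.7))  # 3/2
#' @export
ground_spin <- function(system, tol = 1e-9) {
  ladder <- hde_energies(system)
  e_min  <- min(ladder$energy)
  scale  <- max(1, max(abs(ladder$energy)))
  at_min <- ladder$S[ladder$energy - e_min <= tol * scale]
  out <- min(at_min)
  attr(out, "degenerate") <- length(unique(at_min)) > 1L
  out
}

#' Ground-spin crossing ratios of the antiferromagnetic ladder
#'
#' For J < 0 the lower ("-") branch minimum moves to higher S as |B/J|
#' grows; the ground spin steps from S to S+1 where the branch energies
#' cross, at |B/J| = 2(S + 1). For the (5/2, 2) pair the crossings sit at
#' 3, 5, 7 and 9, bracketing the intermediate-spin window 3 <= |B/J| <= 9.
#'
#' @param spins A [local_spin_pair()].
#' @return Numeric vector of |B/J| crossing ratios in increasing order
#'   (empty when only one total spin is allowed).
#' @examples
#' crossing_ratios(local_spin_pair())      # 3 5 7 9
#' crossing_ratios(local_spin_pair(1/2, 1))  # 3
#' @export
crossing_ratios <- function(spins = local_spin_pair()) {
  if (!inherits(spins, "local_spin_pair"))
    stop("'spins' must be a local_spin_pair", call. = FALSE)
  S <- spins$S_allowed
  if (length(S) < 2L) return(numeric(0))
  2 * (S[-length(S)] + 1)
}

#' Ground-spin phase diagram versus |B/J|
#'
#' Maps a grid of |B/J| ratios to the ground total spin. For J > 0 the
#' ferromagnetic ladder has the maximal spin everywhere; for J < 0 the
#' ground spin is a non-decreasing step function of the ratio with steps at
#' [crossing_ratios()].
#'
#' @param spins A [local_spin_pair()].
#' @param ratios Non-negative numeric grid of |B/J| values.
#' @param J_sign Sign of J: `-1` (antiferromagnetic, default) or `+1`.
#' @return Data frame with columns `ratio`, `ground_S` and `degenerate`.
#' @examples
#' phase_diagram(ratios = c(1, 4, 6, 8, 10))
#' @export
phase_diagram <- function(spins = local_spin_pair(), ratios, J_sign = -1) {
  if (any(!is.finite(ratios)) || any(ratios < 0))
    stop("'ratios' must be finite and >= 0", call. = FALSE)
  if (!J_sign %in% c(-1, 1))
    stop("'J_sign' must be -1 or +1", call. = FALSE)
  S <- spins$S_allowed
  # with B >= 0 the "-" branch always bounds the "+" branch from below,
  # so the ground level lies on E-(S) = -J S(S+1) - B(S+1/2); vectorized
  # over the ratio grid with |J| = 1
  E <- outer(ratios, S + 0.5, `*`) * (-1)
  E <- sweep(E, 2L, -J_sign * S * (S + 1), `+`)
  e_min <- apply(E, 1L, min)
  scale <- pmax(1, apply(abs(E), 1L, max))
  at_min <- E <= e_min + 1e-9 * scale
  idx <- apply(at_min, 1L, which.max)          # first TRUE = lowest S
  data.frame(ratio = ratios, ground_S = S[idx],
             degenerate = rowSums(at_min) > 1L)
}
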