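#' Spin angular-momentum matrices
#'
#' Matrix representations of Sx, Sy, Sz (and the ladder operators) in the
#' |S, m> basis ordered m = S, S-1, ..., -S. Sy is complex; all satisfy the
#' usual commutation relations and Sx^2 + Sy^2 + Sz^2 = S(S+1) I.
#'
#' @param S Spin quantum number (integer or half-integer >= 0).
#' @return A list with complex matrices `Sx`, `Sy`, `Sz`, `Sp`, `Sm` and
#'   the dimension `n` = 2S+1.
#' @examples
#' spin_matrices(1/2)$Sz   # diag(1/2, -1/2)
#' @export
spin_matrices <- function(S) {
  if (!.is_half_integral(S))
    stop("'S' must be a non-negative integer or half-integer", call. = FALSE)
  m <- seq(S, -S, by = -1)
  n <- length(m)
  Sz <- diag(m + 0i, nrow = n)
  Sp <- matrix(0i, n, n)
  if (n > 1L)
    for (i in 2:n) Sp[i - 1L, i] <- sqrt(S * (S + 1) - m[i] * (m[i] + 1)) + 0i
  Sm <- Conj(t(Sp))
  list(Sx = (Sp + Sm) / 2, Sy = (Sp - Sm) / (2i), Sz = Sz, Sp = Sp, Sm = Sm,
       n = n)
}
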