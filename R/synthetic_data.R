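#' Synthetic magnetometry generator configuration
#'
#' Defines the conditions under which synthetic SQUID observables are
#' generated. The three named fixtures reproduce the study conditions of
#' the [Fe2Q2]+ series: fitted |B/J| ratios 2.0 (complex1, Q = S), 2.9
#' (complex2, Q = Se) and 3.7 (complex3, Q = Te), an assumed Heisenberg
#' scale J = -40 cm^-1 (only the ratio is published; -40 cm^-1 is a
#' typical [Fe2S2]+ magnitude), temperatures 2-290 K and fields 0.1-7 T at
#' 2 K, with 1% multiplicative Gaussian noise. complex2 additionally
#' carries 50:50 spin-isomer mixture weights of S = 1/2 and ZFS-split
#' S = 3/2 (D = +11 cm^-1, E/D = 0.12) components for magnetization
#' curves.
#'
#' @param fixture `"complex1"`, `"complex2"`, `"complex3"` or `"custom"`.
#' @param J Heisenberg exchange (cm^-1); fixtures use -40.
#' @param r Double-exchange ratio |B/J|; fixture defaults 2.0/2.9/3.7.
#' @param g Electronic g; fixture defaults 1.90/1.92/2.00 (the EPR g_iso
#'   of the matching complex).
#' @param sigma_rel Relative Gaussian noise level (default 0.01).
#' @param T_grid Temperature grid (K), default 2-290 K in 2 K steps.
#' @param H_grid Field grid (T), default 0.1-7 T.
#' @param T_mag Magnetization measurement temperature (K), default 2.
#' @param mixture For complex2: list with `weights` and the two component
#'   `zfs` systems used for magnetization curves.
#' @param seed Integer random seed (required for noisy generation).
#' @return A list of class `generator_config`.
#' @examples
#' generator_config("complex3", seed = 1)
#' @export
generator_config <- function(fixture = c("custom", "complex1", "complex2",
                                         "complex3"),
                             J = -40, r = NULL, g = NULL, sigma_rel = 0.01,
                             T_grid = seq(2, 290, by = 2),
                             H_grid = seq(0.1, 7, by = 0.1),
                             T_mag = 2, mixture = NULL, seed = NULL) {
  fixture <- match.arg(fixture)
  defaults <- list(
    complex1 = list(r = 2.0, g = 1.90),
    complex2 = list(r = 2.9, g = 1.92),
    complex3 = list(r = 3.7, g = 2.00)
  )
  if (fixture != "custom") {
    if (is.null(r)) r <- defaults[[fixture]]$r
    if (is.null(g)) g <- defaults[[fixture]]$g
  }
  if (is.null(r) || is.null(g))
    stop("custom fixtures must specify 'r' and 'g'", call. = FALSE)
  if (sigma_rel < 0) stop("'sigma_rel' must be >= 0", call. = FALSE)
  if (any(T_grid <= 0) || any(T_grid > 400))
    stop("'T_grid' must lie in the instrument range (0, 400] K", call. = FALSE)
  if (any(H_grid < 0) || any(H_grid > 7 + 1e-9))
    stop("'H_grid' must lie in the instrument range [0, 7] T", call. = FALSE)
  if (fixture == "complex2" && is.null(mixture))
    mixture <- list(weights = c(0.5, 0.5),
                    zfs = list(zfs_system(1/2, g = 1.92),
                               zfs_system(3/2, D = 11, E_over_D = 0.12,
                                          g = 1.92)))
  obj <- list(fixture = fixture, J = J, r = r, g = g, sigma_rel = sigma_rel,
              T_grid = T_grid, H_grid = H_grid, T_mag = T_mag,
              mixture = mixture, seed = seed)
  class(obj) <- "generator_config"
  obj
}

.set_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
}

#' Generate a synthetic chi*T curve
#'
#' Simulates a variable-temperature molar susceptibility measurement:
#' [chi_t()] of the fixture's HDE ladder over the temperature grid, with
#' multiplicative Gaussian noise chiT * (1 + sigma_rel * eps). The exact
#' generating parameters travel with the curve as a ground-truth record.
#'
#' @param config A [generator_config()].
#' @return A list with `curve` (a susceptibility [magnetometry_curve()])
#'   and `truth` (list of J, B, r, g, sigma_rel, seed).
#' @examples
#' gc <- generator_config("complex3", seed = 7)
#' sim <- generate_chit(gc)
#' @export
generate_chit <- function(config) {
  if (!inherits(config, "generator_config"))
    stop("'config' must be a generator_config", call. = FALSE)
  sys <- exchange_system(J = config$J, B = config$r * abs(config$J))
  mu <- chi_t(sys, g = config$g, T_K = config$T_grid)
  .set_seed(config$seed)
  eps <- if (config$sigma_rel > 0) stats::rnorm(length(mu)) else numeric(length(mu))
  y <- mu * (1 + config$sigma_rel * eps)
  y <- pmax(y, 0)
  curve <- magnetometry_curve(config$T_grid, y, "susceptibility",
                              sigma = config$sigma_rel * mu)
  list(curve = curve,
       truth = list(J = config$J, B = config$r * abs(config$J), r = config$r,
                    g = config$g, sigma_rel = config$sigma_rel,
                    seed = config$seed))
}

#' Generate a synthetic powder magnetization curve
#'
#' Simulates a 2 K field sweep: [powder_moment()] of the fixture's spin
#' system (or a weighted spin-isomer mixture) over the field grid, with
#' multiplicative Gaussian noise. For fixtures without an explicit
#' mixture, a single system is used: S = 1/2 for complex1, and the
#' ZFS-split S = 3/2 (D = +11 cm^-1) for complex3.
#'
#' @param config A [generator_config()].
#' @param orientations Orientation grid passed to [powder_moment()].
#' @return A list with `curve` (a magnetization [magnetometry_curve()])
#'   and `truth` (components, weights, sigma_rel, seed).
#' @export
generate_magnetization <- function(config, orientations = 500L) {
  if (!inherits(config, "generator_config"))
    stop("'config' must be a generator_config", call. = FALSE)
  comps <- if (!is.null(config$mixture)) {
    config$mixture
  } else if (config$fixture == "complex3") {
    list(weights = 1,
         zfs = list(zfs_system(3/2, D = 11, E_over_D = 1/3, g = config$g)))
  } else {
    list(weights = 1, zfs = list(zfs_system(1/2, g = config$g)))
  }
  M <- Reduce(`+`, Map(function(z, w)
    w * powder_moment(z, H = config$H_grid, T_K = config$T_mag,
                      orientations = orientations)$M_powder,
    comps$zfs, comps$weights))
  .set_seed(config$seed)
  eps <- if (config$sigma_rel > 0) stats::rnorm(length(M)) else numeric(length(M))
  y <- M * (1 + config$sigma_rel * eps)
  curve <- magnetometry_curve(config$H_grid, y, "magnetization",
                              T_meas = config$T_mag,
                              sigma = config$sigma_rel * abs(M))
  list(curve = curve,
       truth = list(components = comps, sigma_rel = config$sigma_rel,
                    seed = config$seed))
}
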