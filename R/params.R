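#' Dimensionless control parameters of the crypt shape model
#'
#' Bundles the dimensionless parameters governing organoid crypt energetics:
#' the crypt cell fraction `phi`, the crypt-to-villus in-plane tension ratio
#' `alpha`, the crypt apicobasal differential tension `sigma_c`, the total
#' cell count `n_t`, and optionally the crypt in-plane-to-lateral tension
#' ratio `kappa` = (Gamma_a + Gamma_b)/Gamma_l.
#'
#' When both `kappa` and an `epsilon` (tension asymmetry) are supplied,
#' `sigma_c` is derived from the identity
#' sigma_c = (1/2) epsilon kappa sqrt(4 pi / n_t); if `sigma_c` is also
#' given the two must agree.
#'
#' @param sigma_c crypt differential tension (dimensionless, >= 0)
#' @param alpha in-plane tension ratio crypt/villus (> 0)
#' @param phi crypt cell fraction, in (0, 1)
#' @param n_t total number of cells in the organoid (>= 2)
#' @param kappa crypt (Gamma_a + Gamma_b)/Gamma_l, optional (> 0)
#' @param epsilon crypt tension asymmetry, optional, in [-1, 1]
#' @return an object of class `landscape_params`
#' @export
landscape_params <- function(sigma_c = NULL, alpha = 2, phi = 0.2, n_t = 400,
                             kappa = NULL, epsilon = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0)
  stopifnot(is.numeric(phi), length(phi) == 1, phi > 0, phi < 1)
  stopifnot(is.numeric(n_t), length(n_t) == 1, n_t >= 2)
  if (!is.null(kappa)) stopifnot(is.numeric(kappa), kappa > 0)
  if (!is.null(epsilon)) {
    stopifnot(is.numeric(epsilon), abs(epsilon) <= 1)
    if (is.null(kappa))
      stop("'epsilon' requires 'kappa' to derive sigma_c", call. = FALSE)
    sc_derived <- sigma_c_from_epsilon(epsilon, kappa, n_t)
    if (is.null(sigma_c)) sigma_c <- sc_derived
    else if (abs(sigma_c - sc_derived) > 1e-10 * max(1, abs(sigma_c)))
      stop("inconsistent sigma_c / (epsilon, kappa) pair", call. = FALSE)
  }
  if (is.null(sigma_c)) sigma_c <- 0
  stopifnot(is.numeric(sigma_c), length(sigma_c) == 1, sigma_c >= 0)
  structure(list(sigma_c = sigma_c, alpha = alpha, phi = phi, n_t = n_t,
                 kappa = kappa),
            class = "landscape_params")
}

#' @export
print.landscape_params <- function(x, ...) {
  cat(sprintf(
    "landscape_params: sigma_c=%.4g alpha=%.3g phi=%.3g n_t=%d%s\n",
    x$sigma_c, x$alpha, x$phi, as.integer(x$n_t),
    if (is.null(x$kappa)) "" else sprintf(" kappa=%.3g", x$kappa)))
  invisible(x)
}

#' Convert a tension asymmetry to a differential tension
#'
#' sigma_c = (1/2) epsilon kappa sqrt(4 pi / n_t), where epsilon is the
#' crypt apicobasal tension asymmetry and kappa = (Gamma_a + Gamma_b)/Gamma_l.
#'
#' @param epsilon tension asymmetry in [-1, 1]
#' @param kappa in-plane-to-lateral tension ratio (> 0)
#' @param n_t total cell count
#' @return sigma_c
#' @export
sigma_c_from_epsilon <- function(epsilon, kappa, n_t) {
  stopifnot(all(abs(epsilon) <= 1), kappa > 0, n_t >= 2)
  0.5 * epsilon * kappa * sqrt(4 * pi / n_t)
}

#' Inverse of [sigma_c_from_epsilon()]
#' @param sigma_c differential tension
#' @inheritParams sigma_c_from_epsilon
#' @return epsilon
#' @export
epsilon_from_sigma_c <- function(sigma_c, kappa, n_t) {
  stopifnot(kappa > 0, n_t >= 2)
  2 * sigma_c / (kappa * sqrt(4 * pi / n_t))
}

#' Per-region surface tensions
#'
#' Apical, basal and lateral surface tensions of one epithelial region, in
#' units of the lateral tension Gamma_l.
#'
#' @param gamma_a apical tension (>= 0 unless `allow_negative`)
#' @param gamma_b basal tension (>= 0 unless `allow_negative`)
#' @param gamma_l lateral tension (> 0), reference scale
#' @param allow_negative allow a negative apical or basal tension
#'   (adhesion-dominated interface)
#' @return object of class `region_tensions`
#' @export
region_tensions <- function(gamma_a, gamma_b, gamma_l = 1,
                            allow_negative = FALSE) {
  stopifnot(gamma_l > 0)
  if (!allow_negative && (gamma_a < 0 || gamma_b < 0))
    stop("negative apical/basal tension; use allow_negative = TRUE",
         call. = FALSE)
  structure(list(gamma_a = gamma_a, gamma_b = gamma_b, gamma_l = gamma_l),
            class = "region_tensions")
}

#' Apicobasal tension asymmetry of a region
#'
#' epsilon = (Gamma_a - Gamma_b)/(Gamma_a + Gamma_b); lies in [-1, 1] when
#' both tensions are non-negative.
#'
#' @param tensions a `region_tensions` object
#' @return epsilon
#' @export
tension_asymmetry <- function(tensions) {
  with(tensions, (gamma_a - gamma_b) / (gamma_a + gamma_b))
}

#' Regional tensions implied by the dimensionless parameters
#'
#' Inverts the nondimensionalization: the villus is apicobasally symmetric
#' with (Gamma_a + Gamma_b)_v = 1; the crypt has (Gamma_a + Gamma_b)_c =
#' alpha and (Gamma_a - Gamma_b)_c = 2 sigma_c sqrt(n_t / 4 pi).
#' Gamma_l = 1 in both regions.
#'
#' @param p a [landscape_params()] object
#' @param allow_negative permit a crypt basal tension below zero
#'   (asymmetry > 1); by default this errors
#' @return list with `crypt` and `villus` [region_tensions()]
#' @export
build_tensions <- function(p, allow_negative = FALSE) {
  stopifnot(inherits(p, "landscape_params"))
  diffc <- 2 * p$sigma_c * sqrt(p$n_t / (4 * pi))
  gb <- (p$alpha - diffc) / 2
  if (gb < 0 && !allow_negative)
    stop(sprintf(
      "crypt basal tension %.4g < 0 (tension asymmetry > 1); sigma_c too large for alpha=%.3g, n_t=%d",
      gb, p$alpha, as.integer(p$n_t)), call. = FALSE)
  list(
    crypt = region_tensions((p$alpha + diffc) / 2, gb,
                            allow_negative = allow_negative),
    villus = region_tensions(0.5, 0.5)
  )
}

#' Recover dimensionless parameters from regional tensions
#'
#' Inverse of [build_tensions()]; exact round-trip.
#'
#' @param tensions list with `crypt` and `villus` `region_tensions`
#' @param phi crypt cell fraction
#' @param n_t total cell count
#' @return a [landscape_params()] object
#' @export
tensions_to_params <- function(tensions, phi, n_t) {
  cr <- tensions$crypt; vl <- tensions$villus
  alpha <- (cr$gamma_a + cr$gamma_b) / (vl$gamma_a + vl$gamma_b)
  sigma_c <- 0.5 * (cr$gamma_a - cr$gamma_b) / cr$gamma_l * sqrt(4 * pi / n_t)
  landscape_params(sigma_c = sigma_c, alpha = alpha, phi = phi, n_t = n_t,
                   kappa = (cr$gamma_a + cr$gamma_b) / cr$gamma_l)
}
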