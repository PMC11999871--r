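#' Curvature-dependent mechanosensitive tension law
#'
#' sigma_c = sigma (R_c / R0_ref)^(-n): the crypt differential tension is
#' set by an intrinsic, fate-determined value `sigma` modulated by the
#' crypt radius of curvature. `n = 0` disables the feedback. The reference
#' radius `r0_ref` is the crypt-region radius of curvature before
#' morphogenesis; the default 1.4 R0 is the midplane radius of the swollen
#' spherical organoid at the measured bulged volume v ~ 2.8.
#'
#' @param sigma intrinsic differential tension (>= 0)
#' @param n coupling exponent (>= 0)
#' @param r0_ref reference crypt radius (> 0), units of R0
#' @return object of class `mechano_law`
#' @export
mechano_law <- function(sigma, n = 1, r0_ref = 1.4) {
  stopifnot(is.numeric(sigma), sigma >= 0, is.numeric(n), n >= 0, r0_ref > 0)
  structure(list(sigma = sigma, n = n, r0_ref = r0_ref),
            class = "mechano_law")
}

#' @export
print.mechano_law <- function(x, ...) {
  cat(sprintf("mechano_law: sigma=%.4g n=%.3g r0_ref=%.3g\n",
              x$sigma, x$n, x$r0_ref))
  invisible(x)
}

#' Effective differential tension at a given crypt radius
#'
#' @param law a [mechano_law()]
#' @param r_c crypt radius of curvature (> 0)
#' @return sigma_c = sigma (r_c / r0_ref)^(-n)
#' @export
sigma_c_effective <- function(law, r_c) {
  if (any(r_c <= 0)) stop("r_c must be positive", call. = FALSE)
  law$sigma * (r_c / law$r0_ref)^(-law$n)
}

#' Tension-asymmetry threshold for remaining budded under inflation
#'
#' Converts the closed-form budded onset of the effective landscape into a
#' tension asymmetry: epsilon* = 2 budded_threshold(phi, alpha, n) /
#' (kappa sqrt(4 pi / n_t)). Organoids whose crypt asymmetry exceeds
#' epsilon* stay in the budded/bistable region of the phase diagram on
#' arbitrary lumen inflation; epsilon* decreases with the coupling
#' strength n.
#'
#' @inheritParams budded_threshold
#' @param kappa crypt in-plane-to-lateral tension ratio
#' @param n_t total cell count
#' @return epsilon*
#' @export
epsilon_threshold <- function(phi, alpha, n, kappa, n_t) {
  stopifnot(kappa > 0, n_t >= 2)
  2 * budded_threshold(phi, alpha, n) / (kappa * sqrt(4 * pi / n_t))
}

#' Self-consistent mechanosensitive equilibria at a given volume
#'
#' Equilibrium shapes under the feedback law, obtained from the effective
#' landscape in which sigma_c(R_c) is substituted into the energy
#' (quasistatic tension equilibration). Every returned state satisfies
#' sigma_c = sigma (R_c/R0_ref)^(-n) exactly.
#'
#' @param v normalized lumen volume
#' @param law a [mechano_law()]
#' @param model an [organoid_model()]
#' @return data.frame of equilibria as in [find_equilibria()], with
#'   additional columns `sigma_c` (effective) and `epsilon`
#' @export
selfconsistent_states <- function(v, law, model = organoid_model()) {
  eq <- find_equilibria(v, sigma_c = law$sigma, model = model, law = law)
  if (nrow(eq) == 0) return(eq)
  eq$sigma_c <- sigma_c_effective(law, eq$r_c)
  eq$epsilon <- epsilon_from_sigma_c(eq$sigma_c, kappa = model$alpha,
                                     n_t = model$n_t)
  eq
}
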