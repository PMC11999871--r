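#' Finite-volume two-cap organoid model configuration
#'
#' The organoid is a crypt spherical cap joined at a rim circle to a
#' villus cap, each region a monolayer of incompressible cells (cell
#' volume Omega = 4 pi h0 / n_t, thickness h = Omega/a for per-cell area
#' a). The crypt shape coordinate is x = cos(theta_c); the shared cell
#' scale a relaxes freely against the villus reservoir, and the lumen
#' couples through its pressure p: the mechanical equilibria are minima
#' over x of L_p(x) = min over a of [E - p V]. In the p -> 0 limit this
#' construction reduces analytically to the large-volume landscape
#' Delta F(x) (see [delta_f()]); at finite pressure the -pV work term
#' tilts the landscape, inflation stabilizing the open crypt. Normalized
#' volume v = V/V0 is measured against the stress-free organoid (p = 0,
#' sigma_c = 0, alpha = 1).
#'
#' @param phi crypt cell fraction
#' @param alpha in-plane tension ratio crypt/villus
#' @param n_t total cell count
#' @param h0 reference epithelial thickness in units of R0
#' @param c_p cell perimeter coefficient (disc-equivalent 2 sqrt(pi))
#' @return object of class `organoid_model`
#' @export
organoid_model <- function(phi = 0.2, alpha = 4, n_t = 400, h0 = 0.1,
                           c_p = 2 * sqrt(pi)) {
  stopifnot(phi > 0, phi < 1, alpha > 0, n_t >= 2, h0 > 0, h0 < 1, c_p > 0)
  m <- structure(list(
    phi = phi, alpha = alpha, n_t = n_t, h0 = h0, c_p = c_p,
    omega = 4 * pi * h0 / n_t, a0 = 4 * pi / n_t
  ), class = "organoid_model")
  m$V0 <- reference_volume(m)
  m
}

#' @export
print.organoid_model <- function(x, ...) {
  cat(sprintf(
    "organoid_model: phi=%.3g alpha=%.3g n_t=%d h0=%.3g (V0=%.4g)\n",
    x$phi, x$alpha, as.integer(x$n_t), x$h0, x$V0))
  invisible(x)
}

#' Volume of a spherical cap segment
#'
#' Spherical segment of half-angle `psi` about its pole, cut by the rim
#' plane: (pi/3) R^3 (1 - cos psi)^2 (2 + cos psi). Equals the full sphere
#' volume at psi = pi.
#'
#' @param R sphere radius
#' @param psi cap half-angle in [0, pi]
#' @return volume
#' @export
cap_volume <- function(R, psi) (pi / 3) * R^3 * (1 - cos(psi))^2 * (2 + cos(psi))

# reduced landscape energy and enclosed (apical) volume of the
# configuration (x, a_c, a_v). The crypt contributes the villus-reservoir
# reduction  E_c = P(x) a_c + Q(x) a_c^(-1/2):
#   P(x) = phi n_t [alpha - (1-x)/2]   (crypt in-plane tension net of the
#          villus footprint relief of the reservoir closure)
#   Q(x) = (c_p phi n_t omega / 2) [1 - sigma_c ((1+x)/(2 phi))^((n+1)/2)]
#          (lateral cohesion minus differential-tension work; the
#          mechanosensitive exponent enters as in the effective landscape)
# so that min over a_c of E_c is proportional to the analytic large-volume
# landscape Delta F(x). The villus bulk (in-plane + lateral) carries its
# own scale a_v; the lumen couples through the enclosed apical volume V.
# Returns c(E, V) or NA outside the admissible domain.
energy_volume_x <- function(x, a_c, a_v, sigma_c, model, law = NULL,
                            const_h_c = NA) {
  phi <- model$phi; n_t <- model$n_t
  if (!is.na(const_h_c)) a_c <- model$omega / const_h_c
  if (is.na(x) || x <= -1 || x > 1 || a_c <= 0 || a_v <= 0)
    return(c(NA, NA))
  psi_c <- pi - acos(min(1, max(-1, x)))
  r_c <- sqrt(phi * n_t * a_c / (2 * pi * (1 + x)))
  rho2 <- r_c^2 * (1 - x^2)
  A_v <- (1 - phi) * n_t * a_v
  w <- 2 * pi * rho2 / A_v - 1
  if (w > 1 - 1e-12) return(c(NA, NA))
  psi_v <- acos(max(-1, w))
  r_v <- sqrt(A_v / (2 * pi * (1 - w)))
  if (r_v < r_c * (1 - 1e-9)) return(c(NA, NA))
  h_v <- model$omega / a_v
  h_c <- if (is.na(const_h_c)) model$omega / a_c else const_h_c
  if (r_c - h_c / 2 <= 0 || r_v - h_v / 2 <= 0) return(c(NA, NA))
  n_exp <- if (is.null(law)) 0 else law$n
  sig <- if (is.null(law)) sigma_c else
    law$sigma * law$r0_ref^(law$n)   # radius map absorbed in the bracket
  P <- phi * n_t * (model$alpha - (1 - x) / 2)
  sig_term <- sig * ((1 + x) / (2 * phi))^((n_exp + 1) / 2)
  if (P < 0 || (is.na(const_h_c) && sig_term > 1)) return(c(NA, NA))
  # with a pinned crypt thickness, incompressibility freezes the crypt
  # cell area at omega/h0: the thickness amplification of the active
  # bending moment is switched off and the crypt has no scale freedom
  E_c <- P * a_c + 0.5 * model$c_p * phi * n_t * model$omega *
    (1 - sig_term) / sqrt(a_c)
  E_v <- (1 - phi) * n_t * a_v +
    0.5 * model$c_p * (1 - phi) * n_t * model$omega / sqrt(a_v)
  V <- cap_volume(r_c - h_c / 2, psi_c) + cap_volume(r_v - h_v / 2, psi_v)
  c(E_c + E_v, V)
}

# volume of the stress-free reference organoid: p = 0, sigma = 0,
# alpha = 1, spherical shape (x = 2 phi - 1, equal areas)
reference_volume <- function(model) {
  # stress-free organoid: p = 0, sigma_c = 0; minimize the energy over the
  # shape coordinate and both cell scales with the same inner solver used
  # by the landscape machinery, so v = 1 is exactly the relaxed state
  xs <- seq(max(-0.95, 2 * model$phi - 1.4), 0.5, length.out = 36)
  warm <- NULL
  Fs <- vapply(xs, function(x) {
    r <- inner_min(x, 0, 0, model, warm = warm)
    if (!is.na(r[1])) warm <<- r[2:3]
    if (is.na(r[1])) Inf else r[1]
  }, 0)
  i <- which.min(Fs)
  warm2 <- NULL
  fx <- function(x) {
    r <- inner_min(x, 0, 0, model, warm = warm2)
    if (!is.na(r[1])) warm2 <<- r[2:3]
    if (is.na(r[1])) 1e9 else r[1]
  }
  ox <- stats::optimize(fx, c(xs[max(1, i - 1)], xs[min(length(xs), i + 1)]),
                        tol = 1e-10)
  r <- inner_min(ox$minimum, 0, 0, model, warm = warm2)
  energy_volume_x(ox$minimum, exp(r[2]), exp(r[3]), 0, model)[2]
}

#' Construct the organoid shape at given shape coordinate and cell scales
#'
#' Full geometric record of the two-cap configuration: angles, radii,
#' thicknesses, rim radius, enclosed volume, degree of opening. NULL
#' outside the admissible domain (positive apical radii; the crypt at
#' least as curved as the villus).
#'
#' @param x cosine of the crypt opening angle, in (-1, 1]
#' @param a_c crypt per-cell in-plane area
#' @param a_v villus per-cell in-plane area
#' @param model an [organoid_model()]
#' @param const_h_c fixed crypt thickness for the constant-thickness
#'   control; NA (default) for incompressible cells
#' @return object of class `organoid_shape`, or NULL
#' @export
organoid_state <- function(x, a_c, a_v, model, const_h_c = NA) {
  phi <- model$phi; n_t <- model$n_t
  if (!is.na(const_h_c)) a_c <- model$omega / const_h_c
  if (x <= -1 || x > 1 || a_c <= 0 || a_v <= 0) return(NULL)
  theta_c <- acos(min(1, max(-1, x)))
  psi_c <- pi - theta_c
  r_c <- sqrt(phi * n_t * a_c / (2 * pi * (1 + x)))
  rho2 <- r_c^2 * (1 - x^2)
  A_v <- (1 - phi) * n_t * a_v
  w <- 2 * pi * rho2 / A_v - 1
  if (w > 1 - 1e-12) return(NULL)
  psi_v <- acos(max(-1, w))
  r_v <- sqrt(A_v / (2 * pi * (1 - w)))
  if (r_v < r_c * (1 - 1e-9)) return(NULL)
  h_v <- model$omega / a_v
  h_c <- if (is.na(const_h_c)) model$omega / a_c else const_h_c
  if (r_c - h_c / 2 <= 0 || r_v - h_v / 2 <= 0) return(NULL)
  V <- cap_volume(r_c - h_c / 2, psi_c) + cap_volume(r_v - h_v / 2, psi_v)
  structure(list(
    x = x, a_c = a_c, a_v = a_v,
    theta_c = theta_c, theta_v = pi - psi_v,
    psi_c = psi_c, psi_v = psi_v,
    r_c = r_c, r_v = r_v, h_c = h_c, h_v = h_v,
    rho = sqrt(rho2),
    v = unname(V / model$V0), V = unname(V),
    opening = min(1, theta_c / psi_v),
    const_h_c = const_h_c
  ), class = "organoid_shape")
}

#' @export
print.organoid_shape <- function(x, ...) {
  cat(sprintf(
    "organoid_shape: theta_c=%.4f theta_v=%.4f opening=%.4f r_c=%.4f r_v=%.4f h_c=%.4f v=%.4g\n",
    x$theta_c, x$theta_v, x$opening, x$r_c, x$r_v, x$h_c, x$v))
  invisible(x)
}

#' Lumen volume enclosed by a shape (apical surfaces)
#' @param shape an `organoid_shape`
#' @return volume in model units (multiples of R0^3)
#' @export
lumen_volume <- function(shape) {
  cap_volume(shape$r_c - shape$h_c / 2, shape$psi_c) +
    cap_volume(shape$r_v - shape$h_v / 2, shape$psi_v)
}

#' Per-cell geometry of each region
#'
#' Midplane, apical, basal and lateral per-cell areas, thickness, cell
#' width, and the active bending moment diagnostic
#' m = (gamma_a - gamma_b) h.
#'
#' @param shape an `organoid_shape`
#' @param model the [organoid_model()]
#' @param tensions optional regional tensions (for the bending moment);
#'   when NULL, m = NA
#' @return list with `crypt` and `villus` per-cell geometry
#' @export
cell_geometry <- function(shape, model, tensions = NULL) {
  one <- function(r, h, psi, n_cells, tn) {
    A_mid <- 2 * pi * r^2 * (1 - cos(psi))
    a <- A_mid / n_cells
    list(a_mid = a,
         a_apical = 2 * pi * (r - h / 2)^2 * (1 - cos(psi)) / n_cells,
         a_basal = 2 * pi * (r + h / 2)^2 * (1 - cos(psi)) / n_cells,
         a_lateral = model$c_p * sqrt(a) * h,
         h = h, d = sqrt(a),
         m = if (is.null(tn)) NA_real_ else (tn$gamma_a - tn$gamma_b) * h)
  }
  list(
    crypt = one(shape$r_c, shape$h_c, shape$psi_c, model$phi * model$n_t,
                tensions$crypt),
    villus = one(shape$r_v, shape$h_v, shape$psi_v,
                 (1 - model$phi) * model$n_t, tensions$villus)
  )
}

#' Total mechanical energy of a two-cap organoid shape
#'
#' Sums, over the crypt and villus regions,
#' Gamma_a 2 pi (R - h/2)^2 (1 - cos psi) +
#' Gamma_b 2 pi (R + h/2)^2 (1 - cos psi) +
#' (1/2) Gamma_l N c_p sqrt(A_mid/N) h,
#' with the apical surface facing the lumen.
#'
#' @param shape an [organoid_state()] result
#' @param tensions list with `crypt` and `villus` [region_tensions()]
#' @param model the [organoid_model()]
#' @return dimensionless energy
#' @export
total_energy <- function(shape, tensions, model) {
  if (shape$h_c >= 2 * shape$r_c || shape$h_v >= 2 * shape$r_v)
    stop("non-physical shape: thickness exceeds cap diameter", call. = FALSE)
  e_region <- function(tn, r, h, psi, n_cells) {
    A_mid <- 2 * pi * r^2 * (1 - cos(psi))
    tn$gamma_a * 2 * pi * (r - h / 2)^2 * (1 - cos(psi)) +
      tn$gamma_b * 2 * pi * (r + h / 2)^2 * (1 - cos(psi)) +
      0.5 * tn$gamma_l * n_cells * model$c_p * sqrt(A_mid / n_cells) * h
  }
  e_region(tensions$crypt, shape$r_c, shape$h_c, shape$psi_c,
           model$phi * model$n_t) +
    e_region(tensions$villus, shape$r_v, shape$h_v, shape$psi_v,
             (1 - model$phi) * model$n_t)
}
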