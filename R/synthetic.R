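# Synthetic-data generators emulating the study's measurement types:
# three-point annotations on circles, power-law intensity/curvature pairs,
# pre/post-ablation volume pairs, and forward-model tension-asymmetry
# observations. All generators are deterministic under a fixed seed.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Synthetic three-point annotation of a spherical-cap region
#'
#' Places the middle point at the cap apex and the two boundary points at
#' angular distance psi = pi - theta_true from it on a circle of the given
#' centre and radius (so that [opening_angle()] of the noise-free triplet
#' equals `theta_true`), then adds independent Gaussian coordinate noise.
#'
#' @param theta_true opening angle in (0, pi)
#' @param radius circle radius (> 0)
#' @param centre length-2 centre coordinates
#' @param coord_sd coordinate noise standard deviation
#' @param seed RNG seed (NULL: use current RNG state)
#' @param orientation apex direction in radians
#' @param sample_id,region annotation labels
#' @return data.frame in the annotation schema (3 rows)
#' @export
gen_triplet <- function(theta_true, radius = 1, centre = c(0, 0),
                        coord_sd = 0, seed = NULL, orientation = pi / 2,
                        sample_id = "s1", region = "crypt") {
  if (theta_true <= 0 || theta_true >= pi)
    stop("theta_true must lie in (0, pi)", call. = FALSE)
  stopifnot(radius > 0, coord_sd >= 0)
  with_seed(seed, {
    psi <- pi - theta_true
    ang <- orientation + c(psi, 0, -psi)
    x <- centre[1] + radius * cos(ang) + stats::rnorm(3, 0, coord_sd)
    y <- centre[2] + radius * sin(ang) + stats::rnorm(3, 0, coord_sd)
    data.frame(sample_id = sample_id, region = region,
               role = c("boundary1", "middle", "boundary2"),
               x = x, y = y, stringsAsFactors = FALSE)
  })
}

#' Batch of synthetic crypt/villus annotations
#'
#' One crypt and one villus triplet per sample, consistent with a chosen
#' degree of opening (theta_v is set so theta_c/(pi - theta_v) equals
#' `opening`).
#'
#' @param n_samples number of organoids
#' @param theta_c_true crypt angles (recycled)
#' @param opening degree of opening (recycled); sets theta_v
#' @param radius,coord_sd geometry and noise
#' @param seed RNG seed
#' @return annotation data.frame (6 rows per sample)
#' @export
gen_triplets <- function(n_samples, theta_c_true, opening = 0.8, radius = 50,
                         coord_sd = 0, seed = NULL) {
  th_c <- rep_len(theta_c_true, n_samples)
  opn <- rep_len(opening, n_samples)
  th_v <- pi - th_c / opn
  if (any(th_v < 0 | th_v >= pi))
    stop("incompatible theta_c / opening combination", call. = FALSE)
  with_seed(seed, {
    out <- NULL
    for (i in seq_len(n_samples)) {
      sid <- sprintf("s%03d", i)
      out <- rbind(
        out,
        gen_triplet(th_c[i], radius, c(0, 0), coord_sd, seed = NULL,
                    sample_id = sid, region = "crypt"),
        gen_triplet(th_v[i], radius * 1.4, c(0, -2 * radius), coord_sd,
                    seed = NULL, orientation = -pi / 2,
                    sample_id = sid, region = "villus"))
    }
    out
  })
}

#' Synthetic normalized radius/intensity power-law pairs
#'
#' x uniform in `x_range`; y = x^(-b_true) exp(eta) with
#' eta ~ Normal(0, log_sd^2) — multiplicative lognormal noise, matching
#' the positive, right-skewed support of intensity ratios.
#'
#' @param b_true generating exponent
#' @param n_pairs number of pairs (>= 3)
#' @param x_range positive range of normalized radii
#' @param log_sd standard deviation of the log-noise
#' @param seed RNG seed
#' @return data.frame: sample_id, group, radius_norm, intensity_ratio_norm
#' @export
gen_power_pairs <- function(b_true, n_pairs = 52, x_range = c(0.6, 2.5),
                            log_sd = 0.3, seed = NULL) {
  if (any(x_range <= 0) || x_range[2] <= x_range[1])
    stop("x_range must be positive and increasing", call. = FALSE)
  stopifnot(n_pairs >= 3, log_sd >= 0)
  with_seed(seed, {
    x <- stats::runif(n_pairs, x_range[1], x_range[2])
    y <- x^(-b_true) * exp(stats::rnorm(n_pairs, 0, log_sd))
    n_bulged <- round(n_pairs * 24 / 52)
    data.frame(sample_id = sprintf("p%03d", seq_len(n_pairs)),
               group = rep(c("bulged", "budded"),
                           c(n_bulged, n_pairs - n_bulged)),
               radius_norm = x, intensity_ratio_norm = y,
               stringsAsFactors = FALSE)
  })
}

#' Synthetic pre/post-ablation lumen-volume pairs
#'
#' v_post ~ baseline (1 + Normal(0, rel_sd)); v_pre = v_true v_post
#' (1 + Normal(0, rel_sd)). The batch mean of v_hat = v_pre/v_post
#' converges to v_true (up to the small relative-noise bias) as n grows.
#'
#' @param v_true generating normalized volume (> 0)
#' @param rel_sd relative noise (must be < 0.5: sign-flip risk)
#' @param n number of organoids
#' @param seed RNG seed
#' @param baseline post-ablation volume scale (arbitrary units)
#' @return data.frame: sample_id, v_pre, v_post, v_hat
#' @export
gen_ablation <- function(v_true, rel_sd = 0.1, n = 11, seed = NULL,
                         baseline = 100) {
  stopifnot(v_true > 0, n >= 1)
  if (rel_sd < 0 || rel_sd >= 0.5)
    stop("rel_sd must lie in [0, 0.5) to avoid sign flips", call. = FALSE)
  with_seed(seed, {
    v_post <- baseline * (1 + stats::rnorm(n, 0, rel_sd))
    v_pre <- v_true * v_post * (1 + stats::rnorm(n, 0, rel_sd))
    data.frame(sample_id = sprintf("a%03d", seq_len(n)),
               v_pre = v_pre, v_post = v_post, v_hat = v_pre / v_post,
               stringsAsFactors = FALSE)
  })
}

#' Synthetic tension-asymmetry observations from the forward model
#'
#' Computes the branch-consistent tension asymmetry of the
#' mechanosensitive model at the bulged (open branch, `v_bulged`) and
#' budded (closed branch, `v_budded`) conditions, then multiplies by
#' (1 + Normal(0, rel_sd)) per replicate.
#'
#' @param sigma_true intrinsic differential tension
#' @param n_true mechanosensitivity exponent
#' @param v_bulged,v_budded condition volumes
#' @param counts named counts c(bulged = ..., budded = ...)
#' @param rel_sd relative noise
#' @param seed RNG seed
#' @param model an [organoid_model()]
#' @param r0_ref mechanosensing reference radius
#' @return data.frame: sample_id, group, epsilon; attribute
#'   `"epsilon_true"` holds the noise-free condition values
#' @export
gen_eps_observations <- function(sigma_true, n_true = 1, v_bulged = 2.8,
                                 v_budded = 0.7,
                                 counts = c(bulged = 7, budded = 19),
                                 rel_sd = 0.1, seed = NULL,
                                 model = organoid_model(), r0_ref = 1.4) {
  stopifnot(all(counts >= 1), rel_sd >= 0)
  eb <- forward_eps_grid(sigma_true, n_true, v_bulged, "open", model,
                         r0_ref)
  ed <- forward_eps_grid(sigma_true, n_true, v_budded, "closed", model,
                         r0_ref)
  if (is.na(eb))
    stop("no open-branch state at the bulged condition for this sigma",
         call. = FALSE)
  if (is.na(ed))
    stop("no closed-branch state at the budded condition for this sigma",
         call. = FALSE)
  with_seed(seed, {
    nb <- counts[["bulged"]]; nd <- counts[["budded"]]
    eps <- c(eb * (1 + stats::rnorm(nb, 0, rel_sd)),
             ed * (1 + stats::rnorm(nd, 0, rel_sd)))
    out <- data.frame(
      sample_id = sprintf("e%03d", seq_len(nb + nd)),
      group = rep(c("bulged", "budded"), c(nb, nd)),
      epsilon = eps, stringsAsFactors = FALSE)
    attr(out, "epsilon_true") <- c(bulged = eb, budded = ed)
    out
  })
}
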