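#' Analytic large-volume energy landscape of crypt shape
#'
#' In the large lumen-volume limit the organoid's mechanical energy as a
#' function of the crypt opening angle theta_c reduces to
#' \deqn{\Delta F(x) = [1 - \sigma_c ((1+x)/(2\varphi))^{1/2}]^{2/3}
#'   [1 - (1-x)/(2\alpha)]^{1/3}, \quad x = \cos\theta_c.}
#' Local minima of Delta F are the crypt equilibrium states: x = 1
#' (theta_c = 0) is the budded (closed) crypt, interior minima are bulged
#' (open) crypts.
#'
#' @param x cosine of the crypt opening angle, in [-1, 1] (vectorized)
#' @param sigma_c crypt differential tension (>= 0)
#' @param phi crypt cell fraction in (0, 1)
#' @param alpha in-plane tension ratio (> 0)
#' @return Delta F values (dimensionless, >= 0 on the admissible domain)
#' @seealso [effective_delta_f()] for the mechanosensitive generalization,
#'   [scan_landscape()] for minima enumeration and regime classification.
#' @export
delta_f <- function(x, sigma_c, phi, alpha) {
  effective_delta_f(x, sigma = sigma_c, n = 0, phi = phi, alpha = alpha)
}

#' Effective landscape under curvature-dependent tension feedback
#'
#' Substituting the mechanosensitive law sigma_c = sigma (R_c/R0)^-n with
#' the analytic-limit crypt radius R_c(x) = sqrt(2 phi / (1+x)) (equal cell
#' areas on a sphere, R0 = 1) into the large-volume landscape gives
#' \deqn{\Delta F_n(x) = [1 - \sigma ((1+x)/(2\varphi))^{(n+1)/2}]^{2/3}
#'   [1 - (1-x)/(2\alpha)]^{1/3}.}
#' With n = 0 this is exactly [delta_f()].
#'
#' @param x cosine of the crypt opening angle (vectorized)
#' @param sigma intrinsic differential tension (>= 0)
#' @param n mechanosensitivity exponent (>= 0)
#' @param phi crypt cell fraction
#' @param alpha in-plane tension ratio
#' @return Delta F values
#' @export
effective_delta_f <- function(x, sigma, n = 0, phi, alpha) {
  stopifnot(sigma >= 0, n >= 0, phi > 0, phi < 1, alpha > 0)
  if (any(x < -1 - 1e-12 | x > 1 + 1e-12))
    stop("x must lie in [-1, 1]", call. = FALSE)
  x <- pmin(1, pmax(-1, x))
  b1 <- 1 - sigma * ((1 + x) / (2 * phi))^((n + 1) / 2)
  b2 <- 1 - (1 - x) / (2 * alpha)
  bad1 <- b1 < -1e-12
  bad2 <- b2 < -1e-12
  if (any(bad1) || any(bad2)) {
    which_bad <- if (any(bad1)) "differential-tension (first)" else
      "villus in-plane (second)"
    stop(sprintf(
      "inadmissible x: %s bracket negative at x = %.6g",
      which_bad, x[which(bad1 | bad2)[1]]), call. = FALSE)
  }
  pmax(b1, 0)^(2 / 3) * pmax(b2, 0)^(1 / 3)
}

# admissible x-range [x_lo, x_hi] of the (effective) landscape
landscape_domain <- function(sigma, n, phi, alpha) {
  x_lo <- max(-1, 1 - 2 * alpha)
  x_hi <- 1
  if (sigma > 0) {
    # first bracket zero at (1+x)/(2 phi) = sigma^{-2/(n+1)}
    xb <- 2 * phi * sigma^(-2 / (n + 1)) - 1
    x_hi <- min(x_hi, xb)
  }
  c(x_lo, x_hi)
}

#' Scan the energy landscape and classify the morphological regime
#'
#' Samples Delta F on the admissible domain, locates interior local minima
#' by discrete sign changes with local quadratic refinement, tests the
#' closed-crypt end x = 1 (and the fully-open lower endpoint) as boundary
#' minima, and classifies the regime:
#' * `bulged_monostable`: no minimum at x = 1;
#' * `bistable`: an interior (or lower-boundary) minimum coexists with the
#'   x = 1 minimum;
#' * `budded_monostable`: only the x = 1 minimum.
#'
#' @param sigma_c differential tension (interpreted as the intrinsic tension
#'   sigma when `n > 0`)
#' @param phi crypt cell fraction
#' @param alpha in-plane tension ratio
#' @param n mechanosensitivity exponent (0 = no feedback)
#' @param dx grid step
#' @param delta offset used to test boundary minima
#' @param tie_tol energies closer than this are treated as ties (guards
#'   against floating-point plateau artifacts)
#' @return object of class `energy_landscape` with fields `x_grid`, `values`,
#'   `minima` (data.frame: x, value, type), `regime`
#' @export
scan_landscape <- function(sigma_c, phi, alpha, n = 0, dx = 1e-3,
                           delta = 1e-4, tie_tol = 1e-9) {
  stopifnot(dx > 0, delta > 0)
  dom <- landscape_domain(sigma_c, n, phi, alpha)
  if (dom[2] - dom[1] < 2 * dx)
    stop("empty admissible domain for the landscape", call. = FALSE)
  xg <- seq(dom[1], dom[2], by = dx)
  if (xg[length(xg)] < dom[2]) xg <- c(xg, dom[2])
  f <- function(x) effective_delta_f(x, sigma_c, n, phi, alpha)
  vals <- f(xg)

  minima <- data.frame(x = numeric(0), value = numeric(0),
                       type = character(0))
  dv <- diff(vals)
  s <- sign(dv)
  # carry the previous sign through flat stretches
  for (k in seq_along(s)[-1]) if (s[k] == 0) s[k] <- s[k - 1]
  int_idx <- which(s[-length(s)] < 0 & s[-1] > 0) + 1
  # separation: require strictly larger values on both sides
  int_idx <- int_idx[vapply(int_idx, function(i)
    max(vals[1:i]) > vals[i] + tie_tol &&
      max(vals[i:length(vals)]) > vals[i] + tie_tol, TRUE)]
  for (i in int_idx) {
    # quadratic refinement through the bracketing triple
    x3 <- xg[(i - 1):(i + 1)]; y3 <- vals[(i - 1):(i + 1)]
    denom <- (y3[1] - 2 * y3[2] + y3[3])
    xs <- if (abs(denom) > 1e-15)
      x3[2] + 0.5 * dx * (y3[1] - y3[3]) / denom else x3[2]
    xs <- min(max(xs, x3[1]), x3[3])
    minima <- rbind(minima,
                    data.frame(x = xs, value = f(xs), type = "interior"))
  }
  # boundary minima
  xb <- dom[2]
  if (f(xb) < f(xb - delta) - tie_tol) {
    type <- if (abs(xb - 1) < 1e-9) "budded" else "budded"
    minima <- rbind(minima, data.frame(x = xb, value = f(xb), type = type))
  }
  if (f(dom[1]) < f(dom[1] + delta) - tie_tol)
    minima <- rbind(minima,
                    data.frame(x = dom[1], value = f(dom[1]), type = "open_end"))

  has_budded <- any(minima$type == "budded")
  has_open <- any(minima$type %in% c("interior", "open_end"))
  regime <- if (has_budded && has_open) "bistable"
            else if (has_budded) "budded_monostable"
            else "bulged_monostable"
  structure(list(x_grid = xg, values = vals, minima = minima,
                 regime = regime,
                 params = list(sigma_c = sigma_c, phi = phi, alpha = alpha,
                               n = n, dx = dx)),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("energy_landscape (%s): %d grid points, %d minima\n",
              x$regime, length(x$x_grid), nrow(x$minima)))
  if (nrow(x$minima)) print(x$minima, row.names = FALSE)
  invisible(x)
}

#' Closed-form onset of the budded (closed-crypt) minimum
#'
#' The smallest (intrinsic) tension at which x = 1 becomes a local minimum
#' of the effective landscape, from the sign change of dDeltaF/dx at x = 1:
#' \deqn{\sigma^* = \varphi^{(n+1)/2} / (1 + \alpha (n+1)).}
#' With n = 0 this is sqrt(phi)/(1 + alpha).
#'
#' @param phi crypt cell fraction
#' @param alpha in-plane tension ratio
#' @param n mechanosensitivity exponent
#' @return threshold sigma*
#' @export
budded_threshold <- function(phi, alpha, n = 0) {
  stopifnot(phi > 0, phi < 1, alpha > 0, n >= 0)
  phi^((n + 1) / 2) / (1 + alpha * (n + 1))
}

#' Bistable window of the (effective) analytic landscape
#'
#' Lower edge: [budded_threshold()]. Upper edge: the largest sigma at which
#' an open (interior or fully-open boundary) minimum still exists, located
#' by bisection on [scan_landscape()] regimes.
#'
#' @inheritParams budded_threshold
#' @param tol bisection tolerance on sigma
#' @param dx landscape grid step used during bisection
#' @return numeric c(sigma_lo, sigma_hi), or NULL when no window exists
#' @export
bistable_window <- function(phi, alpha, n = 0, tol = 1e-5, dx = 1e-3) {
  lo <- budded_threshold(phi, alpha, n)
  has_open <- function(s) {
    sl <- scan_landscape(s, phi, alpha, n, dx = dx)
    any(sl$minima$type %in% c("interior", "open_end"))
  }
  # find an upper bound where the open minimum is gone; the window can
  # extend at most to the ceiling sigma = phi^((n+1)/2) where the
  # closed-crypt end of the admissible domain degenerates (for alpha <= 1
  # the zero-energy fully-everted end keeps an open minimum throughout,
  # and the ceiling is the honest upper edge)
  cap <- phi^((n + 1) / 2) * 0.999999
  hi <- lo * 1.5
  for (i in 1:40) {
    if (!has_open(hi)) break
    hi <- hi * 1.5
    if (hi > cap) { hi <- cap; break }
  }
  if (has_open(hi)) {
    if (hi < cap) return(NULL)
    return(c(sigma_lo = lo, sigma_hi = cap))
  }
  a <- lo; b <- hi
  while (b - a > tol) {
    m <- (a + b) / 2
    if (has_open(m)) a <- m else b <- m
  }
  hi <- (a + b) / 2
  if (hi <= lo) return(NULL)
  c(sigma_lo = lo, sigma_hi = hi)
}
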