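# shared fixtures: a single default model instance and a cached
# tension-asymmetry predictor (expensive forward tabulation, built once)

default_model <- organoid_model()

cached_predictor <- local({
  pred <- NULL
  function() {
    if (is.null(pred))
      pred <<- epsilon_predictor(n = 1, model = default_model,
                                 sigma_grid = seq(0.008, 0.05,
                                                  length.out = 15))
    pred
  }
})

# dense-grid oracle for analytic-landscape minima (independent of
# scan_landscape's refinement path)
oracle_minima <- function(sigma_c, phi, alpha, n = 0, dx = 1e-4) {
  dom <- cryptmorph:::landscape_domain(sigma_c, n, phi, alpha)
  xg <- seq(dom[1], dom[2], by = dx)
  v <- effective_delta_f(xg, sigma_c, n, phi, alpha)
  i <- which(diff(sign(diff(v))) == 2) + 1
  list(x = xg[i], value = v[i],
       budded = v[length(v)] < v[length(v) - 1],
       open_end = v[1] < v[2])
}

# numeric budded-onset oracle: bisection on the sign of the landscape
# slope at the closed-crypt end
onset_oracle <- function(phi, alpha, n, delta = 1e-6, tol = 1e-6) {
  slope_in <- function(s) {
    x_hi <- min(1, 2 * phi * s^(-2 / (n + 1)) - 1)
    effective_delta_f(x_hi, s, n, phi, alpha) <
      effective_delta_f(x_hi - delta, s, n, phi, alpha)
  }
  lo <- 1e-4; hi <- phi^((n + 1) / 2) * 0.999
  for (k in 1:50) {
    mid <- (lo + hi) / 2
    if (slope_in(mid)) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}
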