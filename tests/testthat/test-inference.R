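test_that("fit_power_exponent is exact on noise-free power laws", {
  x <- c(0.5, 1, 2, 4)
  fit <- fit_power_exponent(x, x^-2)
  expect_equal(fit$estimate, 2, tolerance = 1e-12)
  expect_equal(fit$residual_ss, 0, tolerance = 1e-20)
  flat <- fit_power_exponent(c(0.5, 1, 2, 3), rep(1, 4))
  expect_equal(flat$estimate, 0, tolerance = 1e-12)
  expect_error(fit_power_exponent(c(1, -2, 3), c(1, 1, 1)), "rows")
})

test_that("the through-origin fit is scale-equivariant on exact power
          laws", {
  x <- c(0.5, 0.9, 1.7, 2.4)
  f1 <- fit_power_exponent(x, x^-1.3)
  cc <- 2.7
  f2 <- fit_power_exponent(cc * x, cc^-1.3 * (cc * x)^-1.3 * cc^1.3)
  expect_equal(f1$estimate, 1.3, tolerance = 1e-10)
  expect_equal(f2$estimate, f1$estimate, tolerance = 1e-10)
})

test_that("the design of the intensity-curvature experiment recovers the
          exponent", {
  tb <- gen_power_pairs(1.0, 52, log_sd = 0.3, seed = 1)
  fit <- fit_power_exponent(tb$radius_norm, tb$intensity_ratio_norm)
  expect_gt(fit$estimate, 0.7)
  expect_lt(fit$estimate, 1.3)
  # recovery is unbiased at the experiment's scale
  est <- vapply(1:200, function(s) {
    d <- gen_power_pairs(1.0, 52, log_sd = 0.3, seed = 700 + s)
    fit_power_exponent(d$radius_norm, d$intensity_ratio_norm)$estimate
  }, 0)
  expect_lt(abs(mean(est) - 1.0), 0.05)
})

test_that("fit_sigma recovers the generating intrinsic tension from
          noise-free forward data", {
  pred <- cached_predictor()
  for (s_true in c(0.02, 0.035)) {
    obs <- gen_eps_observations(s_true, 1, rel_sd = 0,
                                counts = c(bulged = 3, budded = 3),
                                seed = 1, model = default_model)
    fit <- fit_sigma(obs, predictor = pred, refine = TRUE, tol = 1e-5)
    expect_equal(fit$estimate, s_true, tolerance = 1e-4)
  }
})

test_that("the fit_sigma loss is unimodal over the feasible interval for
          noise-free data", {
  pred <- cached_predictor()
  obs <- gen_eps_observations(0.02, 1, rel_sd = 0,
                              counts = c(bulged = 3, budded = 3),
                              seed = 1, model = default_model)
  e_b <- mean(obs$epsilon[obs$group == "bulged"])
  e_d <- mean(obs$epsilon[obs$group == "budded"])
  sg <- seq(0.01, 0.045, length.out = 40)
  loss <- vapply(sg, function(s) {
    pb <- pred(s, "bulged"); pd <- pred(s, "budded")
    if (is.na(pb) || is.na(pd)) return(NA_real_)
    (pb - e_b)^2 + (pd - e_d)^2
  }, 0)
  ok <- is.finite(loss)
  dl <- diff(loss[ok])
  # one descending run followed by one ascending run
  expect_lte(sum(diff(sign(dl)) != 0), 1)
})
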