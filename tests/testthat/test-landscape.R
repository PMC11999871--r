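test_that("delta_f matches direct arithmetic on the printed formula", {
  expect_equal(delta_f(1, 0, 0.5, 1), 1)
  expect_equal(delta_f(0, 0.1, 0.5, 1), 0.9^(2 / 3) * 0.5^(1 / 3),
               tolerance = 1e-12)
  expect_equal(delta_f(1, 0.5, 0.25, 3), 0)  # first bracket vanishes
  expect_error(delta_f(-0.5, 0.1, 0.5, 0.4), "bracket")
})

test_that("the effective landscape reduces to delta_f at n = 0 and obeys
          the feedback arithmetic", {
  set.seed(11)
  xs <- runif(20, -0.5, 0.9)
  expect_equal(effective_delta_f(xs, 0.1, 0, 0.2, 2),
               delta_f(xs, 0.1, 0.2, 2), tolerance = 1e-12)
  expect_equal(effective_delta_f(1, 0.04, 1, 0.2, 2), 0.8^(2 / 3),
               tolerance = 1e-12)
})

test_that("delta_f is non-negative and continuous on random admissible
          domains", {
  set.seed(7)
  for (k in 1:25) {
    phi <- runif(1, 0.05, 0.6)
    alpha <- runif(1, 0.5, 5)
    sigma <- runif(1, 0, 0.8 * sqrt(phi))
    dom <- cryptmorph:::landscape_domain(sigma, 0, phi, alpha)
    xs <- seq(dom[1], dom[2], length.out = 400)
    v <- delta_f(xs, sigma, phi, alpha)
    expect_true(all(v >= 0))
    expect_true(all(is.finite(v)))
    # continuity: neighbouring values change by O(dx)
    expect_lt(max(abs(diff(v))), 30 * diff(xs[1:2])^0.5)
  }
})

test_that("scan_landscape classifies the three regimes and localizes
          minima against a 10x finer oracle", {
  sl <- scan_landscape(0.15, 0.2, 2)
  expect_identical(sl$regime, "bistable")
  or <- oracle_minima(0.15, 0.2, 2, dx = 1e-4)
  ints <- sl$minima[sl$minima$type == "interior", ]
  expect_equal(nrow(ints), length(or$x))
  expect_lt(max(abs(sort(ints$x) - sort(or$x))), 2e-3)
  expect_lt(abs(ints$x[1] - (-0.45)), 0.05)
  expect_true(any(sl$minima$type == "budded"))

  expect_identical(scan_landscape(0.05, 0.2, 2)$regime, "bulged_monostable")
  expect_identical(scan_landscape(0.30, 0.2, 2)$regime, "budded_monostable")
  expect_identical(scan_landscape(0, 0.3, 1)$regime, "bulged_monostable")
})

test_that("scan_landscape errors on an empty admissible domain", {
  # alpha tiny and sigma large squeeze the domain to nothing
  expect_error(scan_landscape(8, 0.05, 0.0006), "domain")
})

test_that("budded_threshold matches its closed form and the numeric
          slope oracle", {
  expect_equal(budded_threshold(0.2, 2, 0), sqrt(0.2) / 3,
               tolerance = 1e-12)
  expect_equal(budded_threshold(0.2, 2, 1), 0.04, tolerance = 1e-12)
  for (cfg in list(c(0.2, 2, 0), c(0.2, 2, 1), c(0.1, 4, 0),
                   c(0.3, 1, 2))) {
    expect_equal(budded_threshold(cfg[1], cfg[2], cfg[3]),
                 onset_oracle(cfg[1], cfg[2], cfg[3]), tolerance = 1e-3)
  }
  # strictly decreasing in alpha
  alphas <- c(0.5, 1, 2, 4, 8)
  expect_true(all(diff(budded_threshold(0.2, alphas, 0)) < 0))
})

test_that("bistable_window brackets the printed-range behaviour and
          widens with mechanosensing", {
  w0 <- bistable_window(0.2, 2, 0)
  expect_equal(unname(w0[1]), sqrt(0.2) / 3, tolerance = 1e-10)
  expect_gt(w0[2], 0.15)
  expect_lt(w0[2], 0.30)
  w1 <- bistable_window(0.2, 2, 1)
  expect_equal(unname(w1[1]), 0.04, tolerance = 1e-10)
  expect_gt(w1[2], 0.04)
  expect_lt(w1[2], 0.15)
  relw <- function(w) (w[2] - w[1]) / w[1]
  expect_gt(relw(w1), relw(w0))
})
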