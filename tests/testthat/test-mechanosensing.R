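test_that("sigma_c_effective follows the curvature power law", {
  expect_equal(sigma_c_effective(mechano_law(0.02, 0, 1), 3.7), 0.02)
  expect_equal(sigma_c_effective(mechano_law(0.02, 1, 1), 0.5), 0.04)
  expect_equal(sigma_c_effective(mechano_law(0.03, 2, 1), 2), 0.0075)
  expect_error(sigma_c_effective(mechano_law(0.02, 1, 1), -1), "positive")
})

test_that("epsilon_threshold converts the budded onset and falls with the
          coupling strength", {
  expect_equal(epsilon_threshold(0.2, 2, 1, kappa = 1, n_t = 400),
               2 * 0.04 / sqrt(4 * pi / 400), tolerance = 1e-6)
  expect_equal(epsilon_threshold(0.2, 2, 1, kappa = 1, n_t = 400), 0.4514,
               tolerance = 1e-3)
  for (phi in c(0.1, 0.2, 0.3)) for (al in c(1, 2, 4))
    expect_lt(epsilon_threshold(phi, al, 1, 1, 400),
              epsilon_threshold(phi, al, 0, 1, 400))
  # kappa -> infinity sends the threshold to zero
  expect_lt(epsilon_threshold(0.2, 2, 1, kappa = 1e6, n_t = 400), 1e-5)
})

test_that("self-consistent states coincide with plain equilibria when
          n = 0 and satisfy the feedback law exactly", {
  m <- default_model
  law0 <- mechano_law(0.05, 0, 1)
  eq0 <- selfconsistent_states(1.0, law0, m)
  eq_plain <- find_equilibria(1.0, 0.05, m)
  expect_equal(nrow(eq0), nrow(eq_plain))
  expect_equal(sort(eq0$opening), sort(eq_plain$opening), tolerance = 1e-4)
  law1 <- mechano_law(0.03, 1, 1.4)
  eq1 <- selfconsistent_states(1.0, law1, m)
  expect_gt(nrow(eq1), 0)
  expect_equal(eq1$sigma_c, sigma_c_effective(law1, eq1$r_c),
               tolerance = 1e-10)
})

test_that("inflation lowers the bulged branch's differential tension but
          barely moves the budded branch's", {
  m <- default_model
  law <- mechano_law(0.02, 1, 1.4)
  open_lo <- equilibrium_shape(1.0, law = law, model = m, prefer = "open")
  open_hi <- equilibrium_shape(2.0, law = law, init = open_lo, model = m)
  sc_lo <- attr(open_lo, "sigma_c"); sc_hi <- attr(open_hi, "sigma_c")
  expect_lt(sc_hi, sc_lo)
  closed_lo <- equilibrium_shape(0.75, law = law, model = m,
                                 prefer = "closed")
  closed_hi <- equilibrium_shape(0.95, law = law, init = closed_lo,
                                 model = m)
  dsc_closed <- abs(attr(closed_hi, "sigma_c") - attr(closed_lo, "sigma_c"))
  # matched relative volume change on the open branch
  dsc_open <- abs(sc_hi - sc_lo)
  expect_lt(dsc_closed / abs(attr(closed_lo, "sigma_c")),
            dsc_open / abs(sc_lo))
})
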