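test_that("generators are bit-identical under a fixed seed", {
  expect_identical(gen_power_pairs(1, 52, seed = 3),
                   gen_power_pairs(1, 52, seed = 3))
  expect_identical(gen_ablation(2.77, 0.1, 11, seed = 3),
                   gen_ablation(2.77, 0.1, 11, seed = 3))
  expect_identical(gen_triplets(3, 1.1, seed = 3),
                   gen_triplets(3, 1.1, seed = 3))
  a <- gen_power_pairs(1, 52, seed = 3)
  b <- gen_power_pairs(1, 52, seed = 4)
  expect_false(identical(a, b))
  expect_identical(names(a), names(b))
})

test_that("power-law pairs have the stated schema, support and noise
          model", {
  tb <- gen_power_pairs(1.0, n_pairs = 52, x_range = c(0.6, 2.5),
                        log_sd = 0.3, seed = 1)
  expect_equal(nrow(tb), 52)
  expect_true(all(tb$radius_norm > 0 & tb$intensity_ratio_norm > 0))
  expect_setequal(unique(tb$group), c("bulged", "budded"))
  # the log-residuals around the generating law are centred at zero
  big <- gen_power_pairs(1.0, n_pairs = 4000, log_sd = 0.3, seed = 2)
  resid <- log(big$intensity_ratio_norm) + 1.0 * log(big$radius_norm)
  expect_lt(abs(mean(resid)), 3 * 0.3 / sqrt(4000))
  expect_error(gen_power_pairs(1, 52, x_range = c(-1, 2)), "positive")
})

test_that("ablation pairs recover the generating volume in the mean", {
  tb0 <- gen_ablation(2.77, rel_sd = 0, n = 11, seed = 1)
  expect_equal(tb0$v_hat, rep(2.77, 11), tolerance = 1e-12)
  tb <- gen_ablation(0.71, rel_sd = 0.1, n = 1000, seed = 1)
  expect_lt(abs(mean(tb$v_hat) - 0.71) / 0.71, 0.02)
  expect_error(gen_ablation(1, rel_sd = 0.6), "rel_sd")
})

test_that("noise-free triplets round-trip through the opening-angle
          estimator", {
  tp <- gen_triplet(pi / 2, radius = 1, coord_sd = 0)
  g <- function(role) as.numeric(tp[tp$role == role, c("x", "y")])
  expect_equal(opening_angle(g("boundary1"), g("middle"), g("boundary2")),
               pi / 2, tolerance = 1e-10)
})

test_that("forward-model asymmetry observations separate the conditions
          the right way around", {
  tb <- gen_eps_observations(0.02, 1, seed = 1, model = default_model)
  expect_equal(nrow(tb), 26)
  expect_equal(sum(tb$group == "bulged"), 7)
  et <- attr(tb, "epsilon_true")
  # closed crypts carry the higher effective tension, hence higher
  # asymmetry
  expect_gt(et[["budded"]], et[["bulged"]])
  # noise-free generation hits the branch values exactly
  tb0 <- gen_eps_observations(0.02, 1, rel_sd = 0, seed = 1,
                              counts = c(bulged = 2, budded = 2),
                              model = default_model)
  expect_equal(unique(tb0$epsilon[tb0$group == "bulged"]),
               attr(tb0, "epsilon_true")[["bulged"]])
})

test_that("generator outputs are accepted by their consuming stages", {
  ann <- gen_triplets(2, 1.0, seed = 9)
  expect_silent(angles_from_annotations(ann))
  tb <- gen_power_pairs(1.2, 20, seed = 9)
  expect_s3_class(fit_power_exponent(tb$radius_norm,
                                     tb$intensity_ratio_norm),
                  "fit_result")
  ab <- gen_ablation(2.77, 0.1, 11, seed = 9)
  expect_silent(infer_v(ab$v_pre, ab$v_post))
})
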