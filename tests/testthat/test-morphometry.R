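test_that("circumcentre reproduces known centres and is translation
          equivariant", {
  expect_equal(unname(circumcentre(c(1, 0), c(0, 1), c(-1, 0))), c(0, 0),
               tolerance = 1e-12)
  c1 <- circumcentre(c(1, 0) + c(5, 7), c(0, 1) + c(5, 7),
                     c(-1, 0) + c(5, 7))
  expect_equal(unname(c1), c(5, 7), tolerance = 1e-10)
  expect_error(circumcentre(c(0, 0), c(1, 1), c(2, 2)), "collinear")
})

test_that("the circumcentre is equidistant from all three points", {
  set.seed(3)
  for (k in 1:20) {
    ang <- sort(runif(3, 0, 2 * pi))
    R <- runif(1, 0.5, 80); ctr <- runif(2, -50, 50)
    pts <- lapply(ang, function(a) ctr + R * c(cos(a), sin(a)))
    cc <- do.call(circumcentre, pts)
    d <- vapply(pts, function(p) sqrt(sum((p - cc)^2)), 0)
    expect_lt(diff(range(d)) / mean(d), 1e-9)
  }
})

test_that("opening_angle matches hand-computed fixtures", {
  expect_equal(opening_angle(c(1, 0), c(0, 1), c(-1, 0)), pi / 2,
               tolerance = 1e-12)
  expect_equal(opening_angle(c(sqrt(3) / 2, -0.5), c(0, 1),
                             c(-sqrt(3) / 2, -0.5)), pi / 3,
               tolerance = 1e-12)
})

test_that("opening_angle is exact on noise-free synthetic triplets and
          invariant to rigid motions and scaling", {
  for (th in c(0.3, 1.0, 2.0, 2.9)) {
    tp <- gen_triplet(th, radius = 1, centre = c(0, 0), coord_sd = 0)
    g <- function(role) as.numeric(tp[tp$role == role, c("x", "y")])
    expect_equal(opening_angle(g("boundary1"), g("middle"), g("boundary2")),
                 th, tolerance = 1e-10)
  }
  tp <- gen_triplet(2.0, radius = 50, centre = c(10, -3), coord_sd = 0,
                    orientation = 1.1)
  g <- function(role) as.numeric(tp[tp$role == role, c("x", "y")])
  expect_equal(opening_angle(g("boundary1"), g("middle"), g("boundary2")),
               2.0, tolerance = 1e-10)
})

test_that("degree_of_opening handles the budded, spherical and clipped
          cases", {
  expect_equal(degree_of_opening(0, 1), 0)
  expect_equal(degree_of_opening(2 * pi / 3, pi / 3), 1)
  expect_equal(degree_of_opening(pi / 3, pi / 3), 0.5)
  expect_warning(r <- degree_of_opening(2.12, pi / 3 + 0.01), "clipped")
  expect_equal(r, 1)
  expect_warning(r2 <- degree_of_opening(2.8, pi / 3), "inconsistent")
  expect_true(is.na(r2))
})

test_that("asymmetry_from_intensity is the monotone ratio map", {
  expect_equal(asymmetry_from_intensity(1), 0)
  expect_equal(asymmetry_from_intensity(3), 0.5)
  expect_gt(asymmetry_from_intensity(1e6), 0.99999)
  rs <- c(0.2, 0.5, 1, 2, 5)
  expect_true(all(diff(asymmetry_from_intensity(rs)) > 0))
  expect_error(asymmetry_from_intensity(-1), "positive")
})

test_that("infer_v reproduces the ablation arithmetic with batch
          statistics", {
  one <- infer_v(554, 200)
  expect_equal(one$v_hat, 2.77)
  expect_equal(infer_v(71, 100)$v_hat, 0.71)
  batch <- infer_v(rep(554, 5), rep(200, 5))
  expect_equal(attr(batch, "mean"), 2.77)
  expect_equal(attr(batch, "sd"), 0)
  expect_error(infer_v(-1, 10), "positive")
})

test_that("angles_from_annotations round-trips generated organoid
          annotations", {
  ann <- gen_triplets(4, theta_c_true = c(1.2, 0.6, 2.0, 1.5),
                      opening = 0.8, coord_sd = 0, seed = 5)
  res <- angles_from_annotations(ann)
  expect_equal(res$theta_c, c(1.2, 0.6, 2.0, 1.5), tolerance = 1e-9)
  expect_equal(res$opening, rep(0.8, 4), tolerance = 1e-9)
})

test_that("opening_angle is unbiased under coordinate noise", {
  n_rep <- 400
  for (th in c(0.8, 1.5, 2.5)) {
    est <- vapply(seq_len(n_rep), function(s) {
      tp <- gen_triplet(th, radius = 1, coord_sd = 0.01, seed = 10000 + s)
      g <- function(role) as.numeric(tp[tp$role == role, c("x", "y")])
      opening_angle(g("boundary1"), g("middle"), g("boundary2"))
    }, 0)
    se <- sd(est) / sqrt(n_rep)
    expect_lt(abs(mean(est) - th), 3 * se + 1e-4)
  }
})
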