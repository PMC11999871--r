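test_that("detect_snap flags constructed jumps and nothing else", {
  smooth <- seq(1, 0, length.out = 60)
  expect_equal(nrow(detect_snap(smooth, 0.2)), 0)
  series <- rep(0.9, 60)
  series[37:60] <- 0.1
  ev <- detect_snap(series, 0.2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$index, 37L)
  expect_equal(ev$delta, -0.8)
})

test_that("continuation is deterministic given controls", {
  m <- default_model
  wp <- data.frame(v = seq(1.6, 1.0, length.out = 5), sigma = 0.02)
  t1 <- continue_path(wp, m, mechano_law(0.02, 1, 1.4), init = "open")
  t2 <- continue_path(wp, m, mechano_law(0.02, 1, 1.4), init = "open")
  expect_equal(as.data.frame(t1), as.data.frame(t2), tolerance = 1e-12)
})

test_that("a volume excursion below the bistable window is reversible", {
  m <- default_model
  law <- mechano_law(0.008, 1, 1.4)   # below the budded onset
  down <- data.frame(v = seq(1.6, 0.8, length.out = 8), sigma = 0.008)
  up <- data.frame(v = seq(0.8, 1.6, length.out = 8), sigma = 0.008)
  tr_d <- continue_path(down, m, law, init = "open")
  tr_u <- continue_path(up, m, law, init = attr(tr_d, "final_state"))
  expect_equal(tr_u$opening[8], tr_d$opening[1], tolerance = 1e-3)
  expect_equal(nrow(attr(tr_d, "events")), 0)
})

test_that("deflation inside the bistable regime closes the crypt
          irreversibly", {
  m <- default_model
  law <- mechano_law(0.022, 1, 1.4)
  down <- data.frame(v = seq(1.6, 0.7, length.out = 10), sigma = 0.022)
  tr_d <- continue_path(down, m, law, init = "open")
  expect_gt(tr_d$opening[1], 0.5)   # starts on the open branch
  expect_lt(tr_d$opening[10], 0.05)
  # re-inflation within the closed branch's stable extent does not reopen
  up <- data.frame(v = seq(0.7, 1.4, length.out = 10), sigma = 0.022)
  tr_u <- continue_path(up, m, law, init = attr(tr_d, "final_state"))
  expect_lt(tr_u$opening[10], 0.05)
})

test_that("the same endpoint controls reached by different paths give
          different states inside the bistable window", {
  m <- default_model
  law <- mechano_law(0.022, 1, 1.4)
  # path A -> C: raise tension at high volume (stays on the open branch)
  ac <- continue_path(
    data.frame(v = 1.4, sigma = seq(0.005, 0.022, length.out = 8)),
    m, law, init = "open")
  # path A -> B -> C: deflate first (closes), then re-inflate at high
  # tension to the same endpoint controls
  abc <- continue_path(
    rbind(data.frame(v = seq(1.4, 0.7, length.out = 8),
                     sigma = seq(0.005, 0.022, length.out = 8)),
          data.frame(v = seq(0.7, 1.4, length.out = 8), sigma = 0.022)),
    m, law, init = "open")
  op_ac <- ac$opening[nrow(ac)]
  op_abc <- abc$opening[nrow(abc)]
  expect_gt(op_ac, 0.5)
  expect_lt(op_abc, 0.1)
})
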