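test_that("live gating conserves counts at any threshold", {
  sim <- sim_hac_flow(5000, 0.6, dead_fraction = 0.25, seed = 2)
  for (thr in c(0, 50, 500, 2000, 1e6)) {
    live <- gate_live(sim$events, thr)
    gc <- attr(live, "gate_counts")
    expect_equal(gc[["live"]] + gc[["dead"]], gc[["total"]])
    expect_equal(nrow(live), gc[["live"]])
  }
  expect_equal(nrow(gate_live(sim$events, 0)), 0)
  expect_equal(nrow(gate_live(sim$events, Inf)), nrow(sim$events))
  expect_error(gate_live(sim$events, channel = "nope"), "not found")
})

test_that("auto valley gate recovers the simulated live/dead split", {
  sim <- sim_hac_flow(20000, 0.5, dead_fraction = 0.2, seed = 8)
  live <- gate_live(sim$events)
  live_frac <- nrow(live) / nrow(sim$events)
  expect_equal(live_frac, 1 - sim$truth$dead_fraction, tolerance = 0.02)
})

test_that("GFP+ fraction matches generator truth and rejects empty input", {
  sim <- sim_hac_flow(1e5, 0.7, dead_fraction = 0, seed = 5)
  est <- gfp_positive_fraction(sim$events, gfp_threshold = 1000)
  expect_equal(est, sim$truth$gfp_positive_fraction)
  se <- sqrt(0.7 * 0.3 / 1e5)
  expect_lt(abs(est - 0.7), 3 * se)
  hi <- sim_hac_flow(100, 1, seed = 1)$events
  expect_equal(gfp_positive_fraction(hi, 1000), 1)
  expect_equal(gfp_positive_fraction(hi, 1e9), 0)
  expect_error(gfp_positive_fraction(hi[0, ], 1000), "empty")
})

test_that("mixture fit collapses to one component for an undivided population", {
  u <- sim_dye_dilution(5000, c(1), cv = 0.08, seed = 3)
  fit <- fit_dye_dilution(u$events, u$events)
  expect_gte(fit$weights[["g0"]], 0.99)
  expect_equal(division_index(fit), 0, tolerance = 0.02)
})

test_that("mixture fit recovers a 50/50 two-peak profile", {
  s <- sim_dye_dilution(8000, c(0.5, 0.5), cv = 0.05, seed = 4)
  u <- sim_dye_dilution(4000, c(1), cv = 0.05, seed = 5)
  fit <- fit_dye_dilution(s$events, u$events)
  expect_equal(fit$weights[["g0"]], 0.5, tolerance = 0.02)
  expect_equal(fit$weights[["g1"]], 0.5, tolerance = 0.02)
  expect_lt(sum(fit$weights[3:7]), 0.02)
})

test_that("fit is invariant to event order and validates its inputs", {
  s <- sim_dye_dilution(3000, c(0.4, 0.6), seed = 6)
  u <- sim_dye_dilution(2000, c(1), seed = 7)
  f1 <- fit_dye_dilution(s$events, u$events)
  f2 <- fit_dye_dilution(s$events[rev(seq_len(3000)), ], u$events)
  expect_equal(f1$weights, f2$weights)
  expect_equal(f1$mu0, f2$mu0)
  const <- tibble::tibble(proliferation_dye = rep(100, 50))
  expect_error(fit_dye_dilution(s$events, const), "degenerate")
  expect_error(fit_dye_dilution(s$events[0, ], u$events), "nonempty")
})

test_that("division index formulas match hand evaluation", {
  for (def in c("precursor_weighted", "event_weighted")) {
    expect_equal(division_index(c(1), def), 0)
    expect_equal(division_index(c(0, 1), def), 1)
  }
  expect_equal(division_index(c(0.5, 0.5), "event_weighted"), 0.5)
  expect_equal(division_index(c(0.5, 0.5), "precursor_weighted"), 1 / 3)
  expect_error(division_index(c(-1, 2)), "non-negative")
})

test_that("loss-rate formula satisfies its identities and closed form", {
  expect_identical(hac_loss_rate(0.75, 0.75, 3.33), 0)
  expect_equal(hac_loss_rate(0.2, 0.8, 2), 1)
  expect_equal(hac_loss_rate(0.6, 0.9, 3.33),
               2 - 2 * exp(log(0.6 / 0.9) / 3.33), tolerance = 1e-12)
  # scale invariance: percentages and fractions agree
  expect_equal(hac_loss_rate(60, 90, 3.33), hac_loss_rate(0.6, 0.9, 3.33))
  # limits
  expect_equal(hac_loss_rate(1e-12, 0.9, 3.33), 2, tolerance = 1e-3)
  expect_error(hac_loss_rate(0.5, 0, 2), "p0")
  expect_error(hac_loss_rate(0.5, 0.8, 0), "n")
  expect_warning(r <- hac_loss_rate(0.9, 0.6, 2), "negative")
  expect_lt(r, 0)
})

test_that("loss rate decreases strictly in the treated fraction", {
  withr::with_seed(13, {
    for (i in 1:200) {
      p0 <- runif(1, 0.05, 1)
      n <- runif(1, 0.5, 6)
      ps <- sort(runif(2, 0, p0))
      expect_gt(hac_loss_rate(ps[1], p0, n), hac_loss_rate(ps[2], p0, n))
    }
  })
})

test_that("end-to-end estimate recovers the designed loss rate", {
  base <- sim_hac_flow(30000, 0.9, dead_fraction = 0.05, seed = 21)
  trt <- sim_hac_flow(30000, 0.6, dead_fraction = 0.05, seed = 22)
  dye <- sim_dye_dilution(20000, generation_weights_from_di(3.33), seed = 23)
  undiv <- sim_dye_dilution(10000, c(1), seed = 24)
  res <- estimate_hac_loss(base$events, trt$events, dye$events, undiv$events)
  expect_equal(res$rate, 2 - 2 * (0.6 / 0.9)^(1 / 3.33), tolerance = 0.05)
  expect_false(res$flagged)
  expect_equal(res$n, 3.33, tolerance = 0.05)
})
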