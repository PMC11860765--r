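test_that("dye-dilution truth matches hand-evaluated division indices", {
  s0 <- sim_dye_dilution(500, c(1), seed = 1)
  expect_equal(s0$truth$di_precursor, 0)
  expect_equal(s0$truth$di_event, 0)
  expect_true(all(s0$events$generation == 0))

  s1 <- sim_dye_dilution(500, c(0, 1), seed = 1)
  expect_equal(s1$truth$di_precursor, 1)
  expect_equal(s1$truth$di_event, 1)

  # w = {0: 0.5, 1: 0.5}: precursor-weighted (0*.5 + 1*.25)/(.5 + .25) = 1/3
  s2 <- sim_dye_dilution(500, c(0.5, 0.5), seed = 1)
  expect_equal(s2$truth$di_precursor, 1 / 3)
  expect_equal(s2$truth$di_event, 0.5)
})

test_that("dye-dilution peaks sit at halving positions with the stated CV", {
  s <- sim_dye_dilution(20000, c(0.5, 0.3, 0.2), undivided_mean = 8000,
                        cv = 0.05, peak_ratio = 0.5, seed = 7)
  lf <- log(s$events$proliferation_dye)
  for (g in 0:2) {
    sel <- s$events$generation == g
    expect_equal(mean(lf[sel]), log(8000) + g * log(0.5), tolerance = 0.01)
    expect_equal(sd(lf[sel]), 0.05, tolerance = 0.1)
  }
})

test_that("generators are pure functions of spec and seed", {
  a <- sim_dye_dilution(1000, c(0.3, 0.7), seed = 42)
  b <- sim_dye_dilution(1000, c(0.3, 0.7), seed = 42)
  expect_identical(a, b)
  h1 <- sim_hac_flow(1000, 0.6, 0.1, seed = 9)
  h2 <- sim_hac_flow(1000, 0.6, 0.1, seed = 9)
  expect_identical(h1, h2)
  expect_false(identical(a$events,
                         sim_dye_dilution(1000, c(0.3, 0.7), seed = 43)$events))
})

test_that("weights constructed for a target DI reproduce it exactly", {
  for (di in c(0.5, 2.80, 3.33, 3.62, 5.9)) {
    w <- generation_weights_from_di(di, n_generations = 6)
    expect_equal(division_index(w, "precursor_weighted"), di)
    we <- generation_weights_from_di(di, n_generations = 6, "event_weighted")
    expect_equal(division_index(we, "event_weighted"), di)
  }
  expect_error(generation_weights_from_di(7.5, 6), "lie in")
})

test_that("HAC flow mixtures realize the requested fractions", {
  all_pos <- sim_hac_flow(2000, gfp_positive_fraction = 1, dead_fraction = 0, seed = 1)
  expect_equal(all_pos$truth$gfp_positive_fraction, 1)
  expect_equal(all_pos$truth$dead_fraction, 0)
  none <- sim_hac_flow(2000, gfp_positive_fraction = 0, seed = 1)
  expect_equal(none$truth$gfp_positive_fraction, 0)
  big <- sim_hac_flow(1e5, gfp_positive_fraction = 0.7, dead_fraction = 0.2, seed = 3)
  se <- sqrt(0.7 * 0.3 / (1e5 * 0.8))
  expect_lt(abs(big$truth$gfp_positive_fraction - 0.7), 3 * se)
  expect_error(sim_hac_flow(10, 1.2), "fractions")
})

test_that("degenerate dye-dilution specs fail loudly", {
  expect_error(sim_dye_dilution(10, numeric(0)), "weights")
  expect_error(sim_dye_dilution(10, c(-1, 2)), "weights")
  expect_error(sim_dye_dilution(10, c(1), peak_ratio = 1), "peak_ratio")
})
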