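test_that("focus detection handles empty, single-blob and boundary cases", {
  labels <- matrix(0L, 20, 20); labels[5:15, 5:15] <- 1L
  zero <- matrix(0, 20, 20)
  expect_equal(nrow(detect_foci(zero, labels, threshold = 100)), 0)

  ch <- matrix(0, 20, 20); ch[9:11, 9:11] <- 500
  f <- detect_foci(ch, labels, threshold = 300)
  expect_equal(nrow(f), 1)
  expect_equal(c(f$row, f$col, f$cell_id, f$area), c(10, 10, 1, 9))

  # blob straddling the nucleus boundary is clipped to in-nucleus pixels
  ch2 <- matrix(0, 20, 20); ch2[4:6, 4:6] <- 500
  f2 <- detect_foci(ch2, labels, threshold = 300, min_area = 1)
  expect_equal(f2$area, 4) # only rows/cols 5:6 fall inside the nucleus
  expect_error(detect_foci(matrix(0, 5, 5), labels, 100), "same shape")
})

test_that("detection equals flood-fill labeling on random masked images", {
  withr::with_seed(31, {
    for (i in 1:15) {
      ch <- matrix(runif(400), 20, 20)
      labels <- matrix(0L, 20, 20)
      labels[3:18, 3:10] <- 1L; labels[3:18, 12:18] <- 2L
      f <- detect_foci(ch, labels, threshold = 0.6, min_area = 1)
      oracle <- oracle_label((ch >= 0.6) & (labels > 0), 8)
      expect_equal(nrow(f), max(oracle), info = paste("case", i))
    }
  })
})

test_that("patch extraction follows the even-box convention and drops border foci", {
  img <- matrix(seq_len(40 * 40), 40, 40)
  foci <- tibble::tibble(cell_id = 1L, focus_id = 1:2,
                         row = c(20L, 3L), col = c(20L, 20L))
  expect_message(p <- extract_patches(img, foci, box_size = 10), "dropped")
  expect_equal(nrow(p), 1)
  expect_identical(p$patch[[1]], img[15:24, 15:24])
  expect_equal(attr(p, "dropped")$focus_id, 2L)
  expect_error(extract_patches(img, foci, box_size = 9), "even")
})

test_that("a synthetic Gaussian focus peaks at the patch center pixel", {
  f <- sim_exofish_field(n_cells = 4, foci_per_cell = 1, noise_sd = 0,
                         width = 200, height = 200, seed = 6)
  det <- detect_foci(f$image, f$labels, threshold = 400)
  p <- extract_patches(f$image, det, box_size = 10)
  for (patch in p$patch) {
    expect_equal(which(patch == max(patch), arr.ind = TRUE)[1, ],
                 c(row = 6, col = 6))
  }
})

test_that("median focus equals the order-statistics oracle", {
  expect_identical(median_focus(list(matrix(7, 4, 4))), matrix(7, 4, 4))
  one_px <- lapply(c(1, 5, 9), function(v) matrix(v, 1, 1))
  expect_identical(median_focus(one_px), matrix(5, 1, 1))
  withr::with_seed(17, {
    for (n in c(2, 3, 4, 7)) {
      patches <- replicate(n, matrix(runif(9), 3, 3), simplify = FALSE)
      expect_equal(median_focus(patches), oracle_median_patch(patches))
    }
  })
  expect_error(median_focus(list()), "at least one")
})

test_that("perimeter background is the median of the outer ring", {
  expect_equal(perimeter_background(matrix(3, 5, 5)), 3)
  p <- matrix(10, 3, 3); p[2, 2] <- 100
  expect_equal(perimeter_background(p), 10)
  p4 <- matrix(0, 4, 4)
  ring_vals <- c(5, 1, 9, 2, 8, 3, 7, 4, 6, 10, 12, 11)
  p4[1, ] <- ring_vals[1:4]; p4[4, ] <- ring_vals[5:8]
  p4[2:3, 1] <- ring_vals[9:10]; p4[2:3, 4] <- ring_vals[11:12]
  p4[2:3, 2:3] <- 1000
  expect_equal(perimeter_background(p4), oracle_median(ring_vals))
  expect_error(perimeter_background(matrix(1, 2, 2)), "3x3")
})

test_that("focus signal sums without clamping and absorbs constant offsets", {
  expect_equal(focus_signal(matrix(4, 6, 6)), 0)
  p <- matrix(10, 3, 3); p[2, 2] <- 100
  expect_equal(focus_signal(p), 90)
  p_dim <- matrix(10, 3, 3); p_dim[2, 2] <- 5
  expect_equal(focus_signal(p_dim), -5)
  withr::with_seed(23, {
    for (i in 1:20) {
      patch <- matrix(sample(0:4095, 100, replace = TRUE), 10, 10)
      c0 <- sample(-500:500, 1)
      expect_identical(focus_signal(patch + c0), focus_signal(patch))
    }
  })
})

test_that("per-cell quantification reports skipped cells with reasons", {
  labels <- matrix(0L, 30, 30)
  labels[5:12, 5:12] <- 1L   # will hold a focus
  labels[18:25, 18:25] <- 2L # empty nucleus
  ch <- matrix(0, 30, 30); ch[8:9, 8:9] <- 600
  q <- quantify_foci(ch, labels, threshold = 300, box_size = 6)
  expect_equal(q$cell_id, 1L)
  skipped <- attr(q, "skipped")
  expect_equal(skipped$cell_id, 2L)
  expect_equal(skipped$reason, "no_foci")
})

test_that("anchored quantification: identical channel gives ratio 1, halved ~0.5", {
  a <- sim_anchored_field(n_cells = 9, signal_scales = c(same = 1),
                          noise_sd = 0, seed = 3)
  q <- anchored_quantify(a$channels$anchor, list(same = a$channels$anchor),
                         a$labels, threshold = 400)
  expect_equal(q$ratio[q$channel == "same"], rep(1, 9))

  zero <- anchored_quantify(a$channels$anchor,
                            list(z = matrix(0, nrow(a$channels$anchor),
                                            ncol(a$channels$anchor))),
                            a$labels, threshold = 400)
  expect_true(all(zero$signal_sum[zero$channel == "z"] <= 0))

  big <- sim_anchored_field(width = 800, height = 500, n_cells = 54,
                            signal_scales = c(half = 0.5), seed = 4)
  qh <- anchored_quantify(big$channels$anchor, big$channels["half"],
                          big$labels, threshold = 400)
  ratios <- qh$ratio[qh$channel == "half"]
  expect_gte(length(ratios), 50)
  expect_equal(mean(ratios), 0.5, tolerance = 0.10)
})

test_that("control normalization maps the control mean to exactly 1", {
  df <- tibble::tibble(signal = c(2, 4, 6, 8, 10, 12),
                       condition = rep(c("ctrl", "treat"), each = 3))
  out <- normalize_to_control(df, signal, condition, "ctrl")
  expect_equal(mean(out$normalized[out$condition == "ctrl"]), 1)
  expect_equal(mean(out$normalized[out$condition == "treat"]), 10 / 4)
  expect_error(normalize_to_control(df, signal, condition, "missing"), "not present")
  zero <- tibble::tibble(signal = c(0, 0, 5), condition = c("c", "c", "t"))
  expect_error(normalize_to_control(zero, signal, condition, "c"), "zero")
})
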