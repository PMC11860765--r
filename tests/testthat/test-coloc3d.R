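coloc_stack <- function(n_nuclei = 3, fractions = c(0.5, 0, 0.5), seed = 1,
                        amp_partner = 3000, dims = c(150, 150, 15)) {
  sim_stack(
    dims = dims, n_nuclei = n_nuclei, nucleus_radius = 1.8,
    channels = list(
      ref = list(n_spots = 0, spot_radius = 0.25, amplitude = 3000),
      partner = list(n_spots = 0, spot_radius = 0.25, amplitude = amp_partner)),
    engineered_overlaps = data.frame(ref_channel = "ref",
                                     partner_channel = "partner",
                                     fraction = fractions,
                                     nucleus_id = seq_len(n_nuclei)),
    seed = seed)
}

spot_pars <- list(smooth_sigma = c(1, 1, 0.3), seed_threshold = 1500,
                  include_threshold = 750)

test_that("3D Otsu segmentation recovers the true nuclear mask", {
  st <- coloc_stack(seed = 2)
  seg <- segment_nuclei_3d(st)
  agree <- mean((seg$mask) == (st$truth$nucleus_labels > 0))
  expect_gte(agree, 0.99)
  # voxels outside the mask are zeroed in every channel
  for (ch in names(seg$channels)) {
    expect_true(all(seg$channels[[ch]][!seg$mask] == 0))
  }
})

test_that("segmentation is idempotent on the masked stack", {
  st <- coloc_stack(seed = 3)
  seg1 <- segment_nuclei_3d(st)
  seg2 <- segment_nuclei_3d(seg1$channels, voxel_size = st$voxel_size)
  expect_identical(seg1$mask, seg2$mask)
})

test_that("a pure-noise stack yields an empty mask, not spurious nuclei", {
  noise <- list(dna = array(stats::rnorm(50 * 50 * 10, 100, 10), c(50, 50, 10)))
  expect_warning(seg <- segment_nuclei_3d(noise, voxel_size = c(0.1, 0.1, 0.71)),
                 "bimodal")
  expect_lt(mean(seg$mask), 0.01)
})

test_that("individualization count equals a 2D labeling oracle", {
  st <- coloc_stack(n_nuclei = 3, seed = 4)
  seg <- segment_nuclei_3d(st)
  recs <- individualize_nuclei(seg)
  proj <- apply(seg$mask, c(1, 2), any)
  expect_length(recs, max(oracle_label(proj, 8)))
  expect_length(recs, 3)
  # each crop holds its nucleus' full 3D mask
  total_in_crops <- sum(vapply(recs, function(r) sum(r$mask), numeric(1)))
  expect_equal(total_in_crops, sum(seg$mask))
})

test_that("QC rules exclude with the right reason codes", {
  recs <- list(
    stub_record(1, area_px = 350 / (0.1^2)),   # 350 um^2 at 0.1 um pixels
    stub_record(2, area_px = 150 / (0.1^2)),
    stub_record(3, area_px = 100, edge = TRUE),
    stub_record(4, area_px = 100)
  )
  ann <- data.frame(nucleus_id = 4, flag = "mitotic")
  qc <- qc_filter(recs, pixel_size = 0.1, annotations = ann)
  expect_equal(vapply(qc$kept, `[[`, numeric(1), "nucleus_id"), 2)
  expect_equal(qc$excluded$reason[qc$excluded$nucleus_id == 1], "too_large")
  expect_equal(qc$excluded$reason[qc$excluded$nucleus_id == 3], "edge")
  expect_equal(qc$excluded$reason[qc$excluded$nucleus_id == 4], "mitotic")
  expect_error(qc_filter(recs, 0.1, annotations = data.frame(nucleus_id = 1, flag = "ugly")),
               "unknown annotation")
})

test_that("selection returns exactly n shuffled nuclei, reproducibly", {
  recs <- lapply(1:150, stub_record)
  sel <- select_nuclei(recs, n = 100, seed = 7)
  expect_length(sel, 100)
  ids <- vapply(sel, `[[`, numeric(1), "nucleus_id")
  expect_false(all(ids == seq_len(100))) # order is shuffled
  sel2 <- select_nuclei(recs, n = 100, seed = 7)
  expect_identical(sel, sel2)
  expect_warning(few <- select_nuclei(lapply(1:40, stub_record), n = 100, seed = 1),
                 "only 40")
  expect_length(few, 40)
})

test_that("spot segmentation finds engineered foci and separates neighbours", {
  vol <- array(100, c(30, 30, 9))
  bump <- function(v, ctr, amp = 3000) {
    for (r in 1:30) for (c in 1:30) {
      d2 <- (r - ctr[1])^2 + (c - ctr[2])^2
      v[r, c, ctr[3]] <- v[r, c, ctr[3]] + amp * exp(-d2 / 8)
    }
    v
  }
  one <- bump(vol, c(15, 15, 5))
  s1 <- segment_spots(one, c(1, 1, 0.3), seed_threshold = 1500,
                      include_threshold = 750)
  expect_equal(nrow(s1), 1)
  peak <- which(one == max(one))
  expect_true(peak %in% s1$voxels[[1]])

  two <- bump(bump(vol, c(9, 9, 5)), c(21, 21, 5))
  s2 <- segment_spots(two, c(1, 1, 0.3), seed_threshold = 1500,
                      include_threshold = 750)
  expect_equal(nrow(s2), 2)
  expect_error(segment_spots(one, 1, seed_threshold = 10, include_threshold = 20),
               "seed_threshold")
})

test_that("volume overlap equals brute-force voxel counting", {
  mk <- function(id, vox) tibble::tibble(spot_id = id, n_voxels = length(vox),
                                         volume_um3 = NA, peak_intensity = NA,
                                         peak_idx = vox[1], voxels = list(sort(vox)))
  ref <- mk(1L, 1:8)
  partner <- mk(1L, 7:14)
  ev <- volume_overlap(ref, partner)
  expect_equal(ev$fraction, 2 / 8)
  expect_equal(ev$n_overlap, 2)

  same <- volume_overlap(ref, mk(1L, 1:8))
  expect_equal(same$fraction, 1)
  expect_equal(nrow(volume_overlap(ref, mk(1L, 100:120))), 0)

  withr::with_seed(41, {
    for (i in 1:50) {
      a <- sample(500, sample(5:40, 1))
      b <- sample(500, sample(5:40, 1))
      ev <- volume_overlap(mk(1L, a), mk(1L, b))
      brute <- length(intersect(a, b)) / length(a)
      if (brute == 0) expect_equal(nrow(ev), 0)
      else expect_equal(ev$fraction, brute)
    }
  })
})

test_that("the minimum-overlap filter is boundary inclusive", {
  ev <- tibble::tibble(fraction = c(0.05, 0.10, 0.15, 0.30))
  kept <- filter_events(ev)
  expect_equal(kept$fraction, c(0.10, 0.15, 0.30))
  expect_equal(nrow(filter_events(ev[0, ])), 0)
})

test_that("cohort summaries match hand-computed values", {
  none <- summarize_coloc(tibble::tibble(nucleus_id = integer(),
                                         fraction = numeric()), 1:5)
  expect_equal(none$fraction_with_event, 0)
  expect_equal(none$mean_events, 0)

  each1 <- summarize_coloc(tibble::tibble(nucleus_id = 1:4, fraction = 0.5), 1:4)
  expect_equal(each1$fraction_with_event, 1)
  expect_equal(each1$mean_events, 1)

  mixed <- summarize_coloc(
    tibble::tibble(nucleus_id = c(1, 1, 3), fraction = c(0.2, 0.4, 0.9)), 1:4)
  expect_equal(mixed$fraction_with_event, 0.5)
  expect_equal(mixed$mean_events, 0.75)
  expect_equal(tidy(mixed)$n_events, c(2L, 0L, 1L, 0L))
  expect_equal(glance(mixed)$median_overlap, 0.4)
})

test_that("full pipeline recovers engineered events; depletion drives them to 0", {
  st <- coloc_stack(n_nuclei = 3, fractions = c(0.5, 0, 0.5), seed = 11)
  res <- suppressWarnings(analyze_stack(st, "ref", "partner", spot_pars,
                                        n_select = 100, seed = 1))
  g <- glance(res$summary)
  expect_equal(g$n_nuclei, 3)
  expect_equal(g$fraction_with_event, 2 / 3)
  expect_equal(g$mean_events, 2 / 3)
  # depletion: partner amplitude at background level removes all events
  st0 <- coloc_stack(n_nuclei = 3, fractions = c(0.5, 0, 0.5), seed = 11,
                     amp_partner = 0)
  res0 <- suppressWarnings(analyze_stack(st0, "ref", "partner", spot_pars,
                                         n_select = 100, seed = 1))
  expect_equal(nrow(res0$events), 0)
  expect_equal(glance(res0$summary)$fraction_with_event, 0)
})

test_that("pipeline output is deterministic for fixed inputs and seed", {
  st <- coloc_stack(n_nuclei = 2, fractions = c(0.5, 0), seed = 12)
  r1 <- suppressWarnings(analyze_stack(st, "ref", "partner", spot_pars, seed = 3))
  r2 <- suppressWarnings(analyze_stack(st, "ref", "partner", spot_pars, seed = 3))
  expect_identical(r1$events, r2$events)
  expect_identical(glance(r1$summary), glance(r2$summary))
})
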