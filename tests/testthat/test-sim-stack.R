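spot_ch <- function(n_spots = 0, r = 0.25, amp = 3000) {
  list(n_spots = n_spots, spot_radius = r, amplitude = amp)
}

test_that("engineered identical and disjoint pairs hit fractions 1 and 0", {
  st <- sim_stack(dims = c(60, 60, 15), n_nuclei = 1, nucleus_radius = 2.2,
                  channels = list(a = spot_ch(), b = spot_ch()),
                  engineered_overlaps = data.frame(
                    ref_channel = "a", partner_channel = "b", fraction = 1),
                  noise_sd = 0, seed = 1)
  ov <- st$truth$overlaps
  expect_equal(ov$achieved, 1)
  expect_identical(st$truth$spots$voxels[[1]], st$truth$spots$voxels[[2]])

  st0 <- sim_stack(dims = c(60, 60, 15), n_nuclei = 1, nucleus_radius = 2.2,
                   channels = list(a = spot_ch(), b = spot_ch()),
                   engineered_overlaps = data.frame(
                     ref_channel = "a", partner_channel = "b", fraction = 0),
                   noise_sd = 0, seed = 1)
  vox <- st0$truth$spots$voxels
  expect_equal(st0$truth$overlaps$achieved, 0)
  expect_length(intersect(vox[[1]], vox[[2]]), 0)
})

test_that("recorded achieved overlap equals brute-force voxel counting", {
  st <- sim_stack(dims = c(80, 80, 15), n_nuclei = 1, nucleus_radius = 3,
                  channels = list(a = spot_ch(r = 0.5), b = spot_ch(r = 0.5)),
                  engineered_overlaps = data.frame(
                    ref_channel = "a", partner_channel = "b", fraction = 0.25),
                  noise_sd = 0, seed = 2)
  sp <- st$truth$spots
  ref <- sp$voxels[[which(sp$channel == "a")]]
  par <- sp$voxels[[which(sp$channel == "b")]]
  brute <- length(intersect(ref, par)) / length(ref)
  expect_equal(st$truth$overlaps$achieved, brute)
  expect_lt(abs(st$truth$overlaps$achieved - 0.25), 0.1)
  expect_true(all(st$truth$overlaps$achieved >= 0 & st$truth$overlaps$achieved <= 1))
})

test_that("stack generation is deterministic and validates its spec", {
  args <- list(dims = c(100, 100, 15), n_nuclei = 2, nucleus_radius = 1.8,
               channels = list(a = spot_ch(n_spots = 1)), seed = 9)
  expect_identical(do.call(sim_stack, args), do.call(sim_stack, args))
  expect_error(sim_stack(engineered_overlaps = data.frame(
    ref_channel = "halo", partner_channel = "halo", fraction = 1.5)), "fractions")
  expect_error(
    sim_stack(dims = c(60, 60, 15), n_nuclei = 1, nucleus_radius = 2.2,
              channels = list(a = spot_ch(r = 0.2), b = spot_ch(r = 0.4)),
              engineered_overlaps = data.frame(
                ref_channel = "a", partner_channel = "b", fraction = 0.5)),
    class = "censtab_unrealizable_overlap")
})

test_that("nucleus truth labels cover the DNA-bright voxels", {
  st <- sim_stack(dims = c(60, 60, 15), n_nuclei = 1, nucleus_radius = 2,
                  channels = list(a = spot_ch()), noise_sd = 0, seed = 4)
  expect_identical(st$truth$nucleus_labels > 0, st$channels$dna > 500)
})
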