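# Synthetic multi-channel confocal Z-stacks with engineered ground truth:
# ellipsoidal nuclei on a DNA channel, spherical foci in the other channels,
# and focus pairs placed at a controlled volume-overlap fraction. Default
# geometry mirrors common acquisition: 15 slices spanning 10.65 um in z
# (0.71 um spacing) and 0.1 um lateral pixels.

# Linear voxel indices of an ellipsoidal ball of radius r_um centered at
# (row, col, slice) on a grid with voxel_size = c(x, y, z) um.
ball_voxels <- function(center, r_um, dims, voxel_size) {
  semi <- pmax(r_um / voxel_size[c(2, 1, 3)], 1e-9) # rows<->y, cols<->x, z
  ext <- pmin(ceiling(semi), c(dims[1], dims[2], dims[3]))
  rs <- max(1, center[1] - ext[1]):min(dims[1], center[1] + ext[1])
  cs <- max(1, center[2] - ext[2]):min(dims[2], center[2] + ext[2])
  zs <- max(1, center[3] - ext[3]):min(dims[3], center[3] + ext[3])
  g <- expand.grid(r = rs, c = cs, z = zs)
  d2 <- ((g$r - center[1]) / semi[1])^2 + ((g$c - center[2]) / semi[2])^2 +
    ((g$z - center[3]) / semi[3])^2
  g <- g[d2 <= 1, ]
  sort((g$z - 1L) * dims[1] * dims[2] + (g$c - 1L) * dims[1] + g$r)
}

# Shift a voxel ball along columns (x) until its self-overlap fraction is
# closest to `target`; returns the shift and the achieved fraction.
overlap_shift <- function(vox, dims, target) {
  nrc <- dims[1] * dims[2]
  n <- length(vox)
  best <- c(shift = 0, achieved = 1)
  if (target >= 1) return(best)
  col0 <- ((vox - 1L) %% nrc) %/% dims[1] # 0-based columns
  max_shift <- 2L * (max(col0) - min(col0)) + 3L
  if (max(col0) + max_shift >= dims[2]) {
    abort("engineered overlap does not fit laterally in the stack",
          class = "censtab_unrealizable_overlap")
  }
  for (d in 1:max_shift) {
    shifted <- vox + d * dims[1]
    f <- length(intersect(vox, shifted)) / n
    if (abs(f - target) < abs(best["achieved"] - target)) {
      best <- c(shift = d, achieved = f)
    }
    if (f == 0) break
  }
  best
}

#' Simulate a multi-channel 3D stack with engineered focus overlaps
#'
#' Builds a Z-stack holding `n_nuclei` ellipsoidal nuclei (bright on the
#' `dna` channel) packed laterally on a jittered grid. Each non-DNA channel
#' receives spherical foci of known voxel sets: `engineered_overlaps` places
#' pairs of foci from two channels at a target volume-overlap fraction
#' (realized on the voxel grid and recorded exactly), and each channel's
#' `n_spots` adds well-separated singleton foci per nucleus.
#'
#' @param dims Stack dimensions `c(rows, cols, slices)` in voxels; the
#'   default z depth of 15 slices spans 10.65 um at the default spacing.
#' @param voxel_size Voxel size `c(x, y, z)` in um.
#' @param n_nuclei Number of nuclei.
#' @param nucleus_radius Lateral nucleus radius, um (z semi-axis is capped by
#'   the stack depth).
#' @param channels Named list of focus channels, each a list with elements
#'   `n_spots` (extra singleton foci per nucleus), `spot_radius` (um) and
#'   `amplitude` (a.u. above background).
#' @param engineered_overlaps `NULL`, or a data frame with columns
#'   `ref_channel`, `partner_channel`, `fraction` and optionally
#'   `nucleus_id` (assigned round-robin when absent). One focus pair is
#'   created per row.
#' @param nucleus_level,background,noise_sd DNA-channel intensity inside
#'   nuclei, global background, and additive Gaussian noise SD (clipped
#'   at 0).
#' @param seed Integer seed.
#' @return An object of class `vox_stack`: list with `channels` (named list
#'   of 3D arrays, `dna` first), `voxel_size`, and `truth` (list:
#'   `nuclei` tibble, `nucleus_labels` 3D integer array, `spots` tibble with
#'   a `voxels` list-column of linear indices, `overlaps` tibble with
#'   `target` and exact `achieved` fractions).
#' @export
sim_stack <- function(dims = c(96, 96, 15), voxel_size = c(0.1, 0.1, 0.71),
                      n_nuclei = 1, nucleus_radius = 2.2,
                      channels = list(halo = list(n_spots = 2, spot_radius = 0.3,
                                                  amplitude = 3000)),
                      engineered_overlaps = NULL,
                      nucleus_level = 1000, background = 100, noise_sd = 10,
                      seed = 1) {
  if (any(dims <= 0) || any(voxel_size <= 0)) abort("dims and voxel_size must be positive")
  if (!is.null(engineered_overlaps)) {
    engineered_overlaps <- tibble::as_tibble(engineered_overlaps)
    if (any(engineered_overlaps$fraction < 0 | engineered_overlaps$fraction > 1)) {
      abort("overlap fractions must lie in [0, 1]")
    }
    if (!"nucleus_id" %in% names(engineered_overlaps)) {
      engineered_overlaps$nucleus_id <-
        rep_len(seq_len(n_nuclei), nrow(engineered_overlaps))
    }
  }
  r_vox_lat <- nucleus_radius / voxel_size[1]
  withr::with_seed(seed, {
    centers <- pack_disks(n_nuclei, dims[2], dims[1], r_vox_lat, margin = 3)
    z_mid <- ceiling(dims[3] / 2)
    z_semi <- max(1, min(nucleus_radius / voxel_size[3], (dims[3] - 1) / 2))
    nuc_labels <- array(0L, dims)
    for (k in seq_len(n_nuclei)) {
      vox <- ball_voxels(c(centers$row[k], centers$col[k], z_mid),
                         nucleus_radius, dims, voxel_size)
      nuc_labels[vox] <- k
    }
    dna <- array(background, dims)
    dna[nuc_labels > 0] <- nucleus_level

    # per-nucleus spot sites on a vertical line through the center, spaced so
    # that neighbouring foci (and shifted overlap partners) never touch even
    # after the ~1-voxel dilation of threshold-based segmentation
    max_r_vox <- max(vapply(channels, function(ch) ch$spot_radius, numeric(1))) /
      voxel_size[1]
    site_step <- ceiling(2 * max_r_vox + 5)
    site_offsets <- c(0, -1, 1, -2, 2, -3, 3) * site_step
    next_site <- rep(1L, n_nuclei)
    take_site <- function(k) {
      i <- next_site[k]
      if (i > length(site_offsets) ||
          abs(site_offsets[i]) + max_r_vox + 2 > r_vox_lat - 1) {
        abort("too many foci requested for the nucleus size",
              class = "censtab_packing_error")
      }
      next_site[k] <<- i + 1L
      c(centers$row[k] + site_offsets[i], centers$col[k] - 2, z_mid)
    }

    vols <- lapply(channels, function(ch) array(background, dims))
    spots <- list(); overlaps <- list()
    spot_counter <- setNames(rep(0L, length(channels)), names(channels))
    add_spot <- function(channel, nucleus_id, vox) {
      spot_counter[channel] <<- spot_counter[channel] + 1L
      id <- spot_counter[[channel]]
      amp <- channels[[channel]]$amplitude
      v <- vols[[channel]]; v[vox] <- v[vox] + amp; vols[[channel]] <<- v
      spots[[length(spots) + 1L]] <<- tibble::tibble(
        channel = channel, nucleus_id = nucleus_id, spot_id = id,
        n_voxels = length(vox), voxels = list(vox))
      id
    }

    if (!is.null(engineered_overlaps)) {
      for (i in seq_len(nrow(engineered_overlaps))) {
        ev <- engineered_overlaps[i, ]
        for (ch in c(ev$ref_channel, ev$partner_channel)) {
          if (!ch %in% names(channels)) abort(paste0("unknown channel `", ch, "`"))
        }
        k <- ev$nucleus_id
        center <- take_site(k)
        r_ref <- channels[[ev$ref_channel]]$spot_radius
        r_par <- channels[[ev$partner_channel]]$spot_radius
        if (abs(r_ref - r_par) > 1e-9 && ev$fraction > 0) {
          abort("engineered overlaps require equal spot radii in both channels",
                class = "censtab_unrealizable_overlap")
        }
        vox_ref <- ball_voxels(center, r_ref, dims, voxel_size)
        if (ev$fraction > 0) {
          os <- overlap_shift(vox_ref, dims, ev$fraction)
          vox_par <- vox_ref + os[["shift"]] * dims[1]
          achieved <- os[["achieved"]]
        } else {
          # disjoint partner: separate site on the same line
          center2 <- take_site(k)
          vox_par <- ball_voxels(center2, r_par, dims, voxel_size)
          achieved <- 0
        }
        id_ref <- add_spot(ev$ref_channel, k, vox_ref)
        id_par <- add_spot(ev$partner_channel, k, vox_par)
        overlaps[[length(overlaps) + 1L]] <- tibble::tibble(
          nucleus_id = k, ref_channel = ev$ref_channel,
          partner_channel = ev$partner_channel,
          ref_spot = id_ref, partner_spot = id_par,
          target = ev$fraction, achieved = achieved)
      }
    }
    for (ch in names(channels)) {
      ns <- channels[[ch]]$n_spots %||% 0
      if (ns > 0) {
        for (k in seq_len(n_nuclei)) for (j in seq_len(ns)) {
          add_spot(ch, k, ball_voxels(take_site(k), channels[[ch]]$spot_radius,
                                      dims, voxel_size))
        }
      }
    }

    all_channels <- c(list(dna = dna), vols)
    if (noise_sd > 0) {
      all_channels <- lapply(all_channels, function(v)
        pmax(v + array(rnorm(prod(dims), sd = noise_sd), dims), 0))
    }
    structure(
      list(channels = all_channels, voxel_size = voxel_size,
           truth = list(
             nuclei = tibble::tibble(nucleus_id = seq_len(n_nuclei),
                                     row = centers$row, col = centers$col,
                                     slice = z_mid,
                                     radius_um = nucleus_radius),
             nucleus_labels = nuc_labels,
             spots = if (length(spots)) dplyr::bind_rows(spots) else
               tibble::tibble(channel = character(), nucleus_id = integer(),
                              spot_id = integer(), n_voxels = integer(),
                              voxels = list()),
             overlaps = if (length(overlaps)) dplyr::bind_rows(overlaps) else
               tibble::tibble(nucleus_id = integer(), ref_channel = character(),
                              partner_channel = character(), ref_spot = integer(),
                              partner_spot = integer(), target = numeric(),
                              achieved = numeric())
           )),
      class = "vox_stack")
  })
}

#' @export
print.vox_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("Synthetic Z-stack: %d x %d x %d voxels (%.3g x %.3g x %.3g um), %d channel(s): %s\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              length(x$channels), paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  %d nuclei, %d foci, %d engineered overlap pair(s)\n",
              nrow(x$truth$nuclei), nrow(x$truth$spots), nrow(x$truth$overlaps)))
  invisible(x)
}
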