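# Object-based 3D colocalization: nuclei are segmented by a global Otsu
# threshold on the DNA channel, individualized from the maximum-Z
# projection, quality-filtered, randomized and capped per condition; foci
# are segmented per nucleus by seeded region growing; colocalization is
# scored as the fraction of each reference focus volume overlapped by a
# partner focus, with a minimum-overlap filter against chance apposition.

stack_channels <- function(stack) {
  if (inherits(stack, "vox_stack")) stack$channels else stack
}

stack_voxel_size <- function(stack, voxel_size) {
  if (!is.null(voxel_size)) voxel_size
  else if (inherits(stack, "vox_stack")) stack$voxel_size
  else c(0.1, 0.1, 0.71)
}

#' Segment nuclei in 3D by Otsu thresholding
#'
#' A single global Otsu threshold (256-bin histogram of the whole DNA
#' channel) defines the nuclear mask; every channel's voxel intensities
#' outside the mask are set to 0. If the DNA histogram is not bimodal
#' enough to support a foreground/background split (Otsu effectiveness
#' below `min_effectiveness`), an empty mask is returned with a warning
#' rather than a spurious segmentation of noise.
#'
#' @param stack A `vox_stack` from [sim_stack()], or a named list of 3D
#'   arrays.
#' @param dna_channel Name of the DNA channel.
#' @param voxel_size Voxel size `c(x, y, z)` in um; taken from the
#'   `vox_stack` when `NULL`.
#' @param min_effectiveness Minimum Otsu between-class/total variance ratio
#'   required to accept the threshold (default 0.75).
#' @return Object of class `segmented_stack`: list with `mask` (logical 3D
#'   array), `channels` (masked arrays), `threshold`, `voxel_size`.
#' @export
segment_nuclei_3d <- function(stack, dna_channel = "dna", voxel_size = NULL,
                              min_effectiveness = 0.75) {
  channels <- stack_channels(stack)
  voxel_size <- stack_voxel_size(stack, voxel_size)
  if (!dna_channel %in% names(channels)) {
    abort(paste0("DNA channel `", dna_channel, "` not found"))
  }
  dna <- channels[[dna_channel]]
  thr <- otsu_threshold(dna)
  eff <- attr(thr, "effectiveness")
  if (eff < min_effectiveness) {
    warn(sprintf("DNA histogram not bimodal (Otsu effectiveness %.2f): returning an empty mask", eff))
    mask <- array(FALSE, dim(dna))
  } else {
    mask <- dna > as.numeric(thr)
  }
  masked <- lapply(channels, function(v) { v[!mask] <- 0; v })
  structure(list(mask = mask, channels = masked, threshold = as.numeric(thr),
                 effectiveness = eff, dna_channel = dna_channel,
                 voxel_size = voxel_size),
            class = "segmented_stack")
}

#' Individualize nuclei from the maximum-Z projection
#'
#' A secondary 2D segmentation on the maximum-Z projection of the masked
#' stack (non-zero pixels, holes filled, 8-connected components) splits the
#' field into single nuclei; each nucleus' Z-stack is duplicated into its
#' own crop (bounding box padded by 2 pixels laterally, full depth).
#'
#' @param seg A `segmented_stack` from [segment_nuclei_3d()].
#' @param pad Lateral bounding-box padding in pixels (default 2).
#' @return List of nucleus records, each a list with `nucleus_id`,
#'   `channels` (cropped arrays), `mask` (cropped 3D mask restricted to
#'   this nucleus), `mask2d` (cropped projection mask), `bbox`,
#'   `projected_area_px`, `touches_edge`. Zero nuclei gives an empty list.
#' @export
individualize_nuclei <- function(seg, pad = 2) {
  if (!inherits(seg, "segmented_stack")) abort("`seg` must come from segment_nuclei_3d()")
  d <- dim(seg$mask)
  proj <- apply(seg$mask, c(1, 2), any)
  proj <- fill_holes(proj)
  lab <- label_components(proj, connectivity = 8)
  n <- max(lab)
  if (n == 0) return(list())
  lapply(seq_len(n), function(k) {
    px <- which(lab == k)
    r <- ((px - 1L) %% d[1]) + 1L
    c <- ((px - 1L) %/% d[1]) + 1L
    rows <- max(1L, min(r) - pad):min(d[1], max(r) + pad)
    cols <- max(1L, min(c) - pad):min(d[2], max(c) + pad)
    in2d <- matrix(FALSE, d[1], d[2]); in2d[px] <- TRUE
    mask3d <- seg$mask & array(in2d, d) # this nucleus' voxels only
    list(
      nucleus_id = k,
      channels = lapply(seg$channels, function(v) v[rows, cols, , drop = FALSE]),
      mask = mask3d[rows, cols, , drop = FALSE],
      mask2d = in2d[rows, cols, drop = FALSE],
      bbox = c(row_min = min(rows), row_max = max(rows),
               col_min = min(cols), col_max = max(cols)),
      projected_area_px = length(px),
      touches_edge = any(r == 1L | r == d[1] | c == 1L | c == d[2]),
      voxel_size = seg$voxel_size
    )
  })
}

qc_manual_flags <- c("mitotic", "overlapping", "out_of_focus",
                     "bad_segmentation", "apoptotic")

#' Quality-filter individualized nuclei
#'
#' Applies the exclusion rules: automatic rules `edge` (projection touches a
#' lateral image border) and `too_large` (projected area above
#' `area_limit_um2`), plus annotation-driven flags for the criteria that are
#' human judgments (`mitotic`, `overlapping`, `out_of_focus`,
#' `bad_segmentation`, `apoptotic`). Every excluded nucleus carries its
#' reason code(s).
#'
#' @param records List of nucleus records from [individualize_nuclei()].
#' @param pixel_size Lateral pixel size in um (projected area =
#'   pixels * pixel_size^2).
#' @param area_limit_um2 Maximum projected area in um^2 (default 300).
#' @param annotations Optional data frame (`nucleus_id`, `flag`) of manual
#'   exclusion flags.
#' @return List with `kept` (records passing all rules, each with an empty
#'   `qc_flags`) and `excluded` (tibble: `nucleus_id`, `reason`, one row per
#'   reason).
#' @export
qc_filter <- function(records, pixel_size, area_limit_um2 = 300,
                      annotations = NULL) {
  if (!is.null(annotations)) {
    bad <- setdiff(unique(annotations$flag), qc_manual_flags)
    if (length(bad)) {
      abort(paste0("unknown annotation flag(s): ", paste(bad, collapse = ", ")))
    }
  }
  kept <- list(); excl <- list()
  for (rec in records) {
    reasons <- character()
    if (rec$touches_edge) reasons <- c(reasons, "edge")
    if (rec$projected_area_px * pixel_size^2 > area_limit_um2) {
      reasons <- c(reasons, "too_large")
    }
    if (!is.null(annotations)) {
      reasons <- c(reasons,
                   annotations$flag[annotations$nucleus_id == rec$nucleus_id])
    }
    rec$qc_flags <- reasons
    if (length(reasons)) {
      excl[[length(excl) + 1L]] <- tibble::tibble(nucleus_id = rec$nucleus_id,
                                                  reason = reasons)
    } else {
      kept[[length(kept) + 1L]] <- rec
    }
  }
  list(kept = kept,
       excluded = if (length(excl)) dplyr::bind_rows(excl) else
         tibble::tibble(nucleus_id = integer(), reason = character()))
}

#' Randomize and cap the nuclei analyzed per condition
#'
#' Uniformly shuffles the pooled nuclei of a condition with the given seed
#' and returns the first `n` (all of them, with a warning, if fewer are
#' available) -- the unbiased-selection step that fixes the analyzed sample
#' size per condition.
#'
#' @param records List of QC-passing nucleus records.
#' @param n Number to keep (default 100).
#' @param seed Integer seed; the same seed always selects the same subset.
#' @return List of selected records, in shuffled order.
#' @export
select_nuclei <- function(records, n = 100, seed = 1) {
  ord <- withr::with_seed(seed, sample(length(records)))
  if (length(records) < n) {
    warn(sprintf("only %d nuclei available (requested %d): returning all",
                 length(records), n))
  }
  records[ord][seq_len(min(n, length(records)))]
}

#' Segment foci in a 3D volume by seeded region growing
#'
#' The volume is Gaussian-smoothed; 26-connected local maxima above
#' `seed_threshold` become seeds; regions grow (26-connected, breadth-first)
#' over voxels with smoothed intensity at or above `include_threshold`,
#' contended voxels going to the nearest seed (ties to the brighter seed).
#' Spots outside the volume bounds are discarded. Both thresholds apply to
#' the smoothed intensities.
#'
#' @param volume 3D intensity array (one channel, typically a nucleus crop).
#' @param smooth_sigma Gaussian smoothing SD in voxels (scalar or per-axis).
#' @param seed_threshold Minimum smoothed intensity of a local maximum
#'   seeding a spot; must be >= `include_threshold`.
#' @param include_threshold Smoothed intensity down to which regions grow.
#' @param min_volume,max_volume Spot volume bounds in voxels.
#' @param voxel_size Voxel size `c(x, y, z)` in um (for `volume_um3`).
#' @return Tibble (class `spot_set` via its `channel` attribute not needed):
#'   `spot_id`, `n_voxels`, `volume_um3`, `peak_intensity` (original, not
#'   smoothed), `peak_idx` (linear index of the seed), `voxels` (list-column
#'   of sorted linear indices). Empty tibble when nothing is found.
#' @export
segment_spots <- function(volume, smooth_sigma = 1, seed_threshold,
                          include_threshold, min_volume = 4, max_volume = Inf,
                          voxel_size = c(0.1, 0.1, 0.71)) {
  if (seed_threshold < include_threshold) {
    abort("`seed_threshold` must be >= `include_threshold`")
  }
  empty <- tibble::tibble(spot_id = integer(), n_voxels = integer(),
                          volume_um3 = numeric(), peak_intensity = numeric(),
                          peak_idx = integer(), voxels = list())
  sm <- gaussian_smooth_3d(volume, smooth_sigma)
  seeds <- local_maxima_3d(sm, seed_threshold)
  if (!length(seeds)) return(empty)
  # brighter seeds get lower rank so they win frontier ties deterministically
  seeds <- seeds[order(-sm[seeds], seeds)]
  lab <- region_grow_3d(sm, seeds, include_threshold)
  out <- purrr::map_dfr(seq_along(seeds), function(i) {
    vox <- which(lab == i)
    tibble::tibble(spot_id = i, n_voxels = length(vox),
                   volume_um3 = length(vox) * prod(voxel_size),
                   peak_intensity = max(volume[vox]),
                   peak_idx = seeds[i], voxels = list(sort(vox)))
  })
  out <- out[out$n_voxels >= min_volume & out$n_voxels <= max_volume, ]
  out$spot_id <- seq_len(nrow(out))
  out
}

#' Volume-overlap events between two spot sets
#'
#' For every reference spot, every partner spot with a non-empty voxel
#' intersection yields an event with `fraction = |ref intersect partner| /
#' |ref|` -- the fraction of the reference focus volume overlapped. The
#' denominator is the reference channel by convention (direction is chosen
#' by argument order).
#'
#' @param reference,partner Spot tibbles from [segment_spots()], on the same
#'   voxel grid.
#' @return Tibble: `ref_spot`, `partner_spot`, `n_overlap`, `n_ref`,
#'   `fraction`.
#' @export
volume_overlap <- function(reference, partner) {
  out <- list()
  for (i in seq_len(nrow(reference))) {
    rv <- reference$voxels[[i]]
    for (j in seq_len(nrow(partner))) {
      n_ov <- sum(rv %in% partner$voxels[[j]])
      if (n_ov > 0) {
        out[[length(out) + 1L]] <- tibble::tibble(
          ref_spot = reference$spot_id[i], partner_spot = partner$spot_id[j],
          n_overlap = n_ov, n_ref = length(rv), fraction = n_ov / length(rv))
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(ref_spot = integer(), partner_spot = integer(),
                   n_overlap = integer(), n_ref = integer(), fraction = numeric())
}

#' Filter colocalization events by minimum overlap
#'
#' Keeps events whose overlap fraction is at least `min_fraction`
#' (boundary inclusive: an exact 10% overlap is kept under the default),
#' excluding low-overlap false positives.
#'
#' @param events Event tibble with a `fraction` column.
#' @param min_fraction Minimum overlap fraction (default 0.10).
#' @return Filtered tibble.
#' @export
filter_events <- function(events, min_fraction = 0.10) {
  dplyr::filter(events, .data$fraction >= min_fraction)
}

#' Run focus segmentation and overlap scoring across nuclei
#'
#' Applies [segment_spots()] to the reference and partner channels of each
#' nucleus record, scores [volume_overlap()] events (reference volume in the
#' denominator), and applies the minimum-overlap filter.
#'
#' @param records List of nucleus records (after QC/selection).
#' @param ref_channel,partner_channel Channel names.
#' @param spot_params Named list of [segment_spots()] settings
#'   (`smooth_sigma`, `seed_threshold`, `include_threshold`, `min_volume`,
#'   `max_volume`), shared by both channels or a list of two such lists
#'   named by channel.
#' @param min_fraction Minimum overlap fraction (default 0.10).
#' @return List: `events` (tibble with `nucleus_id` + event columns),
#'   `focus_counts` (tibble: `nucleus_id`, per-channel focus counts),
#'   `nuclei` (vector of nucleus ids analyzed).
#' @export
coloc_nuclei <- function(records, ref_channel, partner_channel, spot_params,
                         min_fraction = 0.10) {
  pars_for <- function(ch) {
    if (ch %in% names(spot_params) && is.list(spot_params[[ch]])) spot_params[[ch]]
    else spot_params
  }
  ev <- list(); fc <- list()
  for (rec in records) {
    vs <- rec$voxel_size %||% c(0.1, 0.1, 0.71)
    seg <- function(ch) {
      p <- pars_for(ch)
      segment_spots(rec$channels[[ch]],
                    smooth_sigma = p$smooth_sigma %||% 1,
                    seed_threshold = p$seed_threshold,
                    include_threshold = p$include_threshold,
                    min_volume = p$min_volume %||% 4,
                    max_volume = p$max_volume %||% Inf,
                    voxel_size = vs)
    }
    ref <- seg(ref_channel)
    par <- seg(partner_channel)
    e <- filter_events(volume_overlap(ref, par), min_fraction)
    if (nrow(e)) ev[[length(ev) + 1L]] <- dplyr::mutate(e, nucleus_id = rec$nucleus_id,
                                                        .before = 1)
    fc[[length(fc) + 1L]] <- tibble::tibble(
      nucleus_id = rec$nucleus_id,
      !!ref_channel := nrow(ref), !!partner_channel := nrow(par))
  }
  list(
    events = if (length(ev)) dplyr::bind_rows(ev) else
      tibble::tibble(nucleus_id = integer(), ref_spot = integer(),
                     partner_spot = integer(), n_overlap = integer(),
                     n_ref = integer(), fraction = numeric()),
    focus_counts = dplyr::bind_rows(fc),
    nuclei = vapply(records, `[[`, integer(1), "nucleus_id")
  )
}

#' Summarize colocalization over a cohort of nuclei
#'
#' Per-nucleus event counts, the fraction of nuclei with at least one
#' event, the mean events per nucleus, the distribution of overlap
#' fractions, and (when provided) per-channel focus counts per nucleus.
#'
#' @param events Event tibble with `nucleus_id` and `fraction` columns
#'   (post-filter).
#' @param nuclei Vector of all analyzed nucleus ids (so event-free nuclei
#'   count), or a data frame with a `nucleus_id` column (e.g. the
#'   `focus_counts` from [coloc_nuclei()], whose per-channel counts are then
#'   carried along).
#' @return Object of class `coloc_summary`. [tidy()] gives the per-nucleus
#'   table, [glance()] the cohort summary.
#' @export
summarize_coloc <- function(events, nuclei) {
  focus_counts <- NULL
  if (is.data.frame(nuclei)) {
    focus_counts <- nuclei
    ids <- nuclei$nucleus_id
  } else ids <- nuclei
  if (!length(ids)) abort("no nuclei to summarize")
  per <- tibble::tibble(nucleus_id = ids) |>
    dplyr::left_join(dplyr::count(events, .data$nucleus_id, name = "n_events"),
                     by = "nucleus_id") |>
    dplyr::mutate(n_events = dplyr::coalesce(.data$n_events, 0L))
  if (!is.null(focus_counts)) per <- dplyr::left_join(per, focus_counts, by = "nucleus_id")
  structure(
    list(per_nucleus = per,
         n_nuclei = length(ids),
         fraction_with_event = mean(per$n_events >= 1),
         mean_events = mean(per$n_events),
         overlap_fractions = events$fraction),
    class = "coloc_summary")
}

#' @export
print.coloc_summary <- function(x, ...) {
  cat(sprintf("Colocalization over %d nuclei: %.1f%% with >=1 event, %.3g events/nucleus\n",
              x$n_nuclei, 100 * x$fraction_with_event, x$mean_events))
  invisible(x)
}

#' @export
tidy.coloc_summary <- function(x, ...) x$per_nucleus

#' @export
glance.coloc_summary <- function(x, ...) {
  tibble::tibble(n_nuclei = x$n_nuclei,
                 fraction_with_event = x$fraction_with_event,
                 mean_events = x$mean_events,
                 n_events = length(x$overlap_fractions),
                 median_overlap = if (length(x$overlap_fractions))
                   median(x$overlap_fractions) else NA_real_)
}

#' Full 3D colocalization pipeline on one stack
#'
#' Chains [segment_nuclei_3d()], [individualize_nuclei()], [qc_filter()],
#' [select_nuclei()], [coloc_nuclei()] and [summarize_coloc()].
#'
#' @inheritParams segment_nuclei_3d
#' @inheritParams coloc_nuclei
#' @param n_select Nuclei analyzed per condition (default 100).
#' @param seed Seed for the randomized selection.
#' @param area_limit_um2,annotations QC settings, see [qc_filter()].
#' @return List: `summary` (a `coloc_summary`), `events`, `focus_counts`,
#'   `excluded` (QC exclusions), `n_segmented`.
#' @export
analyze_stack <- function(stack, ref_channel, partner_channel, spot_params,
                          dna_channel = "dna", voxel_size = NULL,
                          min_fraction = 0.10, n_select = 100, seed = 1,
                          area_limit_um2 = 300, annotations = NULL) {
  voxel_size <- stack_voxel_size(stack, voxel_size)
  seg <- segment_nuclei_3d(stack, dna_channel, voxel_size)
  recs <- individualize_nuclei(seg)
  qc <- qc_filter(recs, pixel_size = voxel_size[1], area_limit_um2 = area_limit_um2,
                  annotations = annotations)
  sel <- select_nuclei(qc$kept, n = n_select, seed = seed)
  cl <- coloc_nuclei(sel, ref_channel, partner_channel, spot_params, min_fraction)
  list(summary = summarize_coloc(cl$events, cl$focus_counts),
       events = cl$events, focus_counts = cl$focus_counts,
       excluded = qc$excluded, n_segmented = length(recs))
}
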