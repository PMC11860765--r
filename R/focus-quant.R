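# Per-cell "median focus" quantification for FISH and immunofluorescence
# fields: threshold-detected foci, fixed-size boxes around each focus, a
# pixel-wise median focus per cell, perimeter-median background subtraction,
# and the background-subtracted signal sum. Also the anchored variant where
# one channel (e.g. CENP-B) defines the boxes in which a second channel
# (e.g. CENP-A) is quantified.

#' Detect foci by thresholding within nuclei
#'
#' Foci are 8-connected components of `channel >= threshold` restricted to
#' pixels inside a nucleus (`nucleus_labels > 0`), with at least `min_area`
#' pixels. Each focus is reported at its centroid (mean pixel position,
#' rounded half-up) and assigned to the nucleus label under the centroid
#' (majority label of the component if the centroid falls outside a
#' nucleus).
#'
#' @param channel Intensity matrix.
#' @param nucleus_labels Integer label matrix of nuclei (same shape).
#' @param threshold Detection threshold (a.u.); for 12-bit-like data values
#'   around 300-600 are typical.
#' @param min_area Minimum component area in pixels (default 2, suppressing
#'   single-pixel noise).
#' @return Tibble: `cell_id`, `focus_id` (within the field), `row`, `col`,
#'   `area`. Empty (zero rows) when nothing is detected.
#' @export
detect_foci <- function(channel, nucleus_labels, threshold, min_area = 2) {
  if (!all(dim(channel) == dim(nucleus_labels))) {
    abort("`channel` and `nucleus_labels` must have the same shape")
  }
  if (threshold <= 0) abort("`threshold` must be positive")
  mask <- (channel >= threshold) & (nucleus_labels > 0)
  lab <- label_components(mask, connectivity = 8)
  st <- component_stats(lab)
  st <- st[st$area >= min_area, ]
  if (!nrow(st)) {
    return(tibble::tibble(cell_id = integer(), focus_id = integer(),
                          row = integer(), col = integer(), area = integer()))
  }
  cell <- nucleus_labels[cbind(st$row, st$col)]
  if (any(cell == 0)) {
    # concave component whose centroid is outside any nucleus: majority label
    for (i in which(cell == 0)) {
      px <- which(lab == st$object_id[i])
      labs <- nucleus_labels[px]
      labs <- labs[labs > 0]
      cell[i] <- as.integer(names(which.max(table(labs))))
    }
  }
  tibble::tibble(cell_id = as.integer(cell), focus_id = seq_len(nrow(st)),
                 row = st$row, col = st$col, area = st$area)
}

#' Extract fixed-size boxes around focus centroids
#'
#' Cuts a `box_size` x `box_size` patch around each focus. For an even box
#' of side s centered at (r, c) the rows are `r - s/2` to `r + s/2 - 1` (and
#' likewise columns), so the centroid sits at patch position
#' `(s/2 + 1, s/2 + 1)`. Foci whose box would cross the image boundary are
#' dropped and reported.
#'
#' @param channel Intensity matrix.
#' @param foci Tibble with `cell_id`, `focus_id`, `row`, `col` (from
#'   [detect_foci()], or anchor-channel foci for anchored quantification).
#' @param box_size Even box side, conventionally 10-20 pixels.
#' @return Tibble `cell_id`, `focus_id`, `patch` (list-column of matrices).
#'   Dropped border foci are attached as attribute `"dropped"` and announced
#'   with a message.
#' @export
extract_patches <- function(channel, foci, box_size = 10) {
  if (box_size %% 2 != 0 || box_size < 4) abort("`box_size` must be an even integer >= 4")
  h <- box_size / 2
  nr <- nrow(channel); nc <- ncol(channel)
  ok <- foci$row - h >= 1 & foci$row + h - 1 <= nr &
    foci$col - h >= 1 & foci$col + h - 1 <= nc
  dropped <- foci[!ok, ]
  if (nrow(dropped)) {
    inform(sprintf("%d focus/foci dropped: box of size %d exceeds the image bounds",
                   nrow(dropped), box_size))
  }
  kept <- foci[ok, ]
  patches <- purrr::map2(kept$row, kept$col, function(r, c) {
    channel[(r - h):(r + h - 1), (c - h):(c + h - 1), drop = FALSE]
  })
  out <- tibble::tibble(cell_id = kept$cell_id, focus_id = kept$focus_id,
                        patch = patches)
  attr(out, "dropped") <- dropped
  out
}

#' Pixel-wise median focus of a set of patches
#'
#' The per-cell median focus: output pixel (i, j) is the median over patches
#' of pixel (i, j). An even number of patches uses the mean of the two
#' central order statistics.
#'
#' @param patches List of equally sized square matrices (one cell's
#'   patches), or a patch tibble from [extract_patches()] (all its patches
#'   are pooled).
#' @return Matrix of the same size as each patch.
#' @export
median_focus <- function(patches) {
  if (is.data.frame(patches)) patches <- patches$patch
  if (!length(patches)) abort("no patches: cell must have at least one focus")
  dims <- vapply(patches, dim, integer(2))
  if (any(dims != dims[, 1])) abort("all patches must have identical size")
  arr <- array(unlist(patches), dim = c(dims[1, 1], dims[2, 1], length(patches)))
  apply(arr, c(1, 2), median)
}

#' Background estimate from the patch perimeter
#'
#' The median of the outermost one-pixel ring of the patch (4 * (s - 1)
#' values for an s x s patch), the local background estimate that is
#' subtracted from the median focus.
#'
#' @param patch Square matrix, at least 3 x 3.
#' @return Scalar background level.
#' @export
perimeter_background <- function(patch) {
  s <- nrow(patch)
  if (s < 3 || ncol(patch) != s) abort("`patch` must be square and at least 3x3")
  ring <- c(patch[1, ], patch[s, ], patch[2:(s - 1), 1], patch[2:(s - 1), s])
  median(ring)
}

#' Background-subtracted focus signal sum
#'
#' `sum(patch - background)`: total fluorescence of the median focus above
#' local background, capturing both focus intensity and size. Negative
#' differences are retained (no clamping), so adding a constant to the whole
#' patch leaves the signal unchanged (the perimeter background absorbs it).
#'
#' @param patch Median-focus matrix.
#' @param background Scalar background, by default
#'   [perimeter_background()] of the patch.
#' @return Scalar signal sum (may be negative for empty boxes).
#' @export
focus_signal <- function(patch, background = perimeter_background(patch)) {
  sum(patch - background)
}

#' Per-cell median-focus quantification of one channel
#'
#' Runs the full per-cell procedure: detect foci, cut boxes, build the
#' median focus, estimate the perimeter background, and sum the
#' background-subtracted signal. Cells whose foci were all dropped at the
#' border, or with no detected foci, are skipped with a reason.
#'
#' @inheritParams detect_foci
#' @inheritParams extract_patches
#' @param keep_patches Keep each cell's median-focus matrix in a `patch`
#'   list-column (default `FALSE`).
#' @return Tibble: `cell_id`, `n_foci`, `background`, `signal_sum`
#'   (+ `patch`). Skipped cells are attached as attribute `"skipped"`
#'   (`cell_id`, `reason`).
#' @export
quantify_foci <- function(channel, nucleus_labels, threshold, min_area = 2,
                          box_size = 10, keep_patches = FALSE) {
  foci <- detect_foci(channel, nucleus_labels, threshold, min_area)
  all_cells <- sort(unique(as.integer(nucleus_labels[nucleus_labels > 0])))
  patches <- extract_patches(channel, foci, box_size)
  res <- patches |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_map(function(g, key) {
      mf <- median_focus(g$patch)
      bg <- perimeter_background(mf)
      tibble::tibble(cell_id = key$cell_id, n_foci = nrow(g), background = bg,
                     signal_sum = focus_signal(mf, bg),
                     patch = if (keep_patches) list(mf) else list(NULL))
    }) |>
    dplyr::bind_rows()
  if (!nrow(res)) {
    res <- tibble::tibble(cell_id = integer(), n_foci = integer(),
                          background = numeric(), signal_sum = numeric(),
                          patch = list())
  }
  if (!keep_patches) res$patch <- NULL
  skipped <- setdiff(all_cells, res$cell_id)
  attr(res, "skipped") <- tibble::tibble(
    cell_id = skipped,
    reason = ifelse(skipped %in% foci$cell_id, "all_boxes_at_border", "no_foci"))
  res
}

#' Anchored two-channel quantification
#'
#' Boxes are defined once from the anchor channel's foci (e.g. CENP-B);
#' the median-focus signal of the anchor and of each listed signal channel
#' is then computed inside those same boxes, and each signal is reported as
#' a ratio to the anchor (per cell).
#'
#' @param anchor_channel Intensity matrix used to detect foci and define
#'   boxes.
#' @param signal_channels Named list of intensity matrices quantified inside
#'   the anchor-defined boxes.
#' @inheritParams quantify_foci
#' @return Long tibble: `cell_id`, `channel` (`"anchor"` or a signal
#'   channel name), `n_foci`, `background`, `signal_sum`, `ratio`
#'   (signal over anchor; 1 for the anchor itself). Cells with no anchor
#'   foci are skipped with a reason (attribute `"skipped"`).
#' @export
anchored_quantify <- function(anchor_channel, signal_channels, nucleus_labels,
                              threshold, min_area = 2, box_size = 10) {
  if (is.null(names(signal_channels)) || any(names(signal_channels) == "")) {
    abort("`signal_channels` must be a named list")
  }
  for (ch in signal_channels) {
    if (!all(dim(ch) == dim(anchor_channel))) abort("all channels must have the same shape")
  }
  foci <- detect_foci(anchor_channel, nucleus_labels, threshold, min_area)
  anchor_patches <- extract_patches(anchor_channel, foci, box_size)
  kept_foci <- dplyr::semi_join(foci, anchor_patches, by = c("cell_id", "focus_id"))

  quant_one <- function(channel, name) {
    extract_patches(channel, kept_foci, box_size) |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::group_map(function(g, key) {
        mf <- median_focus(g$patch)
        bg <- perimeter_background(mf)
        tibble::tibble(cell_id = key$cell_id, channel = name, n_foci = nrow(g),
                       background = bg, signal_sum = focus_signal(mf, bg))
      }) |>
      dplyr::bind_rows()
  }
  res <- dplyr::bind_rows(c(
    list(quant_one(anchor_channel, "anchor")),
    purrr::imap(signal_channels, quant_one)))
  if (!nrow(res)) {
    res <- tibble::tibble(cell_id = integer(), channel = character(),
                          n_foci = integer(), background = numeric(),
                          signal_sum = numeric())
  }
  anchor_sum <- res |>
    dplyr::filter(.data$channel == "anchor") |>
    dplyr::select("cell_id", anchor_sum = "signal_sum")
  res <- res |>
    dplyr::left_join(anchor_sum, by = "cell_id") |>
    dplyr::mutate(ratio = .data$signal_sum / .data$anchor_sum) |>
    dplyr::select(-"anchor_sum") |>
    dplyr::arrange(.data$cell_id, .data$channel != "anchor", .data$channel)
  all_cells <- sort(unique(as.integer(nucleus_labels[nucleus_labels > 0])))
  skipped <- setdiff(all_cells, res$cell_id)
  attr(res, "skipped") <- tibble::tibble(
    cell_id = skipped,
    reason = ifelse(skipped %in% foci$cell_id, "all_boxes_at_border", "no_anchor_foci"))
  res
}

#' Normalize per-cell values to a control condition
#'
#' Divides every value by the mean of the control condition, so the control
#' mean maps to exactly 1 (the convention for reporting treatment effects
#' relative to a negative control).
#'
#' @param data Data frame of per-cell values.
#' @param value,condition Columns (tidy-eval) holding the readout and the
#'   condition label.
#' @param control Control condition label.
#' @return `data` with an added `normalized` column.
#' @export
normalize_to_control <- function(data, value, condition, control) {
  v <- dplyr::pull(data, {{ value }})
  cond <- dplyr::pull(data, {{ condition }})
  if (!control %in% cond) abort(paste0("control condition `", control, "` not present"))
  m <- mean(v[cond == control])
  if (!is.finite(m) || m == 0) abort("control mean is zero or undefined; cannot normalize")
  dplyr::mutate(data, normalized = {{ value }} / m)
}
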