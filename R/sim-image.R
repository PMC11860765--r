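# Synthetic 2D fluorescence fields and colony plates with full ground truth.
# Nuclei are disks packed on a jittered grid; foci are isotropic Gaussian
# bumps at integer pixel positions (diffraction-limited puncta); noise is
# additive Gaussian clipped at zero.

# Pack n disk centers of radius `radius` (+ margin) into a width x height
# field on a jittered grid. Errors if the field cannot hold them.
pack_disks <- function(n, width, height, radius, margin, jitter_frac = 0.4) {
  cell <- 2 * (radius + margin)
  gx <- max(1L, floor(width / cell))
  gy <- max(1L, floor(height / cell))
  if (gx * gy < n) {
    abort(sprintf("cannot pack %d objects of radius %g into a %dx%d field",
                  n, radius, width, height),
          class = "censtab_packing_error")
  }
  sx <- width / gx; sy <- height / gy
  ord <- sample(gx * gy, n)
  gi <- (ord - 1L) %% gx
  gj <- (ord - 1L) %/% gx
  slack_x <- pmax(sx / 2 - radius - margin, 0)
  slack_y <- pmax(sy / 2 - radius - margin, 0)
  tibble::tibble(
    col = floor(gi * sx + sx / 2 + runif(n, -1, 1) * jitter_frac * slack_x + 0.5),
    row = floor(gj * sy + sy / 2 + runif(n, -1, 1) * jitter_frac * slack_y + 0.5)
  )
}

add_gaussian_bump <- function(img, row, col, amplitude, sigma) {
  r <- ceiling(4 * sigma)
  rows <- max(1, row - r):min(nrow(img), row + r)
  cols <- max(1, col - r):min(ncol(img), col + r)
  d2 <- outer((rows - row)^2, (cols - col)^2, "+")
  img[rows, cols] <- img[rows, cols] + amplitude * exp(-d2 / (2 * sigma^2))
  img
}

draw_count <- function(foci_per_cell, n) {
  if (length(foci_per_cell) == 1) rep(as.integer(foci_per_cell), n)
  else sample(seq(foci_per_cell[1], foci_per_cell[2]), n, replace = TRUE)
}

# Rejection-sample m focus positions inside a disk, pairwise separated by
# >= min_sep pixels, at integer pixel coordinates.
place_foci <- function(center_row, center_col, radius, m, min_sep) {
  rows <- integer(0); cols <- integer(0)
  tries <- 0L
  while (length(rows) < m) {
    tries <- tries + 1L
    if (tries > 2000L) {
      abort("could not place the requested foci inside a nucleus; reduce counts or separation",
            class = "censtab_packing_error")
    }
    a <- runif(1, 0, 2 * pi)
    d <- radius * sqrt(runif(1))
    r <- floor(center_row + d * sin(a) + 0.5)
    c <- floor(center_col + d * cos(a) + 0.5)
    if (length(rows) && min((rows - r)^2 + (cols - c)^2) < min_sep^2) next
    rows <- c(rows, r); cols <- c(cols, c)
  }
  tibble::tibble(row = rows, col = cols)
}

#' Simulate a 2D FISH/IF field with punctate foci
#'
#' Generates one field of disk-shaped nuclei on a flat background, each with
#' a controlled number of Gaussian foci of known amplitude, plus additive
#' Gaussian noise clipped at zero. An amplitude-scaling factor emulates
#' treatments (e.g. exonuclease digestion exposing more probe target) that
#' increase per-focus signal.
#'
#' @param width,height Field size in pixels.
#' @param n_cells Number of nuclei.
#' @param foci_per_cell Integer count, or length-2 range sampled uniformly
#'   per cell.
#' @param focus_amplitude Peak height of each focus above background (a.u.).
#' @param focus_sigma Gaussian SD of a focus, pixels.
#' @param background_level Flat background (a.u.).
#' @param noise_sd SD of additive Gaussian noise (a.u.).
#' @param nucleus_radius Nucleus radius, pixels.
#' @param min_focus_sep Minimum center-to-center focus separation, pixels.
#' @param seed Integer seed; identical spec + seed gives identical pixels.
#' @return List: `image` (matrix), `labels` (integer nucleus mask),
#'   `truth` (list with `nuclei` and `foci` tibbles; `foci$amplitude` is the
#'   true peak height of every focus).
#' @export
sim_exofish_field <- function(width = 512, height = 512, n_cells = 25,
                              foci_per_cell = 6, focus_amplitude = 800,
                              focus_sigma = 1.5, background_level = 100,
                              noise_sd = 15, nucleus_radius = 18,
                              min_focus_sep = 7, seed = 1) {
  if (width <= 0 || height <= 0) abort("field dimensions must be positive")
  if (focus_amplitude < 0 || noise_sd < 0) abort("amplitude and noise_sd must be >= 0")
  withr::with_seed(seed, {
    centers <- pack_disks(n_cells, width, height, nucleus_radius, margin = 3)
    labels <- matrix(0L, height, width)
    rr <- matrix(seq_len(height), height, width)
    cc <- matrix(seq_len(width), height, width, byrow = TRUE)
    for (k in seq_len(n_cells)) {
      inside <- (rr - centers$row[k])^2 + (cc - centers$col[k])^2 <= nucleus_radius^2
      labels[inside] <- k
    }
    img <- matrix(background_level, height, width)
    counts <- draw_count(foci_per_cell, n_cells)
    foci <- purrr::map_dfr(seq_len(n_cells), function(k) {
      if (counts[k] == 0) return(tibble::tibble())
      # keep foci away from the rim so detection boxes stay inside the nucleus
      pos <- place_foci(centers$row[k], centers$col[k],
                        max(nucleus_radius - 2 * focus_sigma - 2, 1),
                        counts[k], min_focus_sep)
      tibble::tibble(cell_id = k, focus_id = seq_len(counts[k]),
                     row = pos$row, col = pos$col, amplitude = focus_amplitude)
    })
    if (nrow(foci)) {
      for (i in seq_len(nrow(foci))) {
        img <- add_gaussian_bump(img, foci$row[i], foci$col[i],
                                 foci$amplitude[i], focus_sigma)
      }
    }
    if (noise_sd > 0) {
      img <- img + matrix(rnorm(height * width, sd = noise_sd), height, width)
      img <- pmax(img, 0)
    }
    list(image = img, labels = labels,
         truth = list(
           nuclei = tibble::tibble(cell_id = seq_len(n_cells),
                                   row = centers$row, col = centers$col,
                                   radius = nucleus_radius),
           foci = foci
         ))
  })
}

#' Simulate an anchored two-channel field
#'
#' Like [sim_exofish_field()] but emits one anchor channel (e.g. CENP-B) and
#' one or more signal channels (e.g. CENP-A) sharing the same focus
#' positions, with each signal channel's focus amplitude scaled by a known
#' factor. The fixture for anchored-box quantification.
#'
#' @inheritParams sim_exofish_field
#' @param signal_scales Named numeric vector: per-channel amplitude scale
#'   relative to the anchor (e.g. `c(cenpa = 0.5)`).
#' @return List: `channels` (named list of matrices, `anchor` first),
#'   `labels`, `truth` (as in [sim_exofish_field()], plus `signal_scales`).
#' @export
sim_anchored_field <- function(width = 512, height = 512, n_cells = 25,
                               foci_per_cell = 4, focus_amplitude = 800,
                               signal_scales = c(signal = 0.5),
                               focus_sigma = 1.5, background_level = 100,
                               noise_sd = 10, nucleus_radius = 18,
                               min_focus_sep = 9, seed = 1) {
  base <- sim_exofish_field(width, height, n_cells, foci_per_cell,
                            focus_amplitude, focus_sigma, background_level,
                            noise_sd, nucleus_radius, min_focus_sep, seed)
  foci <- base$truth$foci
  channels <- list(anchor = base$image)
  for (j in seq_along(signal_scales)) {
    img <- withr::with_seed(seed + 1000L * j, {
      im <- matrix(background_level, height, width)
      if (nrow(foci)) {
        for (i in seq_len(nrow(foci))) {
          im <- add_gaussian_bump(im, foci$row[i], foci$col[i],
                                  foci$amplitude[i] * signal_scales[[j]], focus_sigma)
        }
      }
      if (noise_sd > 0) im <- pmax(im + matrix(rnorm(height * width, sd = noise_sd), height, width), 0)
      im
    })
    channels[[names(signal_scales)[j]]] <- img
  }
  list(channels = channels, labels = base$labels,
       truth = c(base$truth, list(signal_scales = signal_scales)))
}

#' Simulate a colony plate
#'
#' Disk-shaped colonies (and optionally one 1-pixel-wide streak, a
#' low-circularity artifact) on a dark background, as an 8-bit-like image.
#'
#' @param n_disks Number of disk colonies.
#' @param disk_radius Radius in pixels (scalar or per-disk vector).
#' @param width,height Plate image size, pixels.
#' @param streak_length If non-`NULL`, adds one horizontal 1-px streak of
#'   this length.
#' @param background,foreground Intensity levels (0-255 scale).
#' @param seed Integer seed.
#' @return List: `image` (matrix), `truth` (tibble: `object_id`, `type`,
#'   `row`, `col`, `area`; streaks carry their analytic circularity
#'   `4*pi*A/P^2` with `P = 2*(L-1) + pi`).
#' @export
sim_colony_plate <- function(n_disks, disk_radius = 6, width = 600, height = 400,
                             streak_length = NULL, background = 20,
                             foreground = 200, seed = 1) {
  radius <- rep(disk_radius, length.out = max(n_disks, 1))
  withr::with_seed(seed, {
    img <- matrix(background, height, width)
    truth <- tibble::tibble()
    if (n_disks > 0) {
      centers <- pack_disks(n_disks, width, height, max(radius), margin = 4)
      rr <- matrix(seq_len(height), height, width)
      cc <- matrix(seq_len(width), height, width, byrow = TRUE)
      areas <- integer(n_disks)
      for (k in seq_len(n_disks)) {
        inside <- (rr - centers$row[k])^2 + (cc - centers$col[k])^2 <= radius[k]^2
        img[inside] <- foreground
        areas[k] <- sum(inside)
      }
      truth <- tibble::tibble(object_id = seq_len(n_disks), type = "disk",
                              row = centers$row, col = centers$col,
                              area = areas, circularity = NA_real_)
    }
    if (!is.null(streak_length)) {
      if (streak_length + 2 > width) abort("streak does not fit the plate",
                                           class = "censtab_packing_error")
      row_s <- if (n_disks > 0) {
        free <- setdiff(seq(3, height - 2), unlist(lapply(seq_len(n_disks), function(k)
          seq(max(1, truth$row[k] - radius[k] - 3), min(height, truth$row[k] + radius[k] + 3)))))
        if (!length(free)) abort("no free row for the streak", class = "censtab_packing_error")
        free[1]
      } else floor(height / 2)
      img[row_s, 2:(streak_length + 1)] <- foreground
      perim <- 2 * (streak_length - 1) + pi
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        object_id = nrow(truth) + 1L, type = "streak", row = row_s, col = 2L,
        area = streak_length, circularity = 4 * pi * streak_length / perim^2))
    }
    list(image = img, truth = truth)
  })
}
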