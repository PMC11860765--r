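# Low-level raster primitives shared by the 2D quantification and the 3D
# colocalization pipeline. All coordinates are 1-based (row, col[, slice]),
# origin at the top-left, matching R's array indexing.

neighbour_offsets_2d <- function(connectivity = 8) {
  if (connectivity == 8) {
    list(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
         dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  } else if (connectivity == 4) {
    list(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else {
    abort("`connectivity` must be 4 or 8")
  }
}

#' Label connected components of a binary image
#'
#' Flood-fill labeling of the foreground of a 2D binary mask. Components are
#' numbered 1, 2, ... in column-major order of their first pixel, the same
#' deterministic order on every call.
#'
#' @param mask Logical or 0/1 numeric matrix; non-zero entries are foreground.
#' @param connectivity Neighbourhood, 8 (default, the particle-analysis
#'   convention) or 4.
#' @return Integer matrix of the same shape; 0 is background.
#' @examples
#' m <- matrix(0, 5, 5); m[1:2, 1:2] <- 1; m[4:5, 4:5] <- 1
#' label_components(m)
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix")
  nr <- nrow(mask); nc <- ncol(mask)
  off <- neighbour_offsets_2d(connectivity)
  lab <- matrix(0L, nr, nc)
  fg <- mask > 0
  seeds <- which(fg)
  cur <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      c <- ((frontier - 1L) %/% nr) + 1L
      cr <- outer(r, off$dr, "+")
      cc <- outer(c, off$dc, "+")
      ok <- cr >= 1L & cr <= nr & cc >= 1L & cc <= nc
      ci <- unique((cc[ok] - 1L) * nr + cr[ok])
      ci <- ci[fg[ci] & lab[ci] == 0L]
      lab[ci] <- cur
      frontier <- ci
    }
  }
  lab
}

# 3D analogue over a logical array; 26- or 6-connectivity.
label_components_3d <- function(mask, connectivity = 26) {
  d <- dim(mask)
  if (length(d) != 3) abort("`mask` must be a 3D array")
  if (connectivity == 26) {
    g <- expand.grid(dr = -1:1, dc = -1:1, dz = -1:1)
    g <- g[!(g$dr == 0 & g$dc == 0 & g$dz == 0), ]
  } else if (connectivity == 6) {
    g <- data.frame(dr = c(-1, 1, 0, 0, 0, 0), dc = c(0, 0, -1, 1, 0, 0),
                    dz = c(0, 0, 0, 0, -1, 1))
  } else abort("`connectivity` must be 6 or 26")
  nr <- d[1]; nc <- d[2]; nz <- d[3]; nrc <- nr * nc
  lab <- array(0L, d)
  fg <- mask > 0
  seeds <- which(fg)
  cur <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      i0 <- frontier - 1L
      z <- i0 %/% nrc
      r <- i0 %% nr
      c <- (i0 %% nrc) %/% nr
      cr <- outer(r, as.integer(g$dr), "+")
      cc <- outer(c, as.integer(g$dc), "+")
      cz <- outer(z, as.integer(g$dz), "+")
      ok <- cr >= 0L & cr < nr & cc >= 0L & cc < nc & cz >= 0L & cz < nz
      ci <- unique(cz[ok] * nrc + cc[ok] * nr + cr[ok] + 1L)
      ci <- ci[fg[ci] & lab[ci] == 0L]
      lab[ci] <- cur
      frontier <- ci
    }
  }
  lab
}

#' Fill holes in a binary mask
#'
#' Background regions (4-connected) that do not touch the image border are
#' converted to foreground.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Logical matrix.
#' @export
fill_holes <- function(mask) {
  bg <- label_components(matrix(as.numeric(!(mask > 0)), nrow(mask)), connectivity = 4)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0]
  (mask > 0) | (bg > 0 & !(bg %in% border))
}

#' Otsu threshold on a 256-bin histogram
#'
#' Maximizes the between-class variance over the histogram of all supplied
#' intensities (the whole stack is pooled, not per slice). The threshold is
#' the upper edge of the selected bin; foreground is `x > threshold`.
#'
#' @param x Numeric vector, matrix or array of intensities.
#' @param n_bins Number of histogram bins (default 256).
#' @return Scalar threshold, with the Otsu effectiveness metric
#'   (between-class / total variance, in \[0, 1\]) attached as attribute
#'   `"effectiveness"`.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) abort("Otsu threshold is undefined for a constant image")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w <- cumsum(h)
  sx <- cumsum(h * mids)
  total <- w[n_bins]; totalx <- sx[n_bins]
  w1 <- w[-n_bins]; w2 <- total - w1
  m1 <- sx[-n_bins] / w1
  m2 <- (totalx - sx[-n_bins]) / w2
  bcv <- w1 / total * w2 / total * (m1 - m2)^2
  bcv[w1 == 0 | w2 == 0] <- -Inf
  k <- which.max(bcv)
  mu <- totalx / total
  vtot <- sum(h * (mids - mu)^2) / total
  thr <- breaks[k + 1]
  attr(thr, "effectiveness") <- if (vtot > 0) bcv[k] / vtot else 0
  thr
}

# Per-object area and centroid from a label matrix. Centroids are the mean
# pixel coordinates rounded half-up to the nearest pixel.
component_stats <- function(lab) {
  idx <- which(lab > 0)
  if (!length(idx)) {
    return(tibble::tibble(object_id = integer(), area = integer(),
                          row = integer(), col = integer()))
  }
  nr <- nrow(lab)
  id <- lab[idx]
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  tibble::tibble(
    object_id = sort(unique(id)),
    area = as.integer(tabulate(id)[sort(unique(id))]),
    row = as.integer(floor(tapply(r, id, mean) + 0.5)),
    col = as.integer(floor(tapply(c, id, mean) + 0.5))
  )
}

#' Perimeter of a single object by contour tracing
#'
#' Traces the outer boundary of the object (Moore neighbourhood, 8-connected)
#' through pixel centers and sums the step lengths: 1 for axial moves, sqrt(2)
#' for diagonal moves, plus a half-pixel convexity correction of pi so that a
#' large rasterized disk measures close to its true circumference (circularity
#' near 1). A single isolated pixel has perimeter pi.
#'
#' @param mask Logical or 0/1 matrix containing exactly one connected object.
#' @return Scalar perimeter estimate in pixel units.
#' @export
contour_perimeter <- function(mask) {
  fg <- mask > 0
  n_fg <- sum(fg)
  if (n_fg == 0) abort("`mask` contains no foreground")
  if (n_fg == 1) return(pi)
  nr <- nrow(fg); nc <- ncol(fg)
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && fg[r, c]
  # raster-scan (row-major) for the start pixel; its left neighbour is background
  start <- NULL
  for (r in seq_len(nr)) {
    cs <- which(fg[r, ])
    if (length(cs)) { start <- c(r, cs[1]); break }
  }
  # clockwise Moore neighbourhood, starting from "west"
  moves <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                 c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  cur <- start
  dir <- 1L # index into moves of the backtrack direction
  perim <- 0
  first_step <- NULL
  repeat {
    found <- FALSE
    for (k in 0:7) {
      j <- ((dir - 1L + k) %% 8L) + 1L
      cand <- cur + moves[j, ]
      if (at(cand[1], cand[2])) {
        step <- if (moves[j, 1] != 0 && moves[j, 2] != 0) sqrt(2) else 1
        perim <- perim + step
        # new backtrack: direction pointing back toward the previous pixel,
        # rotated one position clockwise past the last background neighbour
        dir <- ((j - 1L + 4L + 1L) %% 8L) + 1L
        prev <- cur
        cur <- cand
        if (is.null(first_step)) {
          first_step <- c(prev, cur)
        } else if (all(c(prev, cur) == first_step)) {
          return(perim - step + pi) # closed: final repeat of the first step
        }
        found <- TRUE
        break
      }
    }
    if (!found) return(pi) # isolated after masking; degenerate
    if (perim > 8 * (nr * nc)) abort("contour tracing failed to close")
  }
}

# Separable Gaussian smoothing of a 3D array; sigma in voxels per axis
# (scalar recycled). Edges are replicated.
gaussian_smooth_3d <- function(a, sigma) {
  sigma <- rep(sigma, length.out = 3)
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    n <- dim(a)[axis]
    out <- array(0, dim(a))
    for (j in seq(-r, r)) {
      idx <- pmin(pmax(seq_len(n) + j, 1L), n)
      sl <- switch(axis,
                   a[idx, , , drop = FALSE],
                   a[, idx, , drop = FALSE],
                   a[, , idx, drop = FALSE])
      out <- out + k[j + r + 1] * sl
    }
    a <- out
  }
  a
}

# Linear indices of 26-connected local maxima of a 3D array with value above
# `threshold`. Plateaus (ties) are collapsed to one representative voxel
# (smallest linear index) per connected plateau.
local_maxima_3d <- function(a, threshold) {
  d <- dim(a); nr <- d[1]; nc <- d[2]; nz <- d[3]
  is_max <- array(TRUE, d)
  for (dr in -1:1) for (dc in -1:1) for (dz in -1:1) {
    if (dr == 0 && dc == 0 && dz == 0) next
    shifted <- array(-Inf, d)
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc; zs <- seq_len(nz) - dz
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc; ok_z <- zs >= 1 & zs <= nz
    shifted[ok_r, ok_c, ok_z] <- a[rs[ok_r], cs[ok_c], zs[ok_z]]
    is_max <- is_max & (a >= shifted)
  }
  is_max <- is_max & (a > threshold)
  if (!any(is_max)) return(integer())
  plat <- label_components_3d(is_max, connectivity = 26)
  as.integer(tapply(which(plat > 0), plat[plat > 0], min))
}

# Multi-source 26-connected region growing. Every voxel with a >= threshold
# reachable from a seed is assigned to the seed that reaches it first
# (breadth-first, i.e. fewest steps); ties within a wavefront go to the
# lower-ranked seed. Returns an integer array of seed ranks (0 = unassigned).
region_grow_3d <- function(a, seeds, threshold) {
  d <- dim(a); nr <- d[1]; nc <- d[2]; nz <- d[3]; nrc <- nr * nc
  lab <- array(0L, d)
  ok <- a >= threshold
  seeds <- seeds[ok[seeds]]
  if (!length(seeds)) return(lab)
  lab[seeds] <- seq_along(seeds)
  g <- expand.grid(dr = -1:1, dc = -1:1, dz = -1:1)
  g <- g[!(g$dr == 0 & g$dc == 0 & g$dz == 0), ]
  frontier <- seeds
  while (length(frontier)) {
    i0 <- frontier - 1L
    z <- i0 %/% nrc
    r <- i0 %% nr
    c <- (i0 %% nrc) %/% nr
    cr <- outer(r, as.integer(g$dr), "+")
    cc <- outer(c, as.integer(g$dc), "+")
    cz <- outer(z, as.integer(g$dz), "+")
    src <- matrix(lab[frontier], nrow = length(frontier), ncol = nrow(g))
    keep <- cr >= 0L & cr < nr & cc >= 0L & cc < nc & cz >= 0L & cz < nz
    ci <- cz[keep] * nrc + cc[keep] * nr + cr[keep] + 1L
    sl <- src[keep]
    sel <- ok[ci] & lab[ci] == 0L
    ci <- ci[sel]; sl <- sl[sel]
    if (!length(ci)) break
    o <- order(ci, sl)
    ci <- ci[o]; sl <- sl[o]
    first <- !duplicated(ci)
    ci <- ci[first]; sl <- sl[first]
    lab[ci] <- sl
    frontier <- ci
  }
  lab
}
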