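# TIFF import/export for fields and stacks. Intensities are stored as
# 16-bit multi-page TIFF (pages = Z slices, ZYX order) with a YAML sidecar
# recording the axis order, voxel size and intensity scale.

#' Write an image or Z-stack as 16-bit TIFF with a YAML sidecar
#'
#' @param x Matrix (2D field) or 3D array (Z-stack, slices last).
#' @param path Output `.tif` path; the sidecar is written to
#'   `paste0(path, ".yaml")`.
#' @param voxel_size Voxel size `c(x, y, z)` in um, recorded in the sidecar.
#' @param max_value Intensity mapped to the top of the 16-bit range.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(x, path, voxel_size = c(0.1, 0.1, 0.71),
                             max_value = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the `tiff` package is required for TIFF export")
  }
  pages <- if (is.matrix(x)) list(x) else
    lapply(seq_len(dim(x)[3]), function(z) x[, , z])
  pages <- lapply(pages, function(p) pmin(pmax(p / max_value, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(axes = "ZYX", voxel_size_um = as.numeric(voxel_size),
                        max_value = max_value, n_slices = length(pages)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read an image written by [write_image_tiff()]
#'
#' @param path `.tif` path with an adjacent `.yaml` sidecar.
#' @return Matrix or 3D array in original intensity units, with the sidecar
#'   list attached as attribute `"metadata"`.
#' @export
read_image_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("the `tiff` package is required for TIFF import")
  }
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) p * meta$max_value)
  out <- if (length(pages) == 1) pages[[1]] else
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  attr(out, "metadata") <- meta
  out
}
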