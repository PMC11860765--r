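# Colony counting with a circularity filter, the automated particle-analysis
# readout of clonogenic survival plates.

#' Count colonies with a circularity filter
#'
#' Objects are 8-connected components above an intensity threshold on an
#' 8-bit-like image. Each object's circularity is `4 * pi * area /
#' perimeter^2` with the perimeter from [contour_perimeter()]; objects with
#' circularity inside `circularity` (bounds inclusive) are counted as
#' colonies, which excludes thin streaks and scratches (circularity below
#' 0.01) while keeping round colonies (close to 1).
#'
#' @param image Single-channel intensity matrix.
#' @param threshold Binarization threshold (object if `image > threshold`).
#' @param circularity Length-2 inclusive bounds, default `c(0.01, 1.00)`.
#' @return An object of class `colony_counts`: list with `count` (colonies
#'   kept) and `objects`, a tibble of every detected object (`object_id`,
#'   `row`, `col`, `area`, `perimeter`, `circularity`, `kept`). [tidy()]
#'   returns the object table.
#' @export
count_colonies <- function(image, threshold, circularity = c(0.01, 1.00)) {
  if (!is.matrix(image)) abort("`image` must be a single-channel matrix")
  if (length(circularity) != 2 || circularity[1] > circularity[2]) {
    abort("`circularity` must be increasing bounds of length 2")
  }
  lab <- label_components(image > threshold, connectivity = 8)
  st <- component_stats(lab)
  if (nrow(st)) {
    st$perimeter <- vapply(st$object_id, function(id) contour_perimeter(lab == id),
                           numeric(1))
    st$circularity <- 4 * pi * st$area / st$perimeter^2
    st$kept <- st$circularity >= circularity[1] & st$circularity <= circularity[2]
  } else {
    st$perimeter <- numeric(0); st$circularity <- numeric(0); st$kept <- logical(0)
  }
  structure(list(count = sum(st$kept), objects = st, circularity = circularity,
                 threshold = threshold),
            class = "colony_counts")
}

#' @export
print.colony_counts <- function(x, ...) {
  cat(sprintf("%d colonies (of %d objects above threshold %g; circularity in [%g, %g])\n",
              x$count, nrow(x$objects), x$threshold,
              x$circularity[1], x$circularity[2]))
  invisible(x)
}

#' @export
tidy.colony_counts <- function(x, ...) x$objects
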