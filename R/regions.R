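#' Partition a tumour mask into core, front-in and front-out bands
#'
#' The tumour core is the main tumour mass eroded by the band width; the
#' invasive front is a band of total width `2 * band_um` straddling the
#' tumour border: `band_um` inside (front-in) and `band_um` outside
#' (front-out).  Masks are binary matrices indexed `[ix, iy]` where
#' `ix = floor(x_um / pixel_size) + 1` (x maps to the first dimension,
#' matching EBImage).  Holes in the tumour mask are filled before
#' partitioning, so "tumour" means the main tumour mass.  Erosion and
#' dilation by a Euclidean disc are computed with distance transforms.
#'
#' @param tumour_mask binary matrix (0/1 or logical).
#' @param pixel_size pixel size in um/pixel, > 0.
#' @param band_um band width in um (default 500).
#' @return object of class `region_partition`: list with logical masks
#'   `core`, `frontin`, `frontout`, numeric `areas` (mm^2, named), the
#'   filled `tumour` mask, `pixel_size`, `band_um`, and `warnings`
#'   (character; notes an empty core when the band exhausts the mask).
#' @export
partition_regions <- function(tumour_mask, pixel_size, band_um = 500) {
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0,
            is.numeric(band_um) || is.integer(band_um), band_um > 0)
  m <- .as_binary_mask(tumour_mask)
  warnings <- character(0)
  if (!any(m)) {
    empty <- matrix(FALSE, nrow(m), ncol(m))
    return(.region_partition(empty, empty, empty, m, pixel_size, band_um,
                             "empty tumour mask"))
  }
  filled <- .as_binary_mask(EBImage::fillHull(m * 1L))
  band_px <- band_um / pixel_size
  # distance (in px) from each tumour pixel to the nearest background pixel
  d_in <- EBImage::distmap(filled * 1L)
  core <- filled & (as.matrix(d_in) > band_px)
  frontin <- filled & !core
  d_out <- EBImage::distmap((1L - filled * 1L))
  frontout <- !filled & (as.matrix(d_out) <= band_px)
  if (!any(core)) warnings <- c(warnings, "band width exhausts tumour mask: core is empty")
  .region_partition(core, frontin, frontout, filled, pixel_size, band_um, warnings)
}

.region_partition <- function(core, frontin, frontout, tumour, pixel_size, band_um, warnings) {
  px_mm2 <- (pixel_size^2) / 1e6
  structure(list(
    core = core, frontin = frontin, frontout = frontout, tumour = tumour,
    areas = c(core = sum(core) * px_mm2,
              frontin = sum(frontin) * px_mm2,
              frontout = sum(frontout) * px_mm2),
    pixel_size = pixel_size, band_um = band_um, warnings = warnings
  ), class = "region_partition")
}

#' Assign cells to tumour regions
#'
#' Labels each cell centre by membership in the disjoint core /
#' front-in / front-out masks of a [partition_regions()] result; cells
#' beyond the front-out band (or outside the raster) are `"outside"`.
#'
#' @param cells data frame with `x_um`, `y_um` columns.
#' @param partition a `region_partition`.
#' @return character vector of labels, one per cell, in
#'   `c("core", "frontin", "frontout", "outside")`.
#' @export
assign_regions <- function(cells, partition) {
  stopifnot(inherits(partition, "region_partition"))
  n <- nrow(cells)
  if (n == 0L) return(character(0))
  ps <- partition$pixel_size
  ix <- floor(cells$x_um / ps) + 1L
  iy <- floor(cells$y_um / ps) + 1L
  dims <- dim(partition$core)
  inside <- ix >= 1L & iy >= 1L & ix <= dims[1] & iy <= dims[2]
  lab <- rep("outside", n)
  idx <- cbind(ix[inside], iy[inside])
  sub <- rep("outside", sum(inside))
  sub[partition$core[idx]] <- "core"
  sub[partition$frontin[idx]] <- "frontin"
  sub[partition$frontout[idx]] <- "frontout"
  lab[inside] <- sub
  lab
}

.as_binary_mask <- function(m) {
  if (inherits(m, "Image")) m <- EBImage::imageData(m)
  if (!is.matrix(m)) m <- as.matrix(m)
  if (is.logical(m)) return(m)
  m > 0.5
}
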