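#' Min-max normalise an immunofluorescence channel
#'
#' Rescales a raster to `[0, 1]` by the per-slide minimum and maximum.
#' A constant raster maps to all zeros (no signal dynamic range means no
#' positive calls, which is the conservative degenerate behaviour).
#'
#' @param raster numeric matrix.
#' @return numeric matrix in `[0, 1]`.
#' @export
normalize_channel <- function(raster) {
  if (length(raster) == 0L) stop("empty raster")
  if (any(!is.finite(raster))) stop("non-finite pixels in raster")
  rng <- range(raster)
  if (rng[1] == rng[2]) return(array(0, dim = dim(raster)))
  (raster - rng[1]) / (rng[2] - rng[1])
}

# pixel offsets of a circular neighbourhood of given radius (px)
.disc_offsets <- function(radius_px) {
  d <- seq(-radius_px, radius_px)
  g <- expand.grid(dx = d, dy = d)
  g[g$dx^2 + g$dy^2 <= radius_px^2, , drop = FALSE]
}

#' Classify cells as marker-positive or -negative
#'
#' For each cell, the mean normalised intensity over a circular
#' neighbourhood of the nucleus centre (radius 11 px by default, clipped
#' at raster edges) is computed for every marker channel; the cell is
#' positive for a marker iff that mean is at or above the threshold
#' (default 32/256 = 0.125; the tie at the threshold counts as
#' positive).
#'
#' @param cell_centres data frame with `x_px`, `y_px` (1-based pixel
#'   coordinates) or `x_um`, `y_um` plus `pixel_size`.
#' @param channels named list of normalised channel matrices (see
#'   [normalize_channel()]); names become flag columns.
#' @param radius_px neighbourhood radius in pixels.
#' @param threshold positivity threshold on mean normalised intensity.
#' @param pixel_size um/px, used only when centres are given in um.
#' @return list with `flags` (logical data frame, one column per
#'   channel; `NA` rows for skipped cells) and `errors` (data frame of
#'   cell index + message for centres outside the raster).
#' @export
classify_markers <- function(cell_centres, channels, radius_px = 11,
                             threshold = 0.125, pixel_size = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  dims <- dim(channels[[1]])
  for (ch in channels) {
    stopifnot(identical(dim(ch), dims))
    if (any(ch < -1e-9) || any(ch > 1 + 1e-9)) stop("channels must be normalised to [0,1]")
  }
  if (!is.null(cell_centres$x_px)) {
    cx <- round(cell_centres$x_px); cy <- round(cell_centres$y_px)
  } else {
    stopifnot(!is.null(pixel_size))
    cx <- floor(cell_centres$x_um / pixel_size) + 1L
    cy <- floor(cell_centres$y_um / pixel_size) + 1L
  }
  n <- length(cx)
  off <- .disc_offsets(radius_px)
  flags <- as.data.frame(matrix(NA, n, length(channels)))
  names(flags) <- names(channels)
  errors <- list()
  for (i in seq_len(n)) {
    if (is.na(cx[i]) || cx[i] < 1 || cy[i] < 1 || cx[i] > dims[1] || cy[i] > dims[2]) {
      errors[[length(errors) + 1L]] <- data.frame(cell = i, message = "centre outside raster")
      next
    }
    ix <- cx[i] + off$dx; iy <- cy[i] + off$dy
    keep <- ix >= 1L & iy >= 1L & ix <= dims[1] & iy <= dims[2]
    idx <- cbind(ix[keep], iy[keep])
    for (ch in names(channels))
      flags[[ch]][i] <- mean(channels[[ch]][idx]) >= threshold
  }
  list(flags = flags,
       errors = if (length(errors)) do.call(rbind, errors)
                else data.frame(cell = integer(0), message = character(0)))
}

#' Assign phenotype classes from marker flags
#'
#' Maps the six marker flags plus tumour-bud membership to the seven
#' phenotype populations used for immune-contexture features.  The
#' populations overlap by design (an M2 macrophage is also a total
#' macrophage); membership is returned as one logical column per
#' population.  Epithelial (PanCK+) cells never count as immune cells;
#' PanCK+ cells outside buds are tumour bulk and contribute only to
#' region geometry.  PD-L1 co-expression state is attached to every
#' cell.
#'
#' @param flags data frame with logical columns `CD3`, `CD8`, `CD68`,
#'   `CD163`, `PDL1`, `PanCK`.
#' @param bud_membership logical vector: cell lies inside a tumour-bud
#'   epithelium object.
#' @return data frame with membership columns `TB`, `M1`, `M2`,
#'   `total_macrophage`, `general_T`, `cytotoxic_T`, `PDL1_cell`,
#'   `epithelial`, plus `pdl1_state` ("pos"/"neg") and a single
#'   most-specific `label` ("other" when no population applies).
#' @export
assign_phenotypes <- function(flags, bud_membership = rep(FALSE, nrow(flags))) {
  need <- c("CD3", "CD8", "CD68", "CD163", "PDL1", "PanCK")
  stopifnot(all(need %in% names(flags)), length(bud_membership) == nrow(flags))
  f <- lapply(flags[need], function(v) !is.na(v) & v)
  bud <- !is.na(bud_membership) & bud_membership
  out <- data.frame(
    TB = bud,
    M1 = f$CD68 & !f$CD163 & !f$PanCK,
    M2 = f$CD163 & !f$PanCK,
    total_macrophage = (f$CD68 | f$CD163) & !f$PanCK,
    general_T = f$CD3 & !f$PanCK,
    cytotoxic_T = f$CD8 & !f$PanCK,
    PDL1_cell = f$PDL1,
    epithelial = f$PanCK | bud,
    pdl1_state = ifelse(f$PDL1, "pos", "neg")
  )
  lab <- rep("other", nrow(out))
  lab[out$PDL1_cell] <- "PDL1_cell"
  lab[out$M2] <- "M2"
  lab[out$M1] <- "M1"
  lab[out$general_T] <- "general_T"
  lab[out$cytotoxic_T] <- "cytotoxic_T"
  lab[f$PanCK & !bud] <- "tumour_nonbud"
  lab[out$TB] <- "TB"
  out$label <- lab
  out
}

#' Identify tumour buds among epithelium objects
#'
#' Extracts 8-connected components of the epithelium mask, counts cell
#' nuclei whose centres fall inside each component, and flags a
#' component as a tumour bud iff it contains one to four nuclei.
#'
#' @param epithelium_mask binary matrix (same convention as
#'   [partition_regions()]).
#' @param cell_centres data frame with `x_um`, `y_um`.
#' @param pixel_size um/px of the mask.
#' @return list with `objects` (data frame: `object_id`,
#'   `nuclei_count`, `is_bud`, `area_px`, `centroid_x_um`,
#'   `centroid_y_um`), `cell_object` (integer component id per cell, 0
#'   when outside every object) and `cell_in_bud` (logical per cell).
#' @export
identify_tumour_buds <- function(epithelium_mask, cell_centres, pixel_size) {
  m <- .as_binary_mask(epithelium_mask)
  n_cells <- if (is.null(cell_centres)) 0L else nrow(cell_centres)
  if (!any(m)) {
    return(list(objects = data.frame(object_id = integer(0), nuclei_count = integer(0),
                                     is_bud = logical(0), area_px = integer(0),
                                     centroid_x_um = numeric(0), centroid_y_um = numeric(0)),
                cell_object = integer(n_cells), cell_in_bud = rep(FALSE, n_cells)))
  }
  lab <- .label_components8(matrix(as.integer(m), nrow(m), ncol(m)))
  n_obj <- max(lab)
  cell_comp <- integer(n_cells)
  if (n_cells > 0L) {
    ix <- floor(cell_centres$x_um / pixel_size) + 1L
    iy <- floor(cell_centres$y_um / pixel_size) + 1L
    inside <- ix >= 1L & iy >= 1L & ix <= nrow(lab) & iy <= ncol(lab)
    cell_comp[inside] <- lab[cbind(ix[inside], iy[inside])]
  }
  counts <- tabulate(cell_comp[cell_comp > 0L], nbins = n_obj)
  fg <- which(lab > 0L, arr.ind = TRUE)
  comp <- lab[fg]
  area <- tabulate(comp, nbins = n_obj)
  cx <- (vapply(split(fg[, 1], comp), mean, numeric(1)) - 0.5) * pixel_size
  cy <- (vapply(split(fg[, 2], comp), mean, numeric(1)) - 0.5) * pixel_size
  objects <- data.frame(object_id = seq_len(n_obj), nuclei_count = counts,
                        is_bud = counts >= 1L & counts <= 4L, area_px = area,
                        centroid_x_um = as.numeric(cx), centroid_y_um = as.numeric(cy))
  bud_ids <- objects$object_id[objects$is_bud]
  list(objects = objects, cell_object = cell_comp,
       cell_in_bud = cell_comp %in% bud_ids)
}
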