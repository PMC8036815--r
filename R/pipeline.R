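#' Quantify the full 201-feature vector for one synthetic patient
#'
#' Runs the measurement pipeline exactly as it would run on real slide
#' data: materialise masks, partition the slide into core / front-in /
#' front-out, identify tumour buds among epithelium objects, assign
#' phenotypes from the marker flags and bud membership, then assemble
#' the image, spatial and clinical feature blocks.
#'
#' @param patient an element of `generate_cohort()$patients`.
#' @param config the matching `cohort_config`.
#' @return named numeric vector of length 201.
#' @export
patient_features <- function(patient, config) {
  masks <- patient_masks(patient, config)
  part <- partition_regions(masks$tumour, masks$pixel_size,
                            band_um = config$region_band)
  cells <- patient$cells
  buds <- identify_tumour_buds(masks$epithelium, cells, masks$pixel_size)
  pheno <- assign_phenotypes(cells, bud_membership = buds$cell_in_bud)
  cells <- cbind(cells[setdiff(names(cells), names(pheno))], pheno)
  cells$region <- assign_regions(cells, part)

  objs <- buds$objects[buds$objects$is_bud, , drop = FALSE]
  if (nrow(objs)) {
    objs$region <- assign_regions(
      data.frame(x_um = objs$centroid_x_um, y_um = objs$centroid_y_um), part)
    objs$pdl1_state <- vapply(objs$object_id, function(oid) {
      memb <- buds$cell_object == oid
      if (any(memb & cells$PDL1)) "pos" else "neg"
    }, character(1))
  } else {
    objs$region <- character(0)
    objs$pdl1_state <- character(0)
  }

  c(image_features(cells, part, objs),
    spatial_features(cells, part, objs, radii = feature_schema()$radii),
    clinical_features(patient$clinical))
}

#' Feature matrix for a whole cohort
#'
#' @param cohort an `ic_cohort`.
#' @return data frame with `patient_id` plus the 201 schema columns.
#' @export
cohort_features <- function(cohort) {
  stopifnot(inherits(cohort, "ic_cohort"))
  rows <- lapply(cohort$patients, patient_features, config = cohort$config)
  out <- as.data.frame(do.call(rbind, rows))
  data.frame(patient_id = vapply(cohort$patients, `[[`, character(1), "patient_id"),
             out, check.names = FALSE)
}

#' Write a synthetic cohort to disk
#'
#' External layout: one `cells_<id>.csv` per patient, a cohort
#' `clinical.csv` (with survival columns), and binary tumour /
#' epithelium masks as TIFF.
#'
#' @param cohort an `ic_cohort`.
#' @param dir output directory (created if needed).
#' @param masks write mask TIFFs as well (default FALSE; they are
#'   cheap to re-materialise with [patient_masks()]).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, masks = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  for (p in cohort$patients) {
    cells <- cbind(patient_id = p$patient_id, p$cells)
    utils::write.csv(cells, file.path(dir, paste0("cells_", p$patient_id, ".csv")),
                     row.names = FALSE)
    if (masks) {
      mk <- patient_masks(p, cohort$config)
      EBImage::writeImage(EBImage::Image(mk$tumour * 1),
                          file.path(dir, paste0("mask_tumour_", p$patient_id, ".tiff")))
      EBImage::writeImage(EBImage::Image(mk$epithelium * 1),
                          file.path(dir, paste0("mask_epithelium_", p$patient_id, ".tiff")))
    }
  }
  invisible(dir)
}
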