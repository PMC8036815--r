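#' Feature schema: the named 201-feature space
#'
#' The per-patient feature vector has three blocks.  Image block (126):
#' 21 populations x 2 metrics (count, density per mm^2) x 3 regions
#' (core, frontin, frontout); the populations are the six cell classes
#' (TB, M1, M2, total_macrophage, general_T, cytotoxic_T) crossed with
#' PD-L1 co-expression state (pos, neg, any), plus PD-L1+ cells overall,
#' PD-L1+ epithelial and PD-L1+ non-epithelial.  Spatial block (60): the
#' cross-type L function at 6 radii for 10 population pairs -- immune
#' populations and PD-L1 around tumour buds, and PD-L1 around each
#' immune population.  Clinical block (15): age plus one-hot sex, TNM
#' stage, T, N and M.  The exact composition within the printed block
#' totals is this package's documented reconstruction.
#'
#' @param radii spatial radii (um).
#' @return list with character vectors `image`, `spatial`, `clinical`,
#'   `all`, the `pairs` data frame (source, target) and `radii`.
#' @export
feature_schema <- function(radii = c(20, 50, 100, 150, 200, 250)) {
  classes <- c("TB", "M1", "M2", "total_macrophage", "general_T", "cytotoxic_T")
  pops <- c(as.vector(outer(classes, c("pos", "neg", "any"), paste, sep = "_")),
            "PDL1cell_any", "PDL1cell_epi", "PDL1cell_nonepi")
  regions <- c("core", "frontin", "frontout")
  image <- as.vector(outer(pops, as.vector(outer(regions, c("count", "density"),
                                                 paste, sep = "_")), paste, sep = "_"))
  pairs <- data.frame(
    source = c(rep("TB", 6), "CD3", "CD8", "CD68", "CD163"),
    target = c("CD3", "CD8", "CD68", "CD163", "PDL1epi", "PDL1nonepi",
               rep("PDL1", 4)))
  spatial <- as.vector(t(outer(paste0("L_", pairs$source, "_", pairs$target),
                               paste0("_r", radii), paste0)))
  clinical <- c("age", "sex_male", "sex_female",
                "stage_II", "stage_IIIA", "stage_IIIB", "stage_IV",
                "T2", "T3", "T4", "N0", "N1", "N2", "M0", "M1stat")
  list(image = image, spatial = spatial, clinical = clinical,
       all = c(image, spatial, clinical), pairs = pairs, radii = radii)
}

# membership vector of an image-block population within phenotyped cells
.pop_members <- function(pop_state, cells) {
  if (startsWith(pop_state, "PDL1cell_")) {
    pop <- "PDL1cell"
    state <- sub("^PDL1cell_", "", pop_state)
  } else {
    pop <- sub("_(pos|neg|any)$", "", pop_state)
    state <- sub("^.*_", "", pop_state)
  }
  base <- switch(pop,
    TB = cells$TB, M1 = cells$M1, M2 = cells$M2,
    total_macrophage = cells$total_macrophage,
    general_T = cells$general_T, cytotoxic_T = cells$cytotoxic_T,
    PDL1cell = cells$PDL1_cell,
    stop("unknown population: ", pop))
  if (pop == "PDL1cell") {
    switch(state, any = base,
           epi = base & cells$epithelial,
           nonepi = base & !cells$epithelial)
  } else {
    switch(state, any = base,
           pos = base & cells$pdl1_state == "pos",
           neg = base & cells$pdl1_state == "neg")
  }
}

#' Image features: counts and densities per region
#'
#' Counts each of the 21 populations within each region and divides by
#' the region area (mm^2) for densities.  Tumour buds are counted as
#' objects (via `bud_objects`), all other populations as cells.  A
#' zero-area region yields count 0 and density 0.
#'
#' @param cells phenotyped cell data frame (output of
#'   [assign_phenotypes()] columns plus `region`); bud cells should
#'   carry `TB = FALSE` here since buds enter as objects.
#' @param partition a `region_partition` (for areas).
#' @param bud_objects data frame of tumour-bud objects with `region` and
#'   `pdl1_state` columns (possibly 0 rows).
#' @return named numeric vector of length 126.
#' @export
image_features <- function(cells, partition, bud_objects = NULL) {
  schema <- feature_schema()
  areas <- partition$areas
  out <- numeric(length(schema$image))
  names(out) <- schema$image
  if (is.null(bud_objects)) bud_objects <- data.frame(region = character(0),
                                                      pdl1_state = character(0))
  for (region in c("core", "frontin", "frontout")) {
    cr <- cells[!is.na(cells$region) & cells$region == region, , drop = FALSE]
    br <- bud_objects[bud_objects$region == region, , drop = FALSE]
    area <- unname(areas[region])
    for (pop in c(as.vector(outer(c("TB", "M1", "M2", "total_macrophage",
                                    "general_T", "cytotoxic_T"),
                                  c("pos", "neg", "any"), paste, sep = "_")),
                  "PDL1cell_any", "PDL1cell_epi", "PDL1cell_nonepi")) {
      if (startsWith(pop, "TB_")) {
        state <- sub("^TB_", "", pop)
        cnt <- if (state == "any") nrow(br) else sum(br$pdl1_state == state)
      } else {
        cnt <- if (nrow(cr)) sum(.pop_members(pop, cr)) else 0L
      }
      out[paste0(pop, "_", region, "_count")] <- cnt
      out[paste0(pop, "_", region, "_density")] <- if (area > 0) cnt / area else 0
    }
  }
  out
}

# point sets for spatial pairs, restricted to the analysed window
.spatial_population <- function(name, cells, bud_objects) {
  inw <- !is.na(cells$region) & cells$region != "outside"
  pick <- function(sel) data.frame(x = cells$x_um[sel & inw], y = cells$y_um[sel & inw])
  switch(name,
    TB = data.frame(x = bud_objects$centroid_x_um[bud_objects$region != "outside"],
                    y = bud_objects$centroid_y_um[bud_objects$region != "outside"]),
    CD3 = pick(cells$CD3 & !cells$PanCK),
    CD8 = pick(cells$CD8 & !cells$PanCK),
    CD68 = pick(cells$CD68 & !cells$PanCK),
    CD163 = pick(cells$CD163 & !cells$PanCK),
    PDL1 = pick(cells$PDL1),
    PDL1epi = pick(cells$PDL1 & cells$epithelial),
    PDL1nonepi = pick(cells$PDL1 & !cells$epithelial),
    stop("unknown spatial population: ", name))
}

#' Spatial features: cross-type L values for the 10 population pairs
#'
#' Evaluates [l_curve()] for each (source, target) pair at the schema
#' radii over the analysed window (tumour mass plus front-out band;
#' area = sum of the three region areas).  Pairs with an empty source or
#' target population are imputed to the CSR-neutral value `L(r) = r`,
#' so missing spatial structure is prognostically uninformative.
#'
#' @param cells phenotyped cell data frame with raw marker flag columns,
#'   `epithelial` and `region`.
#' @param partition a `region_partition`.
#' @param bud_objects tumour-bud objects (see [image_features()]).
#' @param radii radii in um.
#' @return named numeric vector of length 60.
#' @export
spatial_features <- function(cells, partition, bud_objects,
                             radii = c(20, 50, 100, 150, 200, 250)) {
  schema <- feature_schema(radii)
  A_um2 <- sum(partition$areas) * 1e6
  out <- numeric(length(schema$spatial))
  names(out) <- schema$spatial
  for (k in seq_len(nrow(schema$pairs))) {
    src <- schema$pairs$source[k]; tgt <- schema$pairs$target[k]
    px <- .spatial_population(src, cells, bud_objects)
    py <- .spatial_population(tgt, cells, bud_objects)
    nm <- paste0("L_", src, "_", tgt, "_r", radii)
    if (nrow(px) == 0L || nrow(py) == 0L || A_um2 <= 0) {
      out[nm] <- radii
    } else {
      lc <- l_curve(px, py, A_um2, radii)
      out[nm] <- lc$L
    }
  }
  out
}

#' Clinical features: age and one-hot staging
#'
#' @param record one-row data frame or list with `age` (years), `sex`
#'   ("male"/"female"), `T_stage` in T2..T4, `N_stage` in N0..N2,
#'   `M_stage` in M0/M1, `stage` in II/IIIA/IIIB/IV.
#' @return named numeric vector of length 15.
#' @export
clinical_features <- function(record) {
  need <- c("age", "sex", "T_stage", "N_stage", "M_stage", "stage")
  miss <- setdiff(need, names(record))
  if (length(miss) || any(vapply(record[need], function(v) is.null(v) || is.na(v), logical(1))))
    stop("incomplete clinical record: ", paste(miss, collapse = ", "))
  onehot <- function(value, levels, prefix = "") {
    if (!value %in% levels) stop("unknown level '", value, "'")
    stats::setNames(as.numeric(levels == value), paste0(prefix, levels))
  }
  c(age = as.numeric(record$age),
    onehot(record$sex, c("male", "female"), "sex_"),
    onehot(record$stage, c("II", "IIIA", "IIIB", "IV"), "stage_"),
    onehot(record$T_stage, c("T2", "T3", "T4")),
    onehot(record$N_stage, c("N0", "N1", "N2")),
    stats::setNames(onehot(record$M_stage, c("M0", "M1")), c("M0", "M1stat")))
}

#' Restrict a feature matrix to one of the seven feature sets
#'
#' The sets are the single blocks and their unions: image (126),
#' spatial (60), clinical (15), image and spatial (186), image and
#' clinical (141), spatial and clinical (75), image, spatial, and
#' clinical (201).
#'
#' @param features data frame or matrix with schema-named columns (extra
#'   columns such as `patient_id` are retained).
#' @param set_name one of the seven set names above.
#' @return `features` restricted to the requested block columns.
#' @export
feature_subset <- function(features, set_name) {
  schema <- feature_schema()
  blocks <- list(
    "image" = schema$image,
    "spatial" = schema$spatial,
    "clinical" = schema$clinical,
    "image and spatial" = c(schema$image, schema$spatial),
    "image and clinical" = c(schema$image, schema$clinical),
    "spatial and clinical" = c(schema$spatial, schema$clinical),
    "image, spatial, and clinical" = schema$all)
  if (!set_name %in% names(blocks))
    stop("unknown feature set '", set_name, "'")
  keep <- blocks[[set_name]]
  missing <- setdiff(keep, colnames(features))
  if (length(missing)) stop("features lack columns: ", paste(utils::head(missing), collapse = ", "))
  extra <- intersect(c("patient_id"), colnames(features))
  features[, c(extra, keep), drop = FALSE]
}
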