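fake_partition <- function(areas = c(core = 2, frontin = 2, frontout = 1)) {
  structure(list(core = matrix(TRUE, 1, 1), frontin = matrix(FALSE, 1, 1),
                 frontout = matrix(FALSE, 1, 1), tumour = matrix(TRUE, 1, 1),
                 areas = areas, pixel_size = 1, band_um = 500,
                 warnings = character(0)),
            class = "region_partition")
}

empty_cells <- function() {
  data.frame(x_um = numeric(0), y_um = numeric(0),
             CD3 = logical(0), CD8 = logical(0), CD68 = logical(0),
             CD163 = logical(0), PDL1 = logical(0), PanCK = logical(0),
             TB = logical(0), M1 = logical(0), M2 = logical(0),
             total_macrophage = logical(0), general_T = logical(0),
             cytotoxic_T = logical(0), PDL1_cell = logical(0),
             epithelial = logical(0), pdl1_state = character(0),
             region = character(0))
}

test_that("the schema defines exactly 126 + 60 + 15 uniquely named features", {
  sc <- feature_schema()
  expect_length(sc$image, 126)
  expect_length(sc$spatial, 60)
  expect_length(sc$clinical, 15)
  expect_length(sc$all, 201)
  expect_false(any(duplicated(sc$all)))
  expect_equal(nrow(sc$pairs), 10)
})

test_that("feature subsets have the declared block sizes", {
  sc <- feature_schema()
  fm <- as.data.frame(matrix(0, 2, 201, dimnames = list(NULL, sc$all)),
                      check.names = FALSE)
  fm <- cbind(patient_id = c("a", "b"), fm)
  sizes <- c("image" = 126, "spatial" = 60, "clinical" = 15,
             "image and spatial" = 186, "image and clinical" = 141,
             "spatial and clinical" = 75, "image, spatial, and clinical" = 201)
  for (nm in names(sizes))
    expect_equal(ncol(feature_subset(fm, nm)) - 1L, unname(sizes[nm]))
  expect_error(feature_subset(fm, "everything"), "unknown feature set")
})

test_that("image features do the count/density arithmetic", {
  part <- fake_partition()
  buds <- data.frame(region = rep("frontin", 10), pdl1_state = rep("neg", 10))
  fv <- image_features(empty_cells(), part, buds)
  expect_length(fv, 126)
  expect_equal(unname(fv["TB_any_frontin_count"]), 10)
  expect_equal(unname(fv["TB_any_frontin_density"]), 5)  # 10 per 2 mm^2
  expect_equal(unname(fv["TB_neg_frontin_count"]), 10)
  expect_equal(unname(fv["TB_pos_frontin_count"]), 0)
  # empty slide: everything zero
  z <- image_features(empty_cells(), part, NULL)
  expect_true(all(z == 0))
  # zero-area region yields density 0, not NaN
  part0 <- fake_partition(c(core = 0, frontin = 2, frontout = 1))
  z0 <- image_features(empty_cells(), part0, NULL)
  expect_true(all(is.finite(z0)))
})

test_that("cell populations are counted with PD-L1 state splits", {
  cells <- empty_cells()[0, ]
  add <- function(n, region, pdl1, what) {
    df <- empty_cells()[rep(1, 0), ]
    df <- data.frame(x_um = rep(0, n), y_um = 0, CD3 = FALSE, CD8 = FALSE,
                     CD68 = FALSE, CD163 = FALSE, PDL1 = pdl1 == "pos",
                     PanCK = FALSE, TB = FALSE, M1 = FALSE, M2 = FALSE,
                     total_macrophage = FALSE, general_T = FALSE,
                     cytotoxic_T = FALSE, PDL1_cell = pdl1 == "pos",
                     epithelial = FALSE, pdl1_state = pdl1, region = region)
    df[[what]] <- TRUE
    df
  }
  cells <- rbind(add(3, "core", "pos", "general_T"),
                 add(4, "core", "neg", "general_T"),
                 add(2, "frontout", "pos", "M2"))
  fv <- image_features(cells, fake_partition(), NULL)
  expect_equal(unname(fv["general_T_any_core_count"]), 7)
  expect_equal(unname(fv["general_T_pos_core_count"]), 3)
  expect_equal(unname(fv["general_T_neg_core_density"]), 2)  # 4 / 2 mm^2
  expect_equal(unname(fv["M2_pos_frontout_count"]), 2)
  expect_equal(unname(fv["PDL1cell_any_core_count"]), 3)
  expect_equal(unname(fv["PDL1cell_nonepi_frontout_count"]), 2)
})

test_that("spatial features impute CSR when tumour buds are absent", {
  fv <- spatial_features(empty_cells(), fake_partition(),
                         data.frame(centroid_x_um = numeric(0),
                                    centroid_y_um = numeric(0),
                                    region = character(0),
                                    pdl1_state = character(0)))
  expect_length(fv, 60)
  radii <- c(20, 50, 100, 150, 200, 250)
  for (pair in c("TB_CD3", "TB_PDL1epi", "CD8_PDL1"))
    expect_equal(unname(fv[paste0("L_", pair, "_r", radii)]), radii)
})

test_that("spatial features agree with a direct l_curve call", {
  coh <- small_cohort()
  p <- coh$cohort$patients[[2]]
  masks <- patient_masks(p, coh$cfg)
  part <- partition_regions(masks$tumour, masks$pixel_size)
  buds <- identify_tumour_buds(masks$epithelium, p$cells, masks$pixel_size)
  ph <- assign_phenotypes(p$cells, buds$cell_in_bud)
  cells <- cbind(p$cells[setdiff(names(p$cells), names(ph))], ph)
  cells$region <- assign_regions(cells, part)
  objs <- buds$objects[buds$objects$is_bud, ]
  objs$region <- assign_regions(data.frame(x_um = objs$centroid_x_um,
                                           y_um = objs$centroid_y_um), part)
  objs$pdl1_state <- "neg"
  fv <- spatial_features(cells, part, objs)
  sel <- cells$region != "outside" & cells$CD3 & !cells$PanCK
  X <- data.frame(x = objs$centroid_x_um[objs$region != "outside"],
                  y = objs$centroid_y_um[objs$region != "outside"])
  Y <- data.frame(x = cells$x_um[sel], y = cells$y_um[sel])
  direct <- l_curve(X, Y, sum(part$areas) * 1e6)$L
  expect_equal(unname(fv[paste0("L_TB_CD3_r", c(20, 50, 100, 150, 200, 250))]),
               direct)
})

test_that("clinical one-hot encoding is exact and strict", {
  rec <- list(age = 68, sex = "male", T_stage = "T3", N_stage = "N0",
              M_stage = "M1", stage = "IV")
  fv <- clinical_features(rec)
  expect_length(fv, 15)
  on <- c("age", "sex_male", "stage_IV", "T3", "N0", "M1stat")
  expect_equal(unname(fv[on]), c(68, 1, 1, 1, 1, 1))
  expect_true(all(fv[setdiff(names(fv), on)] == 0))
  expect_error(clinical_features(modifyList(rec, list(stage = "V"))), "unknown")
  expect_error(clinical_features(rec[-1]), "incomplete")
})

test_that("patient feature vectors share names and order across patients", {
  coh <- small_cohort()
  f1 <- patient_features(coh$cohort$patients[[1]], coh$cfg)
  f2 <- patient_features(coh$cohort$patients[[3]], coh$cfg)
  expect_identical(names(f1), names(f2))
  expect_identical(names(f1), feature_schema()$all)
  counts <- f1[grepl("_count$", names(f1))]
  expect_true(all(counts == floor(counts)))
  expect_true(all(f1[grepl("_density$", names(f1))] >= 0))
})
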