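#' Configuration for the synthetic MIBC cohort generator
#'
#' Defines the study conditions the generator emulates: slide geometry,
#' per-class point-pattern intensities and clustering, clinical
#' covariate distributions matched to a 78-patient radical-cystectomy
#' cohort, and competing-risk survival with a log-linear hazard on
#' planted feature effects.  Follow-up is administratively censored at
#' 113 months.
#'
#' @param n_patients number of patients (>= 2; default 78).
#' @param seed integer master seed.
#' @param pixel_size um/px for rendered immunofluorescence patches
#'   (default 0.5, a typical 20x scan).
#' @param mask_pixel_size um/px for slide-level masks (default 8;
#'   region geometry does not need subcellular resolution).
#' @param slide_extent slide width/height in um.
#' @param region_band invasive-front band half-width in um (default
#'   500: the front spans 500 um inside and outside the border).
#' @param tumour_radius_range min/max tumour disc radius in um.
#' @param class_intensity_ranges per class, a list of per-region
#'   `c(min, max)` intensities in points per mm^2; a patient's true
#'   intensity is drawn uniformly per class and region.
#' @param clustering per class: `list(process = "poisson")` or
#'   `list(process = "thomas", offspring_mean =, sigma_um =)`.
#' @param pdl1_prob per class probability of PD-L1 co-expression.
#' @param effect_sizes named log-hazard coefficients; names are schema
#'   feature names (density or clinical features) resolved against the
#'   generator's ground truth, z-scored across the cohort.
#' @param baseline_hazard MIBC death hazard (events/month) at the
#'   cohort-average feature profile.
#' @param otd_rate independent other-cause death hazard (events/month).
#' @param admin_censor administrative censoring time in months.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_patients = 78, seed = 1L,
    pixel_size = 0.5, mask_pixel_size = 8,
    slide_extent = c(4000, 4000), region_band = 500,
    tumour_radius_range = c(1000, 1450),
    class_intensity_ranges = list(
      tumour_bulk = list(core = c(250, 550), frontin = c(250, 550), frontout = c(0, 0)),
      TB = list(core = c(1, 15), frontin = c(3, 40), frontout = c(3, 40)),
      general_T = list(core = c(20, 300), frontin = c(20, 300), frontout = c(20, 300)),
      cytotoxic_T = list(core = c(10, 250), frontin = c(10, 250), frontout = c(10, 250)),
      M1 = list(core = c(10, 120), frontin = c(10, 120), frontout = c(10, 120)),
      M2 = list(core = c(10, 120), frontin = c(10, 120), frontout = c(10, 120))),
    clustering = list(
      general_T = list(process = "thomas", offspring_mean = 8, sigma_um = 20),
      cytotoxic_T = list(process = "thomas", offspring_mean = 8, sigma_um = 20)),
    pdl1_prob = c(tumour_bulk = 0.15, TB = 0.15, general_T = 0.10,
                  cytotoxic_T = 0.10, M1 = 0.25, M2 = 0.30),
    effect_sizes = c(TB_any_core_density = 1.0,
                     cytotoxic_T_any_frontin_density = -1.0),
    baseline_hazard = 0.02, otd_rate = 0.006, admin_censor = 113) {
  cfg <- list(n_patients = n_patients, seed = as.integer(seed),
              pixel_size = pixel_size, mask_pixel_size = mask_pixel_size,
              slide_extent = slide_extent, region_band = region_band,
              tumour_radius_range = tumour_radius_range,
              class_intensity_ranges = class_intensity_ranges,
              clustering = clustering, pdl1_prob = pdl1_prob,
              effect_sizes = effect_sizes,
              baseline_hazard = baseline_hazard, otd_rate = otd_rate,
              admin_censor = admin_censor)
  .validate_config(cfg)
  structure(cfg, class = "cohort_config")
}

.validate_config <- function(cfg) {
  if (cfg$n_patients < 2) stop("n_patients must be >= 2")
  if (cfg$pixel_size <= 0 || cfg$mask_pixel_size <= 0) stop("pixel sizes must be > 0")
  if (any(cfg$slide_extent <= 0)) stop("zero slide extent")
  if (cfg$admin_censor <= 0) stop("admin_censor must be > 0")
  if (cfg$baseline_hazard < 0 || cfg$otd_rate < 0) stop("hazard rates must be >= 0")
  if (length(cfg$effect_sizes) && any(!is.finite(cfg$effect_sizes)))
    stop("non-finite effect size")
  for (cl in names(cfg$class_intensity_ranges))
    for (rg in names(cfg$class_intensity_ranges[[cl]]))
      if (any(cfg$class_intensity_ranges[[cl]][[rg]] < 0))
        stop("intensities must be >= 0")
  invisible(TRUE)
}

# ---- point patterns ------------------------------------------------------

.geom_area_um2 <- function(geom) {
  switch(geom$type,
    rect = diff(geom$xrange) * diff(geom$yrange),
    annulus = pi * (geom$r_max^2 - geom$r_min^2),
    stop("unknown geometry type"))
}

.geom_sample <- function(geom, n) {
  if (n == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  switch(geom$type,
    rect = data.frame(x = stats::runif(n, geom$xrange[1], geom$xrange[2]),
                      y = stats::runif(n, geom$yrange[1], geom$yrange[2])),
    annulus = {
      r <- sqrt(stats::runif(n, geom$r_min^2, geom$r_max^2))
      th <- stats::runif(n, 0, 2 * pi)
      data.frame(x = geom$center[1] + r * cos(th),
                 y = geom$center[2] + r * sin(th))
    })
}

.geom_contains <- function(geom, x, y) {
  switch(geom$type,
    rect = x >= geom$xrange[1] & x <= geom$xrange[2] &
           y >= geom$yrange[1] & y <= geom$yrange[2],
    annulus = {
      d <- sqrt((x - geom$center[1])^2 + (y - geom$center[2])^2)
      d >= geom$r_min & d <= geom$r_max
    })
}

.geom_expand <- function(geom, pad) {
  switch(geom$type,
    rect = list(type = "rect", xrange = geom$xrange + c(-pad, pad),
                yrange = geom$yrange + c(-pad, pad)),
    annulus = list(type = "annulus", center = geom$center,
                   r_min = max(0, geom$r_min - pad), r_max = geom$r_max + pad))
}

#' Generate a point pattern over a region
#'
#' Homogeneous Poisson or Thomas cluster process (Poisson parents with
#' Gaussian-displaced Poisson offspring; parents are drawn on a padded
#' region and offspring clipped back, so the interior intensity matches
#' the requested one).
#'
#' @param class_config list with `intensity` (points per mm^2) and
#'   optionally `process` ("poisson", default, or "thomas"),
#'   `offspring_mean`, `sigma_um`.
#' @param region_geometry `list(type = "rect", xrange =, yrange =)` or
#'   `list(type = "annulus", center =, r_min =, r_max =)`, all in um.
#' @param seed optional integer seed (omit to consume the caller's RNG
#'   stream).
#' @return data frame with `x`, `y` in um.
#' @export
generate_point_pattern <- function(class_config, region_geometry, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lambda <- class_config$intensity
  if (is.null(lambda) || !is.finite(lambda) || lambda < 0)
    stop("intensity must be a finite non-negative number (points per mm^2)")
  A <- .geom_area_um2(region_geometry)
  if (!is.finite(A) || A <= 0) stop("region geometry is empty")
  lam_um2 <- lambda / 1e6
  process <- if (is.null(class_config$process)) "poisson" else class_config$process
  if (process == "poisson") {
    n <- stats::rpois(1, lam_um2 * A)
    return(.geom_sample(region_geometry, n))
  }
  if (process != "thomas") stop("unknown process: ", process)
  mu <- class_config$offspring_mean
  sigma <- class_config$sigma_um
  stopifnot(is.finite(mu), mu > 0, is.finite(sigma), sigma > 0)
  pad <- 4 * sigma
  parent_geom <- .geom_expand(region_geometry, pad)
  Ap <- .geom_area_um2(parent_geom)
  kappa <- lam_um2 / mu
  n_par <- stats::rpois(1, kappa * Ap)
  parents <- .geom_sample(parent_geom, n_par)
  if (n_par == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  n_off <- stats::rpois(n_par, mu)
  px <- rep(parents$x, n_off); py <- rep(parents$y, n_off)
  x <- px + stats::rnorm(length(px), 0, sigma)
  y <- py + stats::rnorm(length(py), 0, sigma)
  keep <- .geom_contains(region_geometry, x, y)
  data.frame(x = x[keep], y = y[keep])
}

# ---- immunofluorescence patch rendering ----------------------------------

#' Render a multi-channel immunofluorescence patch
#'
#' Draws each nucleus as a Gaussian blob in every channel: a high
#' amplitude where the cell carries the marker, a faint background
#' amplitude where it does not, plus additive Gaussian noise.  With the
#' default geometry the neighbourhood-mean intensity of a positive cell
#' clears the 0.125 positivity threshold and a negative cell stays well
#' below it.
#'
#' @param cells data frame with `x_um`, `y_um` and one logical column
#'   per channel (the ground-truth marker flags).
#' @param channels channel names (default the six markers).
#' @param patch_extent_um patch width/height in um.
#' @param pixel_size um/px (default 0.5).
#' @param blob_sigma_um Gaussian blob sigma in um.
#' @param amp_pos,amp_neg blob amplitudes for marker-positive and
#'   -negative cells.
#' @param noise_sd additive noise SD.
#' @param seed optional seed for the noise.
#' @return named list of numeric matrices (raw intensities, not yet
#'   normalised), one per channel.
#' @export
render_if_patch <- function(cells,
                            channels = c("CD3", "CD8", "CD68", "CD163", "PDL1", "PanCK"),
                            patch_extent_um = 128, pixel_size = 0.5,
                            blob_sigma_um = 2.5, amp_pos = 0.9, amp_neg = 0.05,
                            noise_sd = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sigma_px <- blob_sigma_um / pixel_size
  npx <- round(patch_extent_um / pixel_size)
  if (patch_extent_um < 6 * blob_sigma_um)
    stop("patch smaller than one blob")
  half <- ceiling(4 * sigma_px)
  w <- seq(-half, half)
  kernel <- exp(-outer(w^2, w^2, "+") / (2 * sigma_px^2))
  out <- lapply(channels, function(ch) {
    img <- matrix(0, npx, npx)
    if (!is.null(cells) && nrow(cells)) {
      stopifnot(ch %in% names(cells))
      cx <- floor(cells$x_um / pixel_size) + 1L
      cy <- floor(cells$y_um / pixel_size) + 1L
      amp <- ifelse(cells[[ch]], amp_pos, amp_neg)
      for (i in seq_len(nrow(cells))) {
        xs <- max(1L, cx[i] - half):min(npx, cx[i] + half)
        ys <- max(1L, cy[i] - half):min(npx, cy[i] + half)
        if (!length(xs) || !length(ys)) next
        img[xs, ys] <- img[xs, ys] +
          amp[i] * kernel[xs - cx[i] + half + 1L, ys - cy[i] + half + 1L]
      }
    }
    if (noise_sd > 0)
      img <- pmax(img + matrix(stats::rnorm(npx * npx, 0, noise_sd), npx, npx), 0)
    img
  })
  names(out) <- channels
  out
}

# ---- cohort generation ---------------------------------------------------

.stage_from_tnm <- function(T_stage, N_stage, M_stage) {
  if (M_stage == "M1") return("IV")
  if (N_stage %in% c("N1", "N2")) return(if (T_stage == "T4") "IIIB" else "IIIA")
  if (T_stage %in% c("T3", "T4")) return("IIIA")
  "II"
}

.generate_clinical <- function(id) {
  age <- min(87, max(29, round(stats::rnorm(1, 66, 11))))
  sex <- sample(c("male", "female"), 1, prob = c(0.55, 0.45))
  T_stage <- sample(c("T2", "T3", "T4"), 1, prob = c(18, 39, 21))
  N_stage <- sample(c("N0", "N1", "N2"), 1, prob = c(57, 13, 8))
  M_stage <- sample(c("M0", "M1"), 1, prob = c(51, 27))
  data.frame(patient_id = id, age = age, sex = sex,
             T_stage = T_stage, N_stage = N_stage, M_stage = M_stage,
             stage = .stage_from_tnm(T_stage, N_stage, M_stage),
             stringsAsFactors = FALSE)
}

# thin points to a hard-core minimum separation (greedy, order of draw)
.hardcore_thin <- function(pts, min_dist) {
  if (nrow(pts) <= 1L) return(pts)
  keep <- logical(nrow(pts))
  kept_x <- numeric(0); kept_y <- numeric(0)
  for (i in seq_len(nrow(pts))) {
    if (!length(kept_x) ||
        min((kept_x - pts$x[i])^2 + (kept_y - pts$y[i])^2) >= min_dist^2) {
      keep[i] <- TRUE
      kept_x <- c(kept_x, pts$x[i]); kept_y <- c(kept_y, pts$y[i])
    }
  }
  pts[keep, , drop = FALSE]
}

.generate_patient <- function(cfg, id, slides = TRUE) {
  center <- cfg$slide_extent / 2
  R <- stats::runif(1, cfg$tumour_radius_range[1], cfg$tumour_radius_range[2])
  band <- cfg$region_band
  geoms <- list(
    core = list(type = "annulus", center = center, r_min = 0, r_max = max(0, R - band)),
    frontin = list(type = "annulus", center = center, r_min = max(0, R - band), r_max = R),
    frontout = list(type = "annulus", center = center, r_min = R, r_max = R + band))
  regions <- names(geoms)
  classes <- names(cfg$class_intensity_ranges)
  lambda <- matrix(0, length(classes), length(regions),
                   dimnames = list(classes, regions))
  for (cl in classes) for (rg in regions) {
    rng <- cfg$class_intensity_ranges[[cl]][[rg]]
    lambda[cl, rg] <- stats::runif(1, rng[1], rng[2])
  }
  if (!slides) {
    return(list(patient_id = id, cells = NULL, clinical = .generate_clinical(id),
                geometry = list(center = center, tumour_radius = R),
                ground_truth = list(lambda = lambda)))
  }

  # tumour buds: hard-core object centres, 1-4 nuclei each
  bud_list <- list()
  for (rg in regions) {
    if (.geom_area_um2(geoms[[rg]]) <= 0 || lambda["TB", rg] == 0) next
    centres <- generate_point_pattern(list(intensity = lambda["TB", rg]), geoms[[rg]])
    if (nrow(centres)) bud_list[[rg]] <- centres
  }
  buds <- if (length(bud_list)) do.call(rbind, bud_list) else
    data.frame(x = numeric(0), y = numeric(0))
  buds <- .hardcore_thin(buds, 60)
  bud_nuclei <- list()
  if (nrow(buds)) {
    n_nuc <- sample.int(4, nrow(buds), replace = TRUE)
    for (b in seq_len(nrow(buds))) {
      r <- 6 * sqrt(stats::runif(n_nuc[b])); th <- stats::runif(n_nuc[b], 0, 2 * pi)
      bud_nuclei[[b]] <- data.frame(x = buds$x[b] + r * cos(th),
                                    y = buds$y[b] + r * sin(th))
    }
  }

  cell_list <- list()
  add_cells <- function(pts, class) {
    if (nrow(pts) == 0L) return()
    flags <- data.frame(CD3 = FALSE, CD8 = FALSE, CD68 = FALSE, CD163 = FALSE,
                        PDL1 = FALSE, PanCK = FALSE)[rep(1, nrow(pts)), , drop = FALSE]
    switch(class,
      tumour_bulk = { flags$PanCK <- TRUE },
      TB = { flags$PanCK <- TRUE },
      general_T = { flags$CD3 <- TRUE },
      cytotoxic_T = { flags$CD8 <- TRUE },
      M1 = { flags$CD68 <- TRUE },
      M2 = { flags$CD68 <- TRUE; flags$CD163 <- TRUE })
    flags$PDL1 <- stats::runif(nrow(pts)) < cfg$pdl1_prob[[class]]
    cell_list[[length(cell_list) + 1L]] <<- data.frame(
      x_um = pts$x, y_um = pts$y, flags, class_true = class,
      in_bud = class == "TB", row.names = NULL)
  }

  # epithelial bulk occupies the tumour mass (shrunk by a stromal rim),
  # with stromal clearings punched around each bud
  bulk_geom <- list(type = "annulus", center = center, r_min = 0,
                    r_max = max(0, R - 40))
  for (rg in c("core", "frontin")) {
    lam <- lambda["tumour_bulk", rg]
    if (lam == 0) next
    g <- geoms[[rg]]
    g$r_max <- min(g$r_max, R - 40)
    if (g$r_max <= g$r_min) next
    pts <- generate_point_pattern(list(intensity = lam), g)
    if (nrow(pts) && nrow(buds)) {
      d2min <- vapply(seq_len(nrow(pts)), function(i)
        min((buds$x - pts$x[i])^2 + (buds$y - pts$y[i])^2), numeric(1))
      pts <- pts[d2min > 30^2, , drop = FALSE]
    }
    add_cells(pts, "tumour_bulk")
  }
  if (length(bud_nuclei)) add_cells(do.call(rbind, bud_nuclei), "TB")
  for (cl in setdiff(classes, c("tumour_bulk", "TB"))) {
    clu <- cfg$clustering[[cl]]
    for (rg in regions) {
      lam <- lambda[cl, rg]
      if (lam == 0 || .geom_area_um2(geoms[[rg]]) <= 0) next
      cc <- list(intensity = lam)
      if (!is.null(clu)) cc <- utils::modifyList(clu, cc)
      add_cells(generate_point_pattern(cc, geoms[[rg]]), cl)
    }
  }
  cells <- do.call(rbind, cell_list)

  list(patient_id = id,
       cells = cells,
       clinical = .generate_clinical(id),
       geometry = list(center = center, tumour_radius = R, buds = buds,
                       bulk_rim = 40, bud_blob_radius = 14, bud_clearing = 30),
       ground_truth = list(lambda = lambda))
}

# resolve a named effect feature against a patient's ground truth
.true_feature <- function(name, patient) {
  lambda <- patient$ground_truth$lambda
  m <- regmatches(name, regexec(
    "^(TB|general_T|cytotoxic_T|M1|M2|total_macrophage)_any_(core|frontin|frontout)_density$",
    name))[[1]]
  if (length(m) == 3L) {
    cl <- m[2]; rg <- m[3]
    if (cl == "total_macrophage") return(lambda["M1", rg] + lambda["M2", rg])
    return(lambda[cl, rg])
  }
  clin <- clinical_features(patient$clinical)
  if (name %in% names(clin)) return(unname(clin[name]))
  stop("effect size refers to unknown feature: ", name)
}

#' Generate a synthetic MIBC cohort
#'
#' Draws `n_patients` synthetic patients: slide geometry (a disc tumour
#' with a stromal rim and detached tumour-bud objects), per-class point
#' patterns, clinical covariates, and competing-risk survival.  MIBC
#' death times are exponential with hazard
#' `baseline_hazard * exp(sum(effect * z))` where `z` are the named
#' true features z-scored across the cohort; other-cause death is an
#' independent exponential; follow-up ends at `admin_censor`.
#'
#' @param config a [cohort_config()].
#' @param slides generate cell tables and slide geometry (default
#'   TRUE).  With FALSE only clinical covariates, ground-truth
#'   intensities and survival are drawn -- sufficient (and much
#'   faster) for survival-scale calibration studies.
#' @return object of class `ic_cohort`: list with `patients` (each
#'   carrying `cells`, `clinical`, `geometry`, `ground_truth`,
#'   `survival_months`, `event_cause`), `clinical` (cohort data frame
#'   including survival), and `config`.
#' @export
generate_cohort <- function(config, slides = TRUE) {
  .validate_config(config)
  set.seed(config$seed)
  patients <- lapply(seq_len(config$n_patients), function(i)
    .generate_patient(config, sprintf("P%03d", i), slides = slides))

  eff <- config$effect_sizes
  lp <- numeric(length(patients))
  if (length(eff)) {
    tf <- vapply(patients, function(p)
      vapply(names(eff), .true_feature, numeric(1), patient = p),
      numeric(length(eff)))
    tf <- matrix(tf, nrow = length(eff))  # features x patients
    for (k in seq_along(eff)) {
      v <- tf[k, ]
      s <- stats::sd(v)
      z <- if (is.finite(s) && s > 0) (v - mean(v)) / s else rep(0, length(v))
      lp <- lp + eff[k] * z
    }
  }
  t_mibc <- stats::rexp(length(patients), rate = config$baseline_hazard * exp(lp))
  t_otd <- if (config$otd_rate > 0)
    stats::rexp(length(patients), rate = config$otd_rate) else rep(Inf, length(patients))
  t_obs <- pmin(t_mibc, t_otd, config$admin_censor)
  cause <- ifelse(t_obs == config$admin_censor, "alive_censored",
                  ifelse(t_mibc <= t_otd, "mibc_death", "other_death"))
  clin <- do.call(rbind, lapply(patients, `[[`, "clinical"))
  clin$survival_months <- t_obs
  clin$event_cause <- cause
  for (i in seq_along(patients)) {
    patients[[i]]$survival_months <- t_obs[i]
    patients[[i]]$event_cause <- cause[i]
    patients[[i]]$ground_truth$linear_predictor <- lp[i]
    patients[[i]]$ground_truth$t_otd <- t_otd[i]
    patients[[i]]$clinical$survival_months <- t_obs[i]
    patients[[i]]$clinical$event_cause <- cause[i]
  }
  structure(list(patients = patients, clinical = clin, config = config),
            class = "ic_cohort")
}

#' Materialise the slide masks of a synthetic patient
#'
#' Builds the binary tumour mask (the full tumour disc) and the
#' epithelium mask (the bulk epithelium shrunk by the stromal rim, with
#' a clearing punched around each tumour bud, plus one small blob per
#' bud) at the configured mask resolution.
#'
#' @param patient an element of `generate_cohort()$patients`.
#' @param config the matching `cohort_config`.
#' @return list with `tumour` and `epithelium` logical matrices and
#'   `pixel_size`.
#' @export
patient_masks <- function(patient, config) {
  ps <- config$mask_pixel_size
  nx <- round(config$slide_extent[1] / ps)
  ny <- round(config$slide_extent[2] / ps)
  g <- patient$geometry
  xc <- (seq_len(nx) - 0.5) * ps - g$center[1]
  yc <- (seq_len(ny) - 0.5) * ps - g$center[2]
  d2 <- outer(xc^2, yc^2, "+")
  tumour <- d2 <= g$tumour_radius^2
  epithelium <- d2 <= (g$tumour_radius - g$bulk_rim)^2
  buds <- g$buds
  if (nrow(buds)) {
    clear_px <- ceiling(g$bud_clearing / ps)
    for (b in seq_len(nrow(buds))) {
      bx <- buds$x[b]; by <- buds$y[b]
      ix <- max(1L, floor(bx / ps) - clear_px):min(nx, ceiling(bx / ps) + clear_px)
      iy <- max(1L, floor(by / ps) - clear_px):min(ny, ceiling(by / ps) + clear_px)
      ld2 <- outer(((ix - 0.5) * ps - bx)^2, ((iy - 0.5) * ps - by)^2, "+")
      epithelium[ix, iy][ld2 <= g$bud_clearing^2] <- FALSE
    }
    for (b in seq_len(nrow(buds))) {
      bx <- buds$x[b]; by <- buds$y[b]
      blob_px <- ceiling(g$bud_blob_radius / ps)
      ix <- max(1L, floor(bx / ps) - blob_px):min(nx, ceiling(bx / ps) + blob_px)
      iy <- max(1L, floor(by / ps) - blob_px):min(ny, ceiling(by / ps) + blob_px)
      ld2 <- outer(((ix - 0.5) * ps - bx)^2, ((iy - 0.5) * ps - by)^2, "+")
      epithelium[ix, iy][ld2 <= g$bud_blob_radius^2] <- TRUE
    }
  }
  list(tumour = tumour, epithelium = epithelium, pixel_size = ps)
}
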