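#' Phantom geometry and rendering parameters for one synthetic eye
#'
#' Describes a layered-retina B-scan phantom: smooth layer boundary curves
#' (internal limiting membrane at the top, retinal pigment epithelium at the
#' bottom, inner-layer interfaces in between), a foveal pit, one of three
#' lesion classes, per-slice geometric drift and multiplicative speckle.
#' The phantom reproduces the two properties the downstream method relies
#' on: adjacent B-scans of one eye are strongly correlated (anatomical
#' continuity across the 121-243 um slice spacing), and the lesion classes
#' are separable from image content alone.
#'
#' @param image_height,image_width image size in pixels (>= 32).
#' @param n_slices number of B-scans in the stack (>= 3; default 7 so that
#'   the pair sampler's +/-2 offset range can be exercised on the three
#'   central training slices without boundary clipping).
#' @param lesion_class one of `"control_erm"`, `"ftmh"`, `"lamellar"`.
#'   FTMH removes all inner-layer signal from ILM to RPE in a contiguous
#'   column band at the fovea; lamellar removes only a partial-depth band
#'   (RPE intact); control carries a hyperreflective surface membrane.
#' @param lesion_width width of the foveal defect in pixels (central slice).
#' @param membrane_brightness membrane intensity in `[0, 1]` (ERM only).
#' @param pit_depth,pit_width foveal pit depth and Gaussian width in pixels.
#' @param slice_drift per-slice geometry perturbation scale in pixels.
#' @param speckle_sigma log-scale of the multiplicative speckle (OCT speckle
#'   is multiplicative, so it is applied as a mean-one log-normal factor
#'   before clipping to `[0, 1]`).
#' @param slice_spacing_um distance between adjacent B-scans in micrometers
#'   (clinical macular protocols use 243 or 121).
#'
#' @return An object of class `retina_phantom_params` (a validated list).
#' @export
retina_phantom_params <- function(image_height = 128, image_width = 128,
                                  n_slices = 7,
                                  lesion_class = c("control_erm", "ftmh", "lamellar"),
                                  lesion_width = round(0.10 * image_width),
                                  membrane_brightness = 0.9,
                                  pit_depth = 0.10 * image_height,
                                  pit_width = 0.12 * image_width,
                                  slice_drift = 0.8,
                                  speckle_sigma = 0.5,
                                  slice_spacing_um = 243) {
  lesion_class <- match.arg(lesion_class)
  check_number(image_height, "image_height", lower = 32)
  check_number(image_width, "image_width", lower = 32)
  check_number(n_slices, "n_slices", lower = 3)
  check_number(lesion_width, "lesion_width", lower = 1)
  check_number(membrane_brightness, "membrane_brightness", 0, 1)
  check_number(pit_depth, "pit_depth", lower = 0)
  check_number(pit_width, "pit_width", lower = 1)
  check_number(slice_drift, "slice_drift", lower = 0)
  check_number(speckle_sigma, "speckle_sigma", lower = 0)
  check_number(slice_spacing_um, "slice_spacing_um", lower = 1)
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 n_slices = as.integer(n_slices),
                 lesion_class = lesion_class,
                 lesion_width = as.integer(lesion_width),
                 membrane_brightness = membrane_brightness,
                 pit_depth = pit_depth, pit_width = pit_width,
                 slice_drift = slice_drift, speckle_sigma = speckle_sigma,
                 slice_spacing_um = slice_spacing_um),
            class = "retina_phantom_params")
}

# Per-eye random geometry: low-order smooth boundary curves with random
# control points. Returns closures over column positions.
sample_eye_geometry <- function(params) {
  H <- params$image_height
  W <- params$image_width
  x <- seq(0, 1, length.out = W)
  # eyes differ markedly in retinal thickness, surface curvature, layer
  # reflectivity and overall gain; this between-eye diversity is the signal
  # slice-contrastive pre-training exploits, so it is drawn per eye from
  # wide ranges while within-eye drift stays small
  ilm_base <- H * runif(1, 0.20, 0.36)
  rpe_base <- ilm_base + H * runif(1, 0.24, 0.42)
  tilt <- runif(1, -0.10, 0.10) * H
  amp <- runif(1, 0.01, 0.07) * H
  freq <- runif(1, 0.4, 1.4)
  phase <- runif(1, 0, 2 * pi)
  base_curve <- tilt * (x - 0.5) + amp * cos(2 * pi * (freq * x) + phase)
  fovea_col <- round(W / 2 + runif(1, -0.04, 0.04) * W)
  fovea_col <- min(max(fovea_col, params$lesion_width + 2L),
                   W - params$lesion_width - 2L)
  inner_fracs <- sort(runif(3, c(0.16, 0.40, 0.64), c(0.32, 0.56, 0.80)))
  # foveal pit morphology. Membrane traction in ERM eyes frequently steepens
  # and deepens the pit into a pseudohole (near-vertical walls, intact base
  # tissue) that mimics FTMH; this confusability is what makes the clinical
  # discrimination hard, so about half of control eyes carry it.
  pit_scale <- 1; pit_shape <- 2; pit_width_scale <- 1
  if (params$lesion_class == "control_erm" && runif(1) < 0.5) {
    pit_scale <- runif(1, 1.6, 2.4)
    pit_shape <- 4
    pit_width_scale <- runif(1, 0.55, 0.8)
  } else if (params$lesion_class == "ftmh") {
    pit_scale <- runif(1, 0.9, 1.3)
  }
  list(ilm_base = ilm_base, rpe_base = rpe_base, base_curve = base_curve,
       pit_scale = pit_scale, pit_shape = pit_shape,
       pit_width_scale = pit_width_scale,
       fovea_col = fovea_col, inner_fracs = inner_fracs,
       layer_levels = runif(4, c(0.35, 0.22, 0.34, 0.24),
                            c(0.62, 0.46, 0.58, 0.50)),
       rpe_level = runif(1, 0.70, 0.95),
       choroid_level = runif(1, 0.06, 0.20),
       gain = runif(1, 0.80, 1.20))
}

# Render one B-scan slice from eye geometry at vertical drift `dz` (pixels)
# and lesion width scale `lscale` in [0, 1]. Noise-free; intensities in
# [0, 1]. Returns the image plus the per-column ILM/RPE boundary rows.
render_slice <- function(params, geom, dz, lscale) {
  H <- params$image_height
  W <- params$image_width
  x <- seq(0, 1, length.out = W)
  ilm <- geom$ilm_base + geom$base_curve + dz
  rpe <- geom$rpe_base + 0.5 * geom$base_curve + 0.7 * dz
  # foveal pit: dip of the inner surface toward (never reaching) the RPE;
  # shape exponent 4 gives the steep-walled flat-bottomed pseudohole form
  z <- (seq_len(W) - geom$fovea_col) / (params$pit_width * geom$pit_width_scale)
  pit <- params$pit_depth * geom$pit_scale * exp(-0.5 * z^geom$pit_shape)
  ilm_p <- pmin(ilm + pit, rpe - 0.10 * (rpe - ilm))
  rows <- matrix(seq_len(H), nrow = H, ncol = W)
  ilm_m <- matrix(ilm_p, nrow = H, ncol = W, byrow = TRUE)
  rpe_m <- matrix(rpe, nrow = H, ncol = W, byrow = TRUE)
  thick <- rpe_m - ilm_m
  img <- matrix(0.03, H, W)          # vitreous
  # inner retina: four bands between ILM and RPE
  bounds <- c(0, geom$inner_fracs, 1)
  for (k in seq_len(4)) {
    lo <- ilm_m + bounds[k] * thick
    hi <- ilm_m + bounds[k + 1] * thick
    img[rows >= lo & rows < hi] <- geom$layer_levels[k]
  }
  # bright RPE band (~3 px) and dimmer choroid below
  img[rows >= rpe_m & rows < rpe_m + 3] <- geom$rpe_level
  img[rows >= rpe_m + 3] <- geom$choroid_level
  # thin bright ILM surface line
  img[rows >= ilm_m - 1 & rows < ilm_m + 1] <- 0.60
  # per-eye global gain (tissue only; vitreous stays dark)
  tissue <- rows >= ilm_m - 1
  img[tissue] <- img[tissue] * geom$gain
  lesion_w <- round(params$lesion_width * lscale)
  if (lesion_w >= 1) {
    cols <- seq(geom$fovea_col - ceiling(lesion_w / 2) + 1,
                length.out = max(lesion_w, 1))
    cols <- cols[cols >= 1 & cols <= W]
    in_band <- matrix(FALSE, H, W)
    in_band[, cols] <- TRUE
    if (params$lesion_class == "ftmh") {
      # full-thickness defect: everything from ILM down to the RPE band
      img[in_band & rows >= ilm_m - 1 & rows < rpe_m] <- 0.01
    } else if (params$lesion_class == "lamellar") {
      # partial-thickness defect: inner half removed, outer layers and RPE intact
      img[in_band & rows >= ilm_m - 1 & rows < ilm_m + 0.45 * thick] <- 0.01
    }
  }
  if (params$lesion_class == "control_erm") {
    # hyperreflective surface membrane over the central macula, slightly wavy
    mem_cols <- seq(max(1, round(W * 0.2)), min(W, round(W * 0.8)))
    wig <- 1.5 * sin(seq(0, 3 * pi, length.out = length(mem_cols)))
    mem_m <- ilm_m
    mem_m[, mem_cols] <- sweep(ilm_m[, mem_cols, drop = FALSE], 2, wig, "+")
    on_mem <- rows >= mem_m - 3 & rows < mem_m - 1
    on_mem[, -mem_cols] <- FALSE
    img[on_mem] <- params$membrane_brightness
  }
  list(img = clip01(img), ilm = ilm_p, rpe = rpe)
}

#' Generate one synthetic eye: a B-scan stack plus its metadata row
#'
#' Renders `n_slices` B-scans sharing one eye's geometry, with smooth
#' per-slice vertical drift (a cumulative random walk of scale
#' `slice_drift`) so adjacent slices are more alike than slices from
#' different eyes. The lesion is centered on the foveal column of the
#' central slice and shrinks with distance from it, as anatomical defects
#' do. Multiplicative log-normal speckle (mean one, log-sd `speckle_sigma`)
#' is applied per pixel before clipping.
#'
#' @param params a [retina_phantom_params()] object.
#' @param demographics a list with `eye_id`, `patient_id`, `laterality`,
#'   `diagnosis`, `age`, `sex`, `preop_vision` (see [generate_cohort()]);
#'   missing entries get neutral defaults.
#' @param seed integer seed; identical `(params, demographics, seed)` give
#'   bit-identical output.
#'
#' @return A list with `volume` (a [bscan_volume()]) and `metadata`
#'   (a one-row `data.frame`).
#' @export
generate_eye <- function(params, demographics = list(), seed = 1) {
  if (!inherits(params, "retina_phantom_params"))
    stop_config("params must be a retina_phantom_params object")
  with_seed(seed, {
    geom <- sample_eye_geometry(params)
    n <- params$n_slices
    central <- (n + 1L) %/% 2L  # 1-based central slice
    drift <- cumsum(rnorm(n, 0, params$slice_drift))
    drift <- drift - drift[central]
    slices <- vector("list", n)
    bounds <- vector("list", n)
    for (s in seq_len(n)) {
      # lesion cross-section follows a spherical-cap profile over slices: a
      # full-thickness defect several hundred micrometers wide stays visible
      # in the neighboring B-scans (its presence is a stable property of the
      # eye), narrowing only toward the cap edge
      lscale <- sqrt(max(0, 1 - (abs(s - central) / 5)^2))
      rs <- render_slice(params, geom, drift[s], lscale)
      img <- rs$img
      bounds[[s]] <- rs[c("ilm", "rpe")]
      if (params$speckle_sigma > 0) {
        sg <- params$speckle_sigma
        fac <- exp(rnorm(length(img), 0, sg) - sg^2 / 2)
        img <- clip01(img * fac)
      }
      slices[[s]] <- img
    }
    vol <- bscan_volume(eye_id = demographics$eye_id %||% "eye0001",
                        slices = slices, central = central,
                        slice_spacing_um = params$slice_spacing_um)
    # per-slice ILM/RPE boundary rows (analysis metadata; not serialized)
    vol$layer_bounds <- bounds
    vol$fovea_col <- geom$fovea_col
    meta <- data.frame(
      eye_id = vol$eye_id,
      patient_id = demographics$patient_id %||% "pat0001",
      laterality = demographics$laterality %||% "OD",
      diagnosis = demographics$diagnosis %||%
        switch(params$lesion_class, ftmh = "FTMH", lamellar = "LAMELLAR",
               control_erm = "ERM"),
      age = demographics$age %||% 70,
      sex = demographics$sex %||% "F",
      preop_vision = demographics$preop_vision %||% 0.5,
      n_slices = n,
      central_slice_index = central - 1L,  # 0-based in the interchange schema
      slice_spacing_um = params$slice_spacing_um,
      path = NA_character_,
      stringsAsFactors = FALSE)
    list(volume = vol, metadata = meta)
  })
}

#' Cohort configuration for the synthetic study population
#'
#' Defaults reproduce the study population the classifier is built for:
#' 61 FTMH eyes (mean age 69.6, SD 6.4; 46 female / 15 male) and 273 ERM
#' control eyes (mean age 70.5, SD 8.6; 140 female / 133 male), a small
#' fraction of patients contributing both eyes, and macular scan protocols
#' at 243 or 121 um slice spacing.
#'
#' @param n_ftmh,n_erm,n_lamellar eyes per class.
#' @param image_height,image_width,n_slices per-eye stack geometry.
#' @param age_mean,age_sd named per-class normal age parameters (years).
#' @param female_prop named per-class probability an eye's patient is female.
#' @param bilateral_prop named per-class probability a patient contributes
#'   two eyes.
#' @param vision_mean,vision_sd per-class pre-operative acuity score
#'   parameters (generic continuous score; higher = worse).
#' @param speckle_sigma,slice_drift,lesion_width_frac,pit_depth_frac
#'   rendering parameters passed through to [retina_phantom_params()]
#'   (lesion width and pit depth as fractions of image size).
#' @param slice_spacing_choices spacing protocols sampled per eye (um).
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_ftmh = 61, n_erm = 273, n_lamellar = 0,
                          image_height = 128, image_width = 128, n_slices = 7,
                          age_mean = c(FTMH = 69.6, ERM = 70.5, LAMELLAR = 70.0),
                          age_sd = c(FTMH = 6.4, ERM = 8.6, LAMELLAR = 8.0),
                          female_prop = c(FTMH = 46 / 61, ERM = 140 / 273,
                                          LAMELLAR = 0.6),
                          bilateral_prop = c(FTMH = 1 / 60, ERM = 9 / 264,
                                             LAMELLAR = 0.03),
                          vision_mean = c(FTMH = 0.9, ERM = 0.5, LAMELLAR = 0.5),
                          vision_sd = c(FTMH = 0.3, ERM = 0.25, LAMELLAR = 0.25),
                          speckle_sigma = 0.5, slice_drift = 0.8,
                          lesion_width_frac = 0.10, pit_depth_frac = 0.10,
                          slice_spacing_choices = c(243, 121)) {
  check_number(n_ftmh, "n_ftmh", lower = 0)
  check_number(n_erm, "n_erm", lower = 0)
  check_number(n_lamellar, "n_lamellar", lower = 0)
  if (n_ftmh + n_erm + n_lamellar < 1)
    stop_config("cohort must contain at least one eye")
  check_number(n_slices, "n_slices", lower = 3)
  structure(mget(names(formals()), envir = environment()),
            class = "cohort_config")
}

# demographics for one patient of a given class
sample_patient_demographics <- function(config, klass) {
  list(age = round(rnorm(1, config$age_mean[[klass]], config$age_sd[[klass]]), 1),
       sex = if (runif(1) < config$female_prop[[klass]]) "F" else "M")
}

#' Generate a synthetic cohort of eyes with demographics
#'
#' Draws patients per class (some bilateral, per `bilateral_prop`), samples
#' their demographics, and renders one phantom volume per eye. Both eyes of
#' a bilateral patient share diagnosis, age and sex but have independent
#' geometry.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; output is bit-reproducible from
#'   `(config, seed)`.
#' @return A list with `volumes` (named list of [bscan_volume()] keyed by
#'   eye id) and `manifest` (a `data.frame`, one row per eye).
#' @export
generate_cohort <- function(config, seed = 1) {
  if (!inherits(config, "cohort_config"))
    stop_config("config must be a cohort_config object")
  counts <- c(FTMH = config$n_ftmh, ERM = config$n_erm,
              LAMELLAR = config$n_lamellar)
  if (sum(counts) < 1) stop_config("cohort must contain at least one eye")
  with_seed(seed, {
    eye_rows <- list()
    eye_i <- 0L
    pat_i <- 0L
    for (klass in names(counts)) {
      remaining <- counts[[klass]]
      while (remaining > 0) {
        pat_i <- pat_i + 1L
        demo <- sample_patient_demographics(config, klass)
        n_eyes <- if (remaining >= 2 &&
                      runif(1) < config$bilateral_prop[[klass]]) 2L else 1L
        lats <- if (n_eyes == 2L) c("OD", "OS") else sample(c("OD", "OS"), 1)
        for (e in seq_len(n_eyes)) {
          eye_i <- eye_i + 1L
          eye_rows[[eye_i]] <- list(
            eye_id = sprintf("eye%04d", eye_i),
            patient_id = sprintf("pat%04d", pat_i),
            laterality = lats[e],
            diagnosis = klass,
            age = demo$age, sex = demo$sex,
            preop_vision = round(rnorm(1, config$vision_mean[[klass]],
                                       config$vision_sd[[klass]]), 3),
            eye_seed = sample.int(2147483646L, 1))
        }
        remaining <- remaining - n_eyes
      }
    }
    volumes <- vector("list", length(eye_rows))
    manifest <- vector("list", length(eye_rows))
    for (i in seq_along(eye_rows)) {
      row <- eye_rows[[i]]
      lesion <- switch(row$diagnosis, FTMH = "ftmh", ERM = "control_erm",
                       LAMELLAR = "lamellar")
      params <- retina_phantom_params(
        image_height = config$image_height, image_width = config$image_width,
        n_slices = config$n_slices, lesion_class = lesion,
        lesion_width = max(4L, round(config$lesion_width_frac * config$image_width)),
        pit_depth = config$pit_depth_frac * config$image_height,
        slice_drift = config$slice_drift, speckle_sigma = config$speckle_sigma,
        slice_spacing_um = sample(config$slice_spacing_choices, 1))
      out <- generate_eye(params, row, seed = row$eye_seed)
      volumes[[i]] <- out$volume
      manifest[[i]] <- out$metadata
    }
    manifest <- do.call(rbind, manifest)
    names(volumes) <- manifest$eye_id
    list(volumes = volumes, manifest = manifest)
  })
}

#' Generate the lamellar/pseudohole challenge set
#'
#' A separate group of eyes carrying partial-thickness foveal defects that
#' visually resemble FTMH but leave the RPE and outer layers intact. The
#' ground-truth binary label for evaluation is FTMH-negative for every eye.
#'
#' @param config a [cohort_config()]; class counts are overridden so that
#'   all eyes are lamellar (`n_lamellar` kept if positive, else 34).
#' @param seed integer seed.
#' @return As [generate_cohort()]; all manifest rows have diagnosis
#'   `LAMELLAR`.
#' @export
generate_challenge_set <- function(config, seed = 1) {
  if (!inherits(config, "cohort_config"))
    stop_config("config must be a cohort_config object")
  n <- if (config$n_lamellar >= 1) config$n_lamellar else 34
  config$n_ftmh <- 0
  config$n_erm <- 0
  config$n_lamellar <- n
  generate_cohort(config, seed = seed)
}
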