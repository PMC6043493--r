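# Synthetic quantitative-MRI brain phantom: lattice-placed bilateral box ROIs
# over a CSF background, ground-truth myelin per ROI, four-compartment
# quantitative maps, a smooth transmit-field surface, partial-volume maps,
# reference structures for intensity calibration, and forward-simulated FLASH
# triplets with dual-angle B1 acquisitions.

.TISSUE_CLASSES <- c("wm", "subcortical_gm", "cortical_gm")

# reference structures outside the brain used by the T1w/T2w calibration
.EYE_PARAMS <- c(r1 = 0.26, r2 = 1.0, pd = 100)
.MUSCLE_PARAMS <- c(r1 = 0.71, r2 = 33, pd = 80)

#' Configuration of the synthetic brain phantom
#'
#' Defaults reproduce the study conditions the pipeline is meant to emulate:
#' 48 white-matter ROIs, 12 subcortical grey ROIs, per-class myelin volume
#' fractions of 30.70/17.38/10.57 percent (SD 4.81/4.11/6.07) for WM,
#' subcortical GM and cortical GM, and cross-metric class offsets that give
#' the MT-saturation and ratio metrics their own class profiles
#' (20.55/16.18 and 27.11/21.17 percent after white-matter calibration).
#'
#' @param grid_shape integer triple of voxel counts per axis.
#' @param n_wm_rois,n_subcortical_rois,n_cortical_rois ROI counts per class
#'   (each >= 1). Every ROI is bilateral: one ROI id labels two mirrored
#'   boxes.
#' @param mvf_mean_by_class,mvf_sd_by_class per-class mean and SD of the
#'   ground-truth myelin volume fraction (fractions in [0, 0.40)).
#' @param mtsat_offset_by_class per-class offsets (MVF fraction units) of the
#'   MT-saturation latent relative to the ground truth; they encode the
#'   MT metric's systematically flatter grey/white contrast.
#' @param ratio_offset_by_class per-class offsets (MVF fraction units) of the
#'   ratio latent. The synthesized contrasts already produce most of the
#'   ratio metric's class profile; the defaults are the small residual
#'   corrections that steer the subcortical and cortical ratio means onto
#'   their target relative levels (88 and 69 percent of white matter).
#' @param subject_sd SD of the subject-by-ROI myelin deviation shared by all
#'   metrics (fraction units).
#' @param mtsat_noise_sd,ratio_noise_sd SD of the metric-specific latent
#'   noise (fraction units); the ratio metric is deliberately the noisier
#'   myelin reporter.
#' @param mtsat_per_mvf MT saturation (dimensionless) produced per unit
#'   myelin volume fraction; the default maps a 30.7 percent WM to a 3.66
#'   p.u. saturation.
#' @param ratio_log_gain gain of the ratio-specific multiplicative
#'   modulation applied to the T1-weighted contrast (per unit MVF).
#' @param noise_sigma additive Gaussian noise, as a fraction of each
#'   volume's mean signal (applied to quantitative maps and simulated
#'   signals).
#' @param b1_range low/high relative transmit-field bounds,
#'   `0 < low <= 1 <= high`.
#' @param water_proportions split of the non-myelin volume between cellular,
#'   free and excess parenchymal water inside brain tissue.
#' @param seed subject-level seed (integer).
#' @param anatomy_seed cohort-level seed fixing ROI geometry and the
#'   per-ROI anatomical myelin profile, shared across subjects.
#' @param params [compartment_params()] used by the forward model.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64L, 64L, 64L),
                           n_wm_rois = 48L,
                           n_subcortical_rois = 12L,
                           n_cortical_rois = 20L,
                           mvf_mean_by_class = c(wm = 0.3070,
                                                 subcortical_gm = 0.1738,
                                                 cortical_gm = 0.1057),
                           mvf_sd_by_class = c(wm = 0.0481,
                                               subcortical_gm = 0.0411,
                                               cortical_gm = 0.0607),
                           mtsat_offset_by_class = c(wm = 0,
                                                     subcortical_gm = 0.0317,
                                                     cortical_gm = 0.0561),
                           ratio_offset_by_class = c(wm = 0,
                                                     subcortical_gm = 0.035,
                                                     cortical_gm = -0.015),
                           subject_sd = 0.015,
                           mtsat_noise_sd = 0.020,
                           ratio_noise_sd = 0.055,
                           mtsat_per_mvf = 0.0366 / 0.3070,
                           ratio_log_gain = 1.85,
                           noise_sigma = 0.01,
                           b1_range = c(0.94, 1.06),
                           water_proportions = c(cellular = 0.96,
                                                 free_water = 0.03,
                                                 epw = 0.01),
                           seed = 1L,
                           anatomy_seed = 101L,
                           params = compartment_params()) {
  grid_shape <- as.integer(grid_shape)
  counts <- c(n_wm_rois, n_subcortical_rois, n_cortical_rois)
  if (length(grid_shape) != 3 || any(grid_shape < 8)) {
    stop("grid_shape must be three dimensions of at least 8 voxels", call. = FALSE)
  }
  if (any(counts < 1)) stop("every ROI count must be >= 1", call. = FALSE)
  mvf_mean_by_class <- mvf_mean_by_class[.TISSUE_CLASSES]
  mvf_sd_by_class <- mvf_sd_by_class[.TISSUE_CLASSES]
  if (any(!is.finite(mvf_mean_by_class)) || any(mvf_mean_by_class < 0) ||
      any(mvf_mean_by_class >= .MVF_CAP)) {
    stop(sprintf(
      "class mean MVF must lie in [0, %.2f): the model rejects nonphysiological myelin fractions",
      .MVF_CAP), call. = FALSE)
  }
  if (any(mvf_sd_by_class < 0)) stop("mvf_sd_by_class must be >= 0", call. = FALSE)
  if (!(b1_range[1] > 0 && b1_range[1] <= 1 && b1_range[2] >= 1)) {
    stop("b1_range must satisfy 0 < low <= 1 <= high", call. = FALSE)
  }
  stopifnot(noise_sigma >= 0, subject_sd >= 0, mtsat_noise_sd >= 0,
            ratio_noise_sd >= 0, mtsat_per_mvf > 0)
  wp <- water_proportions / sum(water_proportions)

  cfg <- structure(
    list(grid_shape = grid_shape, n_wm_rois = as.integer(n_wm_rois),
         n_subcortical_rois = as.integer(n_subcortical_rois),
         n_cortical_rois = as.integer(n_cortical_rois),
         mvf_mean_by_class = mvf_mean_by_class,
         mvf_sd_by_class = mvf_sd_by_class,
         mtsat_offset_by_class = mtsat_offset_by_class[.TISSUE_CLASSES],
         ratio_offset_by_class = ratio_offset_by_class[.TISSUE_CLASSES],
         subject_sd = subject_sd, mtsat_noise_sd = mtsat_noise_sd,
         ratio_noise_sd = ratio_noise_sd, mtsat_per_mvf = mtsat_per_mvf,
         ratio_log_gain = ratio_log_gain, noise_sigma = noise_sigma,
         b1_range = as.numeric(b1_range), water_proportions = wp,
         seed = as.integer(seed), anatomy_seed = as.integer(anatomy_seed),
         params = params),
    class = "phantom_config"
  )
  # fail on impossible geometry now rather than at build time
  .roi_lattice(cfg)
  cfg
}

# Deterministic bilateral lattice placement. The grid is tiled with 8^3 cells;
# each ROI claims one cell in the left half of the x axis plus its mirror in
# the right half. Each box spans 5 voxels per axis (offsets 2..6 of the cell),
# with a 3^3 pure-tissue core and a one-voxel partial-volume shell.
.roi_lattice <- function(cfg) {
  cell <- 8L
  dims <- cfg$grid_shape
  nx <- dims[1] %/% cell; ny <- dims[2] %/% cell; nz <- dims[3] %/% cell
  nx_half <- nx %/% 2L
  total <- cfg$n_wm_rois + cfg$n_subcortical_rois + cfg$n_cortical_rois + 2L
  capacity <- nx_half * ny * nz
  if (capacity < total) {
    stop(sprintf(
      "grid %s cannot host %d bilateral ROIs (+2 reference structures); capacity %d",
      paste(dims, collapse = "x"), total - 2L, capacity), call. = FALSE)
  }
  k <- seq_len(total) - 1L
  cx <- k %% nx_half
  cy <- (k %/% nx_half) %% ny
  cz <- k %/% (nx_half * ny)
  # left box start voxel (1-based) and mirrored right box
  x0 <- cx * cell + 3L
  y0 <- cy * cell + 3L
  z0 <- cz * cell + 3L
  x0_mirror <- dims[1] - (x0 + 4L) + 1L
  list(cell = cell, total = total,
       left = cbind(x = x0, y = y0, z = z0),
       right = cbind(x = x0_mirror, y = y0, z = z0))
}

.box_voxels <- function(origin, side, dims) {
  xs <- origin[1]:(origin[1] + side - 1L)
  ys <- origin[2]:(origin[2] + side - 1L)
  zs <- origin[3]:(origin[3] + side - 1L)
  as.matrix(expand.grid(x = xs, y = ys, z = zs))
}

.vox_index <- function(vox, dims) {
  (vox[, 3] - 1L) * dims[1] * dims[2] + (vox[, 2] - 1L) * dims[1] + vox[, 1]
}

#' Build one synthetic subject
#'
#' Deterministic for a fixed configuration: ROI geometry and the per-ROI
#' anatomical myelin profile come from `anatomy_seed` (shared across a
#' cohort), subject-level deviations, metric-specific latents, the transmit
#' field and measurement noise from `seed`. Per-ROI mean myelin is drawn from
#' the class distribution and clipped to the physiological `[0, 0.40]` range;
#' quantitative maps follow from the four-compartment forward model, with
#' background voxels carrying the fixed CSF parameters.
#'
#' @param config a [phantom_config()].
#' @return Object of class `mri_phantom` with elements `label_map`,
#'   `roi_info` (tibble: roi_id, roi_name, tissue_class, per-metric latent
#'   means), `truth_mvf`, `delta_true`, `partial_volume` (list wm/gm/csf),
#'   `quantitative` (list r1/r2/pd), `b1_map`, `t1w_modulation`,
#'   `contrast_gains`, and `config`.
#' @export
build_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  dims <- config$grid_shape
  lat <- .roi_lattice(config)
  n_tissue <- config$n_wm_rois + config$n_subcortical_rois + config$n_cortical_rois
  classes <- rep(.TISSUE_CLASSES,
                 times = c(config$n_wm_rois, config$n_subcortical_rois,
                           config$n_cortical_rois))

  # --- anatomy stream: fixed across subjects of a cohort
  z_roi <- with_local_seed(config$anatomy_seed, rnorm(n_tissue))

  # --- subject stream
  sub <- with_local_seed(config$seed, {
    list(
      w = rnorm(n_tissue),                     # shared myelin deviation
      e_mt = rnorm(n_tissue),                  # MT-specific latent noise
      e_rt = rnorm(n_tissue),                  # ratio-specific latent noise
      b1_coef = rnorm(10),
      gains = exp(rnorm(2, sd = 0.2))          # T1w / T2w receive gains
    )
  })

  mu <- config$mvf_mean_by_class[classes]
  sigma <- config$mvf_sd_by_class[classes]
  mvf_roi <- pmin(pmax(mu + sigma * z_roi + config$subject_sd * sub$w, 0), .MVF_CAP)
  mt_roi <- pmax(mvf_roi + config$mtsat_offset_by_class[classes] +
                   config$mtsat_noise_sd * sub$e_mt, 0)
  rt_roi <- mvf_roi + config$ratio_offset_by_class[classes] +
    config$ratio_noise_sd * sub$e_rt

  roi_info <- tibble::tibble(
    roi_id = seq_len(n_tissue),
    roi_name = sprintf("%s_%02d", classes,
                       stats::ave(seq_len(n_tissue), classes, FUN = seq_along)),
    tissue_class = classes,
    truth_mvf = unname(mvf_roi),
    mtsat_latent = unname(mt_roi),
    ratio_latent = unname(rt_roi)
  )

  label_map <- array(0L, dims)
  truth <- array(0, dims)
  delta_true <- array(0, dims)
  t1w_mod <- array(1, dims)
  pv_wm <- array(0, dims); pv_gm <- array(0, dims); pv_csf <- array(1, dims)
  # quantitative maps start as CSF background
  csf <- effective_parameters(c(0, 0, 1, 0), config$params)
  r1 <- array(csf[["r1"]], dims)
  r2 <- array(csf[["r2"]], dims)
  pd <- array(csf[["pd"]], dims)

  wp <- config$water_proportions
  side <- 5L
  for (r in seq_len(lat$total)) {
    vox <- rbind(.box_voxels(lat$left[r, ], side, dims),
                 .box_voxels(lat$right[r, ], side, dims))
    idx <- .vox_index(vox, dims)
    core <- rbind(.box_voxels(lat$left[r, ] + 1L, side - 2L, dims),
                  .box_voxels(lat$right[r, ] + 1L, side - 2L, dims))
    core_idx <- .vox_index(core, dims)
    shell_idx <- setdiff(idx, core_idx)

    if (r <= n_tissue) {
      label_map[idx] <- r
      v <- mvf_roi[r]
      truth[idx] <- v
      delta_true[idx] <- config$mtsat_per_mvf * mt_roi[r]
      t1w_mod[idx] <- exp(config$ratio_log_gain * (rt_roi[r] - mvf_roi[r]))
      state <- c(v, (1 - v) * wp)
      eff <- effective_parameters(state, config$params)
      r1[idx] <- eff[["r1"]]; r2[idx] <- eff[["r2"]]; pd[idx] <- eff[["pd"]]
      cls <- classes[r]
      pv_csf[idx] <- 0.1; pv_csf[core_idx] <- 0
      if (cls == "wm") {
        pv_wm[core_idx] <- 1; pv_wm[shell_idx] <- 0.9
      } else if (cls == "cortical_gm") {
        pv_gm[core_idx] <- 1; pv_gm[shell_idx] <- 0.9
      } else {
        # subcortical grey segments partly as white matter
        pv_wm[core_idx] <- 0.5; pv_gm[core_idx] <- 0.5
        pv_wm[shell_idx] <- 0.45; pv_gm[shell_idx] <- 0.45
      }
    } else {
      # reference structures (eye then muscle), outside the brain tissue masks
      ref <- if (r == n_tissue + 1L) .EYE_PARAMS else .MUSCLE_PARAMS
      label_map[idx] <- r
      r1[idx] <- ref[["r1"]]; r2[idx] <- ref[["r2"]]; pd[idx] <- ref[["pd"]]
      pv_csf[idx] <- 0
    }
  }
  roi_info <- dplyr::bind_rows(
    roi_info,
    tibble::tibble(roi_id = n_tissue + 1:2, roi_name = c("eye", "muscle"),
                   tissue_class = c("eye", "muscle"), truth_mvf = 0,
                   mtsat_latent = 0, ratio_latent = 0)
  )

  # smooth low-order polynomial transmit field, min-max mapped into b1_range
  co <- seq_len(dims[1]); u <- (co - mean(co)) / max(co - mean(co))
  co <- seq_len(dims[2]); v2 <- (co - mean(co)) / max(co - mean(co))
  co <- seq_len(dims[3]); w2 <- (co - mean(co)) / max(co - mean(co))
  U <- array(rep(u, times = dims[2] * dims[3]), dims)
  V <- array(rep(rep(v2, each = dims[1]), times = dims[3]), dims)
  W <- array(rep(w2, each = dims[1] * dims[2]), dims)
  cf <- sub$b1_coef
  poly <- cf[1] + cf[2] * U + cf[3] * V + cf[4] * W + cf[5] * U^2 +
    cf[6] * V^2 + cf[7] * W^2 + cf[8] * U * V + cf[9] * U * W + cf[10] * V * W
  rng <- range(poly)
  b1 <- if (diff(config$b1_range) == 0 || diff(rng) == 0) {
    array(mean(config$b1_range), dims)
  } else {
    config$b1_range[1] +
      (poly - rng[1]) / diff(rng) * diff(config$b1_range)
  }

  # measurement noise on the quantitative maps (additive, relative to the
  # mean map value), drawn from a dedicated stream so noise-free phantoms
  # remain bit-identical to sigma = 0 runs
  if (config$noise_sigma > 0) {
    nz <- with_local_seed(config$seed + 1000003L, {
      list(rnorm(length(r1)), rnorm(length(r2)), rnorm(length(pd)))
    })
    r1 <- r1 + config$noise_sigma * mean(r1) * array(nz[[1]], dims)
    r2 <- r2 + config$noise_sigma * mean(r2) * array(nz[[2]], dims)
    pd <- pd + config$noise_sigma * mean(pd) * array(nz[[3]], dims)
  }

  structure(
    list(label_map = label_map, roi_info = roi_info, truth_mvf = truth,
         delta_true = delta_true,
         partial_volume = list(wm = pv_wm, gm = pv_gm, csf = pv_csf),
         quantitative = list(r1 = r1, r2 = r2, pd = pd),
         b1_map = b1, t1w_modulation = t1w_mod,
         contrast_gains = c(t1w = sub$gains[1], t2w = sub$gains[2]),
         config = config),
    class = "mri_phantom"
  )
}

#' @export
print.mri_phantom <- function(x, ...) {
  cat(sprintf(
    "<mri_phantom> %s voxels, %d ROIs (%d WM, %d subcortical GM, %d cortical GM), seed %d\n",
    paste(dim(x$label_map), collapse = "x"),
    sum(x$roi_info$tissue_class %in% .TISSUE_CLASSES),
    x$config$n_wm_rois, x$config$n_subcortical_rois, x$config$n_cortical_rois,
    x$config$seed
  ))
  invisible(x)
}

#' Default FLASH protocol
#'
#' T1-weighted: TR 10 ms, flip 13 degrees; PD- and MT-weighted: TR 24 ms,
#' flip 4 degrees; dual-angle B1 mapping at nominal 10 degrees.
#'
#' @export
flash_protocol <- function() {
  list(
    t1w = list(TR = 0.010, alpha_deg = 13),
    pdw = list(TR = 0.024, alpha_deg = 4),
    mtw = list(TR = 0.024, alpha_deg = 4),
    b1_alpha_deg = 10
  )
}

#' Rational spoiled-FLASH signal model
#'
#' `S = A * alpha * (TR*R1) / (alpha^2/2 + TR*R1 + delta)`: the small-angle
#' rational approximation of the spoiled gradient-echo steady state that the
#' saturation estimators invert exactly. `delta` is the per-TR MT saturation
#' (0 for non-MT acquisitions).
#'
#' @param A signal amplitude (arbitrary units).
#' @param R1 longitudinal relaxation rate (s^-1).
#' @param TR repetition time (s).
#' @param alpha excitation flip angle (radians; this low-level function is
#'   the one interface that takes radians directly).
#' @param delta MT saturation per TR (dimensionless).
#' @return Signal in the units of `A`.
#' @export
flash_signal <- function(A, R1, TR, alpha, delta = 0) {
  A * alpha * (TR * R1) / (alpha^2 / 2 + TR * R1 + delta)
}

#' Simulate the FLASH triplet and dual-angle B1 acquisitions
#'
#' Forward model `S = A * a * (TR*R1) / (a^2/2 + TR*R1 + delta)` with the
#' local flip angle `a = alpha_nominal * b1` and amplitude `A` proportional
#' to proton density. The MT-weighted image carries the phantom's true
#' saturation modulated by the local MT-pulse power,
#' `delta_local = delta_true * (1 - 0.4*b1) / 0.6`, the dependence the
#' residual B1 correction removes. The dual-angle images are proportional to
#' `sin(a_local)` and `sin(2*a_local)`.
#'
#' @param phantom an [build_phantom()] phantom.
#' @param protocol list as from [flash_protocol()].
#' @param noise_sigma additive Gaussian noise as a fraction of each image's
#'   mean signal; defaults to the phantom configuration's value.
#' @return List with `t1w`, `pdw`, `mtw` ([flash_image()]) and `b1_pair`.
#' @export
simulate_flash_triplet <- function(phantom, protocol = flash_protocol(),
                                   noise_sigma = phantom$config$noise_sigma) {
  stopifnot(inherits(phantom, "mri_phantom"))
  for (nm in c("t1w", "pdw", "mtw")) {
    p <- protocol[[nm]]
    if (p$TR <= 0 || p$alpha_deg <= 0) {
      stop("protocol TR and flip angle must be positive", call. = FALSE)
    }
  }
  A <- phantom$quantitative$pd
  R1 <- phantom$quantitative$r1
  b1 <- phantom$b1_map
  delta_local <- phantom$delta_true * (1 - 0.4 * b1) / (1 - 0.4)

  mk <- function(p, delta, mt) {
    a <- deg2rad(p$alpha_deg) * b1
    flash_image(flash_signal(A, R1, p$TR, a, delta), p$TR, p$alpha_deg, mt)
  }
  t1w <- mk(protocol$t1w, 0, FALSE)
  pdw <- mk(protocol$pdw, 0, FALSE)
  mtw <- mk(protocol$mtw, delta_local, TRUE)

  ab <- deg2rad(protocol$b1_alpha_deg) * b1
  img_a <- 1000 * sin(ab)
  img_2a <- 1000 * sin(2 * ab)

  if (noise_sigma > 0) {
    imgs <- list(t1w$signal, pdw$signal, mtw$signal, img_a, img_2a)
    nz <- with_local_seed(phantom$config$seed + 2000003L,
                          lapply(imgs, function(x) rnorm(length(x))))
    add <- function(x, z) x + noise_sigma * mean(x) * array(z, dim(x))
    t1w$signal <- add(t1w$signal, nz[[1]])
    pdw$signal <- add(pdw$signal, nz[[2]])
    mtw$signal <- add(mtw$signal, nz[[3]])
    img_a <- add(img_a, nz[[4]])
    img_2a <- add(img_2a, nz[[5]])
  }

  list(t1w = t1w, pdw = pdw, mtw = mtw,
       b1_pair = list(img_alpha = img_a, img_2alpha = img_2a,
                      alpha_deg = protocol$b1_alpha_deg))
}

#' Write a phantom to disk as NIfTI volumes plus a JSON sidecar
#'
#' All volumes share one affine (they are co-registered by construction) and
#' are stored at double precision so a read-back is voxelwise identical.
#'
#' @param phantom an [build_phantom()] phantom.
#' @param dir output directory, created if needed.
#' @return Invisibly, the vector of file paths written.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "mri_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vols <- list(
    label_map = phantom$label_map, truth_mvf = phantom$truth_mvf,
    delta_true = phantom$delta_true, r1 = phantom$quantitative$r1,
    r2 = phantom$quantitative$r2, pd = phantom$quantitative$pd,
    b1 = phantom$b1_map, t1w_modulation = phantom$t1w_modulation,
    pv_wm = phantom$partial_volume$wm, pv_gm = phantom$partial_volume$gm,
    pv_csf = phantom$partial_volume$csf
  )
  paths <- character(0)
  for (nm in names(vols)) {
    path <- file.path(dir, paste0(nm, ".nii.gz"))
    dtype <- if (nm == "label_map") "int32" else "double"
    ok <- try(RNifti::writeNifti(vols[[nm]], path, datatype = dtype), silent = TRUE)
    if (inherits(ok, "try-error")) {
      stop(sprintf("failed to write %s: %s", path, as.character(ok)), call. = FALSE)
    }
    paths <- c(paths, path)
  }
  meta <- list(
    seed = phantom$config$seed,
    anatomy_seed = phantom$config$anatomy_seed,
    grid_shape = phantom$config$grid_shape,
    mvf_mean_by_class = as.list(phantom$config$mvf_mean_by_class),
    mvf_sd_by_class = as.list(phantom$config$mvf_sd_by_class),
    noise_sigma = phantom$config$noise_sigma,
    b1_range = phantom$config$b1_range,
    contrast_gains = as.list(phantom$contrast_gains),
    protocol = flash_protocol(),
    roi_info = phantom$roi_info
  )
  meta_path <- file.path(dir, "phantom.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, meta_path))
}

#' Read back a phantom directory written by [write_phantom()]
#'
#' @param dir directory containing the NIfTI volumes and `phantom.json`.
#' @return List with the volume arrays and the parsed metadata; not a full
#'   `mri_phantom` (the configuration object is reconstructed only as far as
#'   the sidecar records it).
#' @export
read_phantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "phantom.json"), simplifyVector = TRUE)
  nm <- c("label_map", "truth_mvf", "delta_true", "r1", "r2", "pd", "b1",
          "t1w_modulation", "pv_wm", "pv_gm", "pv_csf")
  vols <- lapply(nm, function(x) {
    v <- RNifti::readNifti(file.path(dir, paste0(x, ".nii.gz")))
    array(as.numeric(v), dim = dim(v))
  })
  names(vols) <- nm
  vols$label_map <- array(as.integer(vols$label_map), dim = dim(vols$label_map))
  c(vols, list(meta = meta))
}
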