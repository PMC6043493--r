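# End-to-end orchestration: simulate a cohort, compute the three myelin
# proxies per subject, extract ROI tables, calibrate, compare, and write the
# report with reproducibility metadata.

#' Configuration of a full pipeline run
#'
#' @param out_dir output directory.
#' @param phantom a [phantom_config()]; its `seed` is the cohort base seed
#'   (subject s uses `seed + s`) and also the shared `anatomy_seed`.
#' @param n_subjects number of synthetic subjects (>= 2 for the statistics
#'   stage).
#' @param protocol FLASH protocol, see [flash_protocol()].
#' @param lookup_step lookup-grid resolution (volume fraction).
#' @param contrast synthetic-contrast parameters: T1w TR 0.5 s / TE 0.01 s,
#'   T2w TR 4.5 s / TE 0.1 s by default.
#' @param refs calibration references, see [calibration_refs()].
#' @param write_volumes write per-subject metric NIfTI volumes.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       phantom = phantom_config(),
                       n_subjects = 20L,
                       protocol = flash_protocol(),
                       lookup_step = 0.01,
                       contrast = list(t1w = c(TR = 0.5, TE = 0.01),
                                       t2w = c(TR = 4.5, TE = 0.1)),
                       refs = calibration_refs(),
                       write_volumes = TRUE) {
  stopifnot(inherits(phantom, "phantom_config"), n_subjects >= 1)
  structure(
    list(out_dir = out_dir, phantom = phantom,
         n_subjects = as.integer(n_subjects), protocol = protocol,
         lookup_step = lookup_step, contrast = contrast, refs = refs,
         write_volumes = isTRUE(write_volumes)),
    class = "run_config"
  )
}

#' Simulate the calibrated T1w/T2w ratio inputs for one subject
#'
#' Synthesises the two contrasts from the phantom's quantitative maps,
#' applies the subject's ratio-specific non-myelin modulation to the
#' T1-weighted image and the per-contrast receive gains, and adds
#' measurement noise.
#'
#' @param phantom an [build_phantom()] phantom.
#' @param contrast list with `t1w` and `t2w` vectors `c(TR, TE)` in seconds.
#' @param noise_sigma additive noise as a fraction of mean signal.
#' @return List with raw arrays `t1w`, `t2w`.
#' @export
simulate_contrast_pair <- function(phantom, contrast = list(t1w = c(TR = 0.5, TE = 0.01),
                                                            t2w = c(TR = 4.5, TE = 0.1)),
                                   noise_sigma = phantom$config$noise_sigma) {
  q <- phantom$quantitative
  t1w <- synthesize_contrast(q, contrast$t1w[["TR"]], contrast$t1w[["TE"]]) *
    phantom$t1w_modulation * phantom$contrast_gains[["t1w"]]
  t2w <- synthesize_contrast(q, contrast$t2w[["TR"]], contrast$t2w[["TE"]]) *
    phantom$contrast_gains[["t2w"]]
  if (noise_sigma > 0) {
    nz <- with_local_seed(phantom$config$seed + 3000003L,
                          list(rnorm(length(t1w)), rnorm(length(t2w))))
    t1w <- t1w + noise_sigma * mean(t1w) * array(nz[[1]], dim(t1w))
    t2w <- t2w + noise_sigma * mean(t2w) * array(nz[[2]], dim(t2w))
  }
  list(t1w = t1w, t2w = t2w)
}

.stage <- function(stage, subject, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed for subject %s: %s",
                 stage, subject, conditionMessage(e)), call. = FALSE)
  })
}

#' Process one subject: all three metric maps plus the ROI table
#'
#' @param config a [run_config()].
#' @param subject subject index (1-based).
#' @param grid a prebuilt [build_lookup()] grid.
#' @return List with the subject's `roi_table` and metric maps.
#' @export
process_subject <- function(config, subject, grid) {
  sid <- sprintf("s%02d", subject)
  pc <- config$phantom
  pc$seed <- pc$seed + subject
  pc$anatomy_seed <- config$phantom$seed
  phantom <- .stage("phantom", sid, build_phantom(pc))

  triplet <- .stage("flash", sid, simulate_flash_triplet(phantom, config$protocol))
  mt <- .stage("mtsat", sid, suppressMessages(mtsat_pipeline(triplet)))
  mvf <- .stage("mvf-symri", sid,
                estimate_mvf(phantom$quantitative, grid))

  pair <- .stage("contrast", sid, simulate_contrast_pair(phantom, config$contrast))
  n_tissue <- sum(phantom$roi_info$tissue_class %in% .TISSUE_CLASSES)
  eye <- phantom$label_map == (n_tissue + 1L)
  muscle <- phantom$label_map == (n_tissue + 2L)
  ratio <- .stage("t1wt2w", sid, {
    t1w_cal <- calibrate_image(
      pair$t1w,
      c(eye = roi_mode(pair$t1w, eye), muscle = roi_mode(pair$t1w, muscle)),
      config$refs$t1w
    )
    t2w_cal <- calibrate_image(
      pair$t2w,
      c(eye = roi_mode(pair$t2w, eye), muscle = roi_mode(pair$t2w, muscle)),
      config$refs$t2w
    )
    ratio_map(t1w_cal, t2w_cal)
  })

  maps <- list(
    mvf_symri = mvf * 100,      # percent
    mtsat = mt$mtsat * 100,     # percent units
    t1w_t2w_ratio = ratio
  )
  tab <- .stage("extract", sid, {
    suppressMessages(bind_roi_tables(
      !!!purrr::imap(maps, function(m, nm) {
        extract_means(m, phantom$label_map, phantom$roi_info,
                      phantom$partial_volume, metric_name = nm,
                      subject_id = sid)
      })
    ))
  })
  list(roi_table = tab, maps = maps, phantom = phantom)
}

#' Run the complete pipeline
#'
#' Simulates `n_subjects` phantoms (subject s seeded at base seed + s, with
#' the shared anatomy seed fixing ROI geometry), computes the three metric
#' maps per subject, pools the ROI table, calibrates the MT-saturation and
#' ratio metrics to the relaxometry myelin fraction by white-matter means,
#' runs the comparison statistics, and writes the report plus a manifest
#' recording seed, configuration hash and package version. Identical
#' configurations give byte-identical reports.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the `comparison_report`, the pooled
#'   `roi_table` and the output paths.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$n_subjects < 2) {
    stop("statistics stage requires n_subjects >= 2; reduce scope or add subjects",
         call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- build_lookup(config$phantom$params, config$lookup_step)

  tabs <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    res <- process_subject(config, s, grid)
    tabs[[s]] <- res$roi_table
    if (config$write_volumes) {
      sdir <- file.path(config$out_dir, sprintf("sub-%02d", s))
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      for (nm in names(res$maps)) {
        RNifti::writeNifti(res$maps[[nm]],
                           file.path(sdir, paste0(nm, ".nii.gz")),
                           datatype = "double")
      }
    }
  }
  roi_table <- dplyr::bind_rows(tabs)
  class(roi_table) <- c("roi_table", class(roi_table))
  table_path <- file.path(config$out_dir, "roi_table.csv")
  # serialise means at full precision so a compare-stage re-run from the CSV
  # reproduces the report bit for bit
  on_disk <- dplyr::mutate(roi_table,
                           mean_value = sprintf("%.17g", .data$mean_value))
  readr::write_csv(on_disk, table_path)

  report <- .stage("compare", "pooled", compare_metrics(roi_table))
  report_paths <- build_report(report, file.path(config$out_dir, "report"),
                               seed = config$phantom$seed)

  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  manifest <- list(
    package = "myelinmetrics",
    version = as.character(utils::packageVersion("myelinmetrics")),
    seed = config$phantom$seed,
    n_subjects = config$n_subjects,
    config_hash = rlang::hash(cfg_for_hash)
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(report = report, roi_table = roi_table,
                 paths = c(roi_table = table_path, manifest = manifest_path,
                           report_paths)))
}
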