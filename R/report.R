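# Assembly of the comparison report: white-matter calibration, per-class
# summary with contrast percentages, correlation matrices with confidence
# intervals and equality tests, per-ROI correlations, and regression/ANCOVA
# tables.

.MVF_METRICS <- c("mvf_mtsat", "mvf_symri", "mvf_t1wt2w")
.REGION_SETS <- c("wm", "subcortical_gm", "cortical_gm", "all")

# wide (subject x roi) x metric layout used by the correlation stages
.wide_metrics <- function(table, metrics) {
  table |>
    dplyr::filter(.data$metric_name %in% metrics) |>
    dplyr::select("subject_id", "roi_id", "roi_name", "tissue_class",
                  "metric_name", "mean_value") |>
    tidyr::pivot_wider(names_from = "metric_name", values_from = "mean_value")
}

.region_rows <- function(wide, region) {
  if (region == "all") wide else dplyr::filter(wide, .data$tissue_class == region)
}

#' Run the full cross-metric comparison on a pooled ROI table
#'
#' Calibrates the MT-saturation index and the T1w/T2w ratio to the
#' relaxometry myelin volume fraction by white-matter means, then computes
#' the per-class summary (means, SDs, grey-to-white contrast percentages and
#' their Steel-Dwass comparison), the pooled Spearman correlation matrix with
#' Fisher confidence intervals and correlation-equality Z tests per region,
#' the per-ROI correlations, and the regression/ANCOVA comparison of the two
#' calibrated metrics against the MT-based one.
#'
#' @param table a pooled `roi_table` (or a path to a CSV written by
#'   [run_all()]) holding the raw metrics `mvf_symri` (percent), `mtsat`
#'   (p.u.) and `t1w_t2w_ratio` for every subject.
#' @param reference metric name supplying the myelin scale.
#' @return Object of class `comparison_report`: tibbles `scaling`, `table1`,
#'   `contrast_tests`, `table2`, `table2_ztests`, `table3`, `table4`,
#'   `table4_ancova`, plus the calibrated `roi_table`.
#' @export
compare_metrics <- function(table, reference = "mvf_symri") {
  if (is.character(table)) {
    # base strtod parsing round-trips the full-precision CSV exactly
    table <- tibble::as_tibble(utils::read.csv(table))
    class(table) <- c("roi_table", class(table))
  }
  n_subjects <- dplyr::n_distinct(table$subject_id)
  if (n_subjects < 2) {
    stop("statistics stage requires at least 2 subjects; got ", n_subjects,
         call. = FALSE)
  }

  sf_mt <- scaling_factor(table, "mtsat", reference)
  sf_rt <- scaling_factor(table, "t1w_t2w_ratio", reference)
  table <- apply_scaling(table, sf_mt, "mvf_mtsat")
  table <- apply_scaling(table, sf_rt, "mvf_t1wt2w")
  scaling <- dplyr::bind_rows(sf_mt, sf_rt)

  # ---- per-class summary and grey/white contrast (Table 1 analogue)
  metric_order <- c("mvf_mtsat", "mtsat", "mvf_symri", "mvf_t1wt2w", "t1w_t2w_ratio")
  summ <- table |>
    dplyr::filter(.data$metric_name %in% metric_order) |>
    dplyr::group_by(.data$metric_name, .data$tissue_class) |>
    dplyr::summarise(mean = mean(.data$mean_value), sd = sd(.data$mean_value),
                     .groups = "drop")
  table1 <- summ |>
    tidyr::pivot_wider(names_from = "tissue_class",
                       values_from = c("mean", "sd")) |>
    dplyr::mutate(
      contrast_subcortical_pct = ifelse(
        .data$metric_name %in% .MVF_METRICS,
        100 * .data$mean_subcortical_gm / .data$mean_wm, NA_real_),
      contrast_cortical_pct = ifelse(
        .data$metric_name %in% .MVF_METRICS,
        100 * .data$mean_cortical_gm / .data$mean_wm, NA_real_)
    ) |>
    dplyr::arrange(match(.data$metric_name, metric_order))

  # Steel-Dwass on per-subject contrast values across the three MVF metrics
  per_subject_contrast <- table |>
    dplyr::filter(.data$metric_name %in% .MVF_METRICS) |>
    dplyr::group_by(.data$subject_id, .data$metric_name, .data$tissue_class) |>
    dplyr::summarise(m = mean(.data$mean_value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "tissue_class", values_from = "m") |>
    dplyr::mutate(
      subcortical_gm_pct = 100 * .data$subcortical_gm / .data$wm,
      cortical_gm_pct = 100 * .data$cortical_gm / .data$wm
    )
  contrast_tests <- purrr::map_dfr(
    c("subcortical_gm_pct", "cortical_gm_pct"),
    function(col) {
      groups <- split(per_subject_contrast[[col]],
                      per_subject_contrast$metric_name)
      steel_dwass(groups) |>
        dplyr::mutate(contrast = sub("_pct$", "", col), .before = 1)
    }
  )

  # ---- pooled correlations per region (Table 2 analogue)
  wide <- .wide_metrics(table, .MVF_METRICS)
  pair_defs <- list(
    c("mvf_mtsat", "mvf_symri"),
    c("mvf_mtsat", "mvf_t1wt2w"),
    c("mvf_symri", "mvf_t1wt2w")
  )
  table2 <- purrr::map_dfr(.REGION_SETS, function(region) {
    dat <- .region_rows(wide, region)
    purrr::map_dfr(pair_defs, function(pr) {
      res <- spearman_ci(dat[[pr[1]]], dat[[pr[2]]])
      dplyr::mutate(res, region = region, metric_a = pr[1], metric_b = pr[2],
                    .before = 1)
    })
  })

  table2_ztests <- purrr::map_dfr(.REGION_SETS, function(region) {
    rows <- dplyr::filter(table2, .data$region == !!region)
    cmb <- utils::combn(nrow(rows), 2)
    purrr::map_dfr(seq_len(ncol(cmb)), function(j) {
      a <- rows[cmb[1, j], ]; b <- rows[cmb[2, j], ]
      zt <- compare_correlations(a$rho, a$n, b$rho, b$n)
      tibble::tibble(
        region = region,
        pair_a = paste(a$metric_a, a$metric_b, sep = " vs "),
        pair_b = paste(b$metric_a, b$metric_b, sep = " vs "),
        z = zt$z, p_value = zt$p_value
      )
    })
  })

  # ---- per-ROI correlations and means (Table 3 analogue)
  table3 <- wide |>
    dplyr::group_by(.data$roi_id, .data$roi_name, .data$tissue_class) |>
    dplyr::group_modify(function(d, key) {
      cors <- purrr::map_dfr(pair_defs, function(pr) {
        if (sum(is.finite(d[[pr[1]]]) & is.finite(d[[pr[2]]])) < 4) {
          return(tibble::tibble(pair = paste(pr, collapse = "_vs_"),
                                rho = NA_real_, ci_low = NA_real_,
                                ci_high = NA_real_, p_value = NA_real_))
        }
        r <- spearman_ci(d[[pr[1]]], d[[pr[2]]])
        tibble::tibble(pair = paste(pr, collapse = "_vs_"), rho = r$rho,
                       ci_low = r$ci_low, ci_high = r$ci_high,
                       p_value = r$p_value)
      }) |>
        tidyr::pivot_wider(names_from = "pair",
                           values_from = c("rho", "ci_low", "ci_high", "p_value"))
      means <- purrr::map_dfc(.MVF_METRICS, function(mm) {
        tibble::tibble(!!paste0("mean_", mm) := mean(d[[mm]]),
                       !!paste0("sd_", mm) := sd(d[[mm]]))
      })
      dplyr::bind_cols(cors, means)
    }) |>
    dplyr::ungroup()

  # ---- regression of the calibrated metrics on the MT-based one (Table 4)
  table4 <- purrr::map_dfr(.REGION_SETS, function(region) {
    dat <- .region_rows(wide, region)
    purrr::map_dfr(c("mvf_symri", "mvf_t1wt2w"), function(resp) {
      ln <- fit_line(dat$mvf_mtsat, dat[[resp]])
      td <- tidy(ln)
      tibble::tibble(
        region = region, response = resp, predictor = "mvf_mtsat",
        intercept = td$estimate[1], intercept_se = td$std.error[1],
        slope = td$estimate[2], slope_se = td$std.error[2], n = ln$n
      )
    })
  })
  table4_ancova <- purrr::map_dfr(.REGION_SETS, function(region) {
    dat <- .region_rows(wide, region)
    res <- ancova_compare(
      data.frame(x = dat$mvf_mtsat, y = dat$mvf_symri),
      data.frame(x = dat$mvf_mtsat, y = dat$mvf_t1wt2w)
    )
    dplyr::mutate(res, region = region, .before = 1)
  })

  structure(
    list(scaling = scaling, table1 = table1, contrast_tests = contrast_tests,
         table2 = table2, table2_ztests = table2_ztests, table3 = table3,
         table4 = table4, table4_ancova = table4_ancova, roi_table = table),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat(sprintf("  scaling factors: %s\n",
              paste(sprintf("%s = %.4g", x$scaling$metric_name, x$scaling$factor),
                    collapse = ", ")))
  wm <- dplyr::filter(x$table2, .data$region == "wm")
  cat("  white-matter Spearman rho:\n")
  for (i in seq_len(nrow(wm))) {
    cat(sprintf("    %s vs %s: %.2f [%.2f-%.2f] (%s)\n", wm$metric_a[i],
                wm$metric_b[i], wm$rho[i], wm$ci_low[i], wm$ci_high[i],
                wm$strength[i]))
  }
  invisible(x)
}

.round_df <- function(df, digits) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), ~ round(.x, digits)))
}

.md_table <- function(df, digits = 2) {
  df <- .round_df(df, digits)
  cols <- names(df)
  fmt <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  if (nrow(df) == 1) fmt <- matrix(fmt, nrow = 1)
  lines <- c(
    paste0("| ", paste(cols, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|"),
    apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  )
  paste(lines, collapse = "\n")
}

#' Write the comparison report to disk
#'
#' Emits each table as CSV (full precision) and a joint Markdown summary with
#' values rounded to two decimals, the rounding the report tables use.
#' Re-running on identical input reproduces byte-identical files.
#'
#' @param report a `comparison_report` from [compare_metrics()].
#' @param out_dir output directory, created if needed.
#' @param seed optional seed recorded in the report header.
#' @return Invisibly, the paths written.
#' @export
build_report <- function(report, out_dir, seed = NULL) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("scaling", "table1", "contrast_tests", "table2", "table2_ztests",
            "table3", "table4", "table4_ancova")
  paths <- character(0)
  for (nm in tabs) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(report[[nm]], p)
    paths <- c(paths, p)
  }
  md <- c(
    "# Cross-metric myelin comparison report",
    if (!is.null(seed)) sprintf("seed: %d", seed),
    "",
    "## Calibration scaling factors", .md_table(report$scaling, 4), "",
    "## Per-class means and grey/white contrast", .md_table(report$table1), "",
    "## Contrast comparison (Steel-Dwass)", .md_table(report$contrast_tests, 4), "",
    "## Pooled Spearman correlations", .md_table(report$table2), "",
    "## Correlation-equality Z tests", .md_table(report$table2_ztests, 4), "",
    "## Regression on the MT-based metric", .md_table(report$table4, 3), "",
    "## ANCOVA line comparison", .md_table(report$table4_ancova, 4), ""
  )
  md_path <- file.path(out_dir, "report.md")
  writeLines(md, md_path)
  invisible(c(paths, md_path))
}
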