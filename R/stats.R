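# Cross-metric calibration and the comparison statistics: scaling factors,
# contrast percentages, Spearman correlations with Fisher confidence
# intervals, correlation-equality Z tests, Steel-Dwass all-pairs contrasts,
# simple regression, and ANCOVA line comparison.

#' White-matter-mean scaling factor between two metrics
#'
#' Zero-intercept calibration: the factor is the ratio of the reference
#' metric's mean over all white-matter ROI means (pooled across subjects) to
#' the target metric's. Multiplying the target metric by the factor makes the
#' two white-matter means equal to machine precision.
#'
#' @param table a `roi_table` from [extract_means()] / [bind_roi_tables()].
#' @param target metric name to be calibrated.
#' @param reference metric name supplying the scale.
#' @return One-row tibble: metric_name, reference_metric, factor, n_rois.
#' @export
scaling_factor <- function(table, target, reference) {
  wm <- dplyr::filter(table, .data$tissue_class == "wm",
                      .data$metric_name %in% c(target, reference))
  if (identical(target, reference)) {
    n <- sum(wm$metric_name == target)
    if (n == 0) stop("metric absent from white-matter ROIs", call. = FALSE)
    return(tibble::tibble(metric_name = target, reference_metric = reference,
                          factor = 1, n_rois = n))
  }
  means <- wm |>
    dplyr::group_by(.data$metric_name) |>
    dplyr::summarise(m = mean(.data$mean_value), n = dplyr::n(), .groups = "drop")
  if (nrow(means) != 2) {
    stop("both metrics must be present for white-matter ROIs", call. = FALSE)
  }
  m_ref <- means$m[means$metric_name == reference]
  m_tgt <- means$m[means$metric_name == target]
  if (!is.finite(m_tgt) || m_tgt <= 0) {
    stop("target metric white-matter mean must be positive", call. = FALSE)
  }
  tibble::tibble(
    metric_name = target, reference_metric = reference,
    factor = m_ref / m_tgt, n_rois = means$n[means$metric_name == target]
  )
}

#' Apply a scaling factor to a metric, producing a calibrated metric
#'
#' @param table a `roi_table`.
#' @param sf one-row tibble from [scaling_factor()].
#' @param new_name metric name for the calibrated records.
#' @return The input table with the calibrated records appended.
#' @export
apply_scaling <- function(table, sf, new_name) {
  cal <- table |>
    dplyr::filter(.data$metric_name == sf$metric_name[1]) |>
    dplyr::mutate(mean_value = .data$mean_value * sf$factor[1],
                  metric_name = new_name)
  bind_roi_tables(table, cal)
}

#' Grey-to-white contrast percentage of a metric
#'
#' `100 * mean(GM-class ROI means) / mean(WM ROI means)`, means pooled over
#' subjects and ROIs.
#'
#' @param table a `roi_table`.
#' @param metric metric name.
#' @param gm_class `"subcortical_gm"` or `"cortical_gm"`.
#' @return A single percentage.
#' @export
contrast_percent <- function(table, metric, gm_class) {
  gm_class <- match.arg(gm_class, c("subcortical_gm", "cortical_gm"))
  dat <- dplyr::filter(table, .data$metric_name == metric)
  m_wm <- mean(dat$mean_value[dat$tissue_class == "wm"])
  m_gm <- mean(dat$mean_value[dat$tissue_class == gm_class])
  100 * m_gm / m_wm
}

#' Spearman correlation with a Fisher-transform confidence interval
#'
#' Rank correlation with average ranks for ties; the confidence interval is
#' `tanh(atanh(rho) +/- z * SE)`. The default standard error is the plain
#' Fisher `1/sqrt(n - 3)`; for Spearman's rho this interval is mildly
#' anticonservative (the rank statistic's Fisher-z variance is about
#' 1.06/(n - 3)), so the Bonett-Wright standard error
#' `sqrt((1 + rho^2/2)/(n - 3))`, which restores nominal coverage, is
#' available as `ci_method = "bonett"`.
#'
#' @param x,y paired observations (>= 4 complete pairs).
#' @param conf_level confidence level, default 0.95.
#' @param ci_method `"fisher"` (plain Fisher standard error) or `"bonett"`.
#' @return One-row tibble: rho, ci_low, ci_high, n, p_value, strength.
#' @export
spearman_ci <- function(x, y, conf_level = 0.95,
                        ci_method = c("fisher", "bonett")) {
  ci_method <- match.arg(ci_method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  rho <- cor(x, y, method = "spearman")
  p <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE)$p.value)
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (abs(rho) >= 1) {
    ci <- c(rho, rho)
  } else {
    se <- switch(ci_method,
                 fisher = 1 / sqrt(n - 3),
                 bonett = sqrt((1 + rho^2 / 2) / (n - 3)))
    ci <- tanh(atanh(rho) + c(-1, 1) * z * se)
  }
  tibble::tibble(rho = rho, ci_low = ci[1], ci_high = ci[2], n = n,
                 p_value = p, strength = classify_rho(rho))
}

#' Fisher-transform confidence interval for a correlation coefficient
#'
#' `tanh(atanh(rho) +/- z * 1/sqrt(n - 3))`; the interval [spearman_ci()]
#' attaches to a computed coefficient, exposed directly so printed
#' coefficients can be turned into intervals.
#'
#' @param rho correlation coefficient (|rho| < 1).
#' @param n number of paired observations (> 3).
#' @param conf_level confidence level, default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @export
fisher_ci <- function(rho, n, conf_level = 0.95) {
  stopifnot(abs(rho) < 1, n > 3)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tanh(atanh(rho) + c(-1, 1) * z / sqrt(n - 3))
}

#' Reference per-class means of the myelin metrics
#'
#' Published adult-brain class means (and SDs) of the five metrics after
#' white-matter calibration, the profile the phantom generator's defaults
#' emulate: calibrated metrics in MVF percent, the raw MT-saturation index
#' in percent units and the raw T1w/T2w ratio dimensionless.
#'
#' @return Tibble with metric_name, tissue_class, mean, sd.
#' @export
reference_class_means <- function() {
  tibble::tibble(
    metric_name = rep(c("mvf_mtsat", "mtsat", "mvf_symri", "mvf_t1wt2w",
                        "t1w_t2w_ratio"), each = 3),
    tissue_class = rep(c("wm", "subcortical_gm", "cortical_gm"), times = 5),
    mean = c(30.70, 20.55, 16.18,
             3.66, 2.45, 1.93,
             30.70, 17.38, 10.57,
             30.70, 27.11, 21.17,
             2.11, 1.86, 1.46),
    sd = c(4.22, 2.40, 3.98,
           0.50, 0.29, 0.47,
           4.81, 4.11, 6.07,
           4.03, 5.27, 4.15,
           0.28, 0.36, 0.29)
  )
}

#' Strength label of a correlation coefficient
#'
#' `|rho|` binned at 0.30 / 0.50 / 0.70 / 0.90 into very weak, weak,
#' moderate, strong, very strong; a boundary value belongs to the upper
#' class.
#'
#' @param rho correlation coefficient(s).
#' @return Character vector of labels.
#' @export
classify_rho <- function(rho) {
  labs <- c("very weak", "weak", "moderate", "strong", "very strong")
  labs[findInterval(abs(rho), c(0.30, 0.50, 0.70, 0.90)) + 1L]
}

#' Z test for the equality of two correlations
#'
#' Fisher r-to-z transform of each coefficient, treated as independent:
#' `Z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided p
#' from the standard normal. When the two correlations share a variable (as
#' the cross-metric comparisons do), `dependent = TRUE` applies Steiger's
#' modification for overlapping correlations, which needs the correlation
#' `r_xy` between the two non-shared variables.
#'
#' @param r1,r2 correlation coefficients (|r| < 1).
#' @param n1,n2 sample sizes (> 3); for the dependent variant a single
#'   common n is used.
#' @param dependent account for a shared variable.
#' @param r_xy correlation between the non-shared variables (dependent case).
#' @return One-row tibble: z, p_value.
#' @export
compare_correlations <- function(r1, n1, r2, n2, dependent = FALSE, r_xy = NULL) {
  stopifnot(abs(r1) <= 1, abs(r2) <= 1, n1 > 3, n2 > 3)
  # a sample coefficient of exactly +/-1 has an unbounded transform; clamp
  # just inside the open interval so the statistic stays finite
  clamp <- function(r) sign(r) * pmin(abs(r), 1 - 1e-15)
  z1 <- atanh(clamp(r1)); z2 <- atanh(clamp(r2))
  if (!dependent) {
    z <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  } else {
    if (is.null(r_xy)) stop("dependent test needs r_xy", call. = FALSE)
    n <- min(n1, n2)
    rbar <- (r1 + r2) / 2
    # Steiger (1980) Z* for correlations sharing one variable
    psi <- r_xy * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_xy^2)
    cov <- psi / (1 - rbar^2)^2
    z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - cov)))
  }
  tibble::tibble(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For every pair of groups the two samples are jointly ranked and the
#' standardised rank-sum statistic computed (average ranks and a tie-corrected
#' variance). Simultaneous p values come either from the studentised-range
#' distribution over k groups (large samples) or from exhaustive enumeration
#' of all group assignments, taking each arrangement's maximum absolute
#' statistic as the reference distribution (small samples). `method = "auto"`
#' enumerates exactly whenever the arrangement count is at most
#' `max_arrangements`.
#'
#' @param groups list of numeric vectors (k >= 2 groups, each n >= 2).
#' @param method `"auto"`, `"asymptotic"` or `"exact"`.
#' @param max_arrangements feasibility cap for exact enumeration.
#' @return Tibble with one row per pair: group1, group2, statistic (the
#'   standardised pairwise rank-sum z), p_adj, method.
#' @export
steel_dwass <- function(groups, method = c("auto", "asymptotic", "exact"),
                        max_arrangements = 2e6) {
  method <- match.arg(method)
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2)) stop("every group needs n >= 2", call. = FALSE)
  nm <- names(groups) %||% paste0("g", seq_len(k))

  pair_z <- function(a, b) {
    pooled <- c(a, b)
    n <- length(pooled)
    r <- rank(pooled)
    W <- sum(r[seq_along(a)])
    E <- length(a) * (n + 1) / 2
    tt <- table(pooled)
    tie <- sum(tt^3 - tt) / (n * (n - 1))
    V <- length(a) * length(b) / 12 * (n + 1 - tie)
    if (V <= 0) 0 else (W - E) / sqrt(V)
  }

  pairs <- utils::combn(k, 2)
  zs <- apply(pairs, 2, function(ij) pair_z(groups[[ij[1]]], groups[[ij[2]]]))

  n_arr <- exp(lgamma(sum(lengths(groups)) + 1) - sum(lgamma(lengths(groups) + 1)))
  use_exact <- switch(method,
    exact = TRUE,
    asymptotic = FALSE,
    auto = n_arr <= max_arrangements
  )
  if (use_exact && n_arr > max_arrangements) {
    stop(sprintf("exact enumeration infeasible: %.3g arrangements", n_arr),
         call. = FALSE)
  }

  if (use_exact) {
    pooled <- sort(unlist(groups, use.names = FALSE))
    p_adj <- steel_dwass_exact_cpp(pooled, lengths(groups), abs(zs))
    meth <- "exact"
  } else {
    p_adj <- 1 - ptukey(sqrt(2) * abs(zs), nmeans = k, df = Inf)
    meth <- "asymptotic"
  }
  tibble::tibble(
    group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
    statistic = zs, p_adj = pmin(pmax(p_adj, 0), 1), method = meth
  )
}

#' Simple linear regression of one metric on another
#'
#' Ordinary least squares with intercept; standard errors from the residual
#' variance. A degenerate predictor (no variance) is rejected.
#'
#' @param x predictor values.
#' @param y response values.
#' @return Object of class `mvf_line` wrapping the fit; see
#'   [tidy.mvf_line()] and [glance.mvf_line()].
#' @export
fit_line <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (var(x) == 0) stop("constant predictor: slope undefined", call. = FALSE)
  fit <- lm(y ~ x)
  structure(list(fit = fit, n = length(x)), class = "mvf_line")
}

#' @export
print.mvf_line <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  cat(sprintf("<mvf_line> intercept %.4g +/- %.3g, slope %.4g +/- %.3g (n = %d)\n",
              co[1, 1], co[1, 2], co[2, 1], co[2, 2], x$n))
  invisible(x)
}

#' Tidy a fitted regression line
#'
#' @param x an `mvf_line` object.
#' @param ... unused.
#' @return Tibble with term, estimate, std.error, statistic, p.value.
#' @export
tidy.mvf_line <- function(x, ...) {
  co <- unname(summary(x$fit)$coefficients)
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = co[, 1], std.error = co[, 2],
    statistic = co[, 3], p.value = co[, 4]
  )
}

#' One-row summary of a fitted regression line
#'
#' @param x an `mvf_line` object.
#' @param ... unused.
#' @return Tibble with r.squared, sigma, nobs.
#' @export
glance.mvf_line <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma, nobs = x$n)
}

#' Compare two regression lines by analysis of covariance
#'
#' Tests slope equality with the interaction F test of the combined model
#' `y ~ x * group`; if the slopes do not differ, the intercept difference is
#' tested in the common-slope model `y ~ x + group`. Perfectly coincident
#' datasets (zero incremental sum of squares on zero residual) are reported
#' as p = 1 rather than 0/0.
#'
#' @param data_a,data_b data frames with columns `x` and `y`.
#' @return Tibble with rows `slope` and `intercept`: estimate (the group
#'   difference), statistic (F), p_value.
#' @export
ancova_compare <- function(data_a, data_b) {
  stopifnot(all(c("x", "y") %in% names(data_a)), all(c("x", "y") %in% names(data_b)))
  df <- dplyr::bind_rows(
    dplyr::mutate(data_a[c("x", "y")], group = "a"),
    dplyr::mutate(data_b[c("x", "y")], group = "b")
  )
  df$group <- factor(df$group)
  m_add <- lm(y ~ x + group, data = df)
  m_int <- lm(y ~ x * group, data = df)
  an <- anova(m_add, m_int)
  rss_int <- an$RSS[2]; dss <- an$`Sum of Sq`[2]
  slope_diff <- coef(m_int)[["x:groupb"]]
  if (!is.finite(an$F[2])) {
    # coincident fits: no slope difference detectable
    p_slope <- if (abs(dss) < 1e-12) 1 else 0
    f_slope <- 0
  } else {
    p_slope <- an$`Pr(>F)`[2]
    f_slope <- an$F[2]
  }
  co_add <- summary(m_add)$coefficients
  int_diff <- co_add["groupb", 1]
  t_int <- co_add["groupb", 3]
  p_int <- co_add["groupb", 4]
  if (!is.finite(t_int)) { t_int <- 0; p_int <- if (abs(int_diff) < 1e-12) 1 else 0 }
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(slope_diff, int_diff),
    statistic = c(f_slope, t_int^2),
    p_value = c(p_slope, p_int)
  )
}
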