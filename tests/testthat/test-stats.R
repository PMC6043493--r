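# Calibration arithmetic and the comparison statistics.

ref_table <- function() {
  # roi_table shaped from the bundled reference class means
  refs <- reference_class_means()
  tibble::tibble(
    subject_id = "ref", roi_id = seq_len(nrow(refs)),
    roi_name = paste0(refs$tissue_class, "_ref"),
    tissue_class = refs$tissue_class, metric_name = refs$metric_name,
    mean_value = refs$mean, voxel_count = 1L
  )
}

test_that("white-matter scaling factors reproduce the published calibration", {
  tab <- ref_table()
  f_ratio <- scaling_factor(tab, "t1w_t2w_ratio", "mvf_symri")
  expect_equal(f_ratio$factor, 30.70 / 2.11, tolerance = 1e-12)
  expect_equal(round(f_ratio$factor, 1), 14.5)
  f_mt <- scaling_factor(tab, "mtsat", "mvf_symri")
  expect_equal(f_mt$factor, 30.70 / 3.66, tolerance = 1e-12)
  # 8.388 from the printed means; rounding of unrounded subject means explains 8.40
  expect_lt(abs(f_mt$factor - 8.40), 0.02)
  ident <- scaling_factor(tab, "mvf_symri", "mvf_symri")
  expect_equal(ident$factor, 1)
  # applying a factor equalises white-matter means to machine precision
  tab2 <- apply_scaling(tab, f_ratio, "mvf_t1wt2w_cal")
  wm <- function(m) mean(tab2$mean_value[tab2$metric_name == m &
                                           tab2$tissue_class == "wm"])
  expect_equal(wm("mvf_t1wt2w_cal"), wm("mvf_symri"), tolerance = 1e-12)
})

test_that("grey-to-white contrast percentages recompute from the reference means", {
  tab <- ref_table()
  expect_equal(contrast_percent(tab, "mvf_mtsat", "subcortical_gm"), 66.94,
               tolerance = 1e-4)
  expect_equal(contrast_percent(tab, "mvf_symri", "cortical_gm"), 34.43,
               tolerance = 1e-4)
  even <- dplyr::mutate(tab, mean_value = 1)
  expect_equal(contrast_percent(even, "mvf_symri", "subcortical_gm"), 100)
})

test_that("Spearman correlation matches a brute-force rank oracle and handles monotone data", {
  mono <- spearman_ci(1:10, (1:10)^3)
  expect_equal(mono$rho, 1)
  expect_lt(mono$p_value, 1e-6)
  x <- c(3.1, 0.2, 5.5, 2.2, 4.9, 1.0)
  y <- c(2.0, 1.1, 4.0, 4.2, 3.3, 0.5)
  expect_equal(spearman_ci(x, y)$rho, oracle_spearman(x, y), tolerance = 1e-12)
  expect_error(spearman_ci(1:3, 3:1), "at least 4")
})

test_that("Fisher intervals at n = 960 reproduce the published bounds", {
  expect_equal(round(fisher_ci(0.72, 960), 2), c(0.69, 0.75))
  expect_equal(round(fisher_ci(0.45, 960), 2), c(0.40, 0.50))
})

test_that("interval coverage at rho 0.7, n 100 behaves as documented", {
  set.seed(2024)
  rho_s <- 0.7
  r_pearson <- 2 * sin(pi * rho_s / 6)  # bivariate normal giving Spearman 0.7
  n <- 100
  hits <- vapply(seq_len(1000), function(i) {
    x <- rnorm(n)
    y <- r_pearson * x + sqrt(1 - r_pearson^2) * rnorm(n)
    fi <- spearman_ci(x, y)
    bo <- spearman_ci(x, y, ci_method = "bonett")
    c(fisher = fi$ci_low <= rho_s && rho_s <= fi$ci_high,
      bonett = bo$ci_low <= rho_s && rho_s <= bo$ci_high)
  }, logical(2))
  cov <- rowMeans(hits)
  # the variance-matched interval is nominal; the plain Fisher interval runs
  # a documented ~1.5 points anticonservative for the rank coefficient
  expect_gt(cov[["bonett"]], 0.93)
  expect_lt(cov[["bonett"]], 0.97)
  expect_gt(cov[["fisher"]], 0.91)
  expect_lte(cov[["fisher"]], cov[["bonett"]])
})

test_that("correlation is invariant under strictly monotone transforms", {
  set.seed(8)
  x <- rnorm(60); y <- 0.6 * x + rnorm(60)
  base <- spearman_ci(x, y)$rho
  expect_equal(spearman_ci(exp(x), y)$rho, base)
  expect_equal(spearman_ci(x, 3 * y + 10)$rho, base)
  expect_equal(spearman_ci(x, y^3)$rho, base)
})

test_that("correlation strength labels use upper-inclusive boundaries", {
  expect_equal(classify_rho(0.72), "strong")
  expect_equal(classify_rho(0.45), "weak")
  expect_equal(classify_rho(c(0.90, 0.70, 0.50, 0.30, 0.1, -0.8)),
               c("very strong", "strong", "moderate", "weak", "very weak", "strong"))
})

test_that("correlation-equality Z test matches direct evaluation and is antisymmetric", {
  eq <- compare_correlations(0.5, 100, 0.5, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  zt <- compare_correlations(0.72, 960, 0.45, 960)
  expect_equal(zt$z, (atanh(0.72) - atanh(0.45)) / sqrt(2 / 957), tolerance = 1e-12)
  expect_equal(zt$z, 9.25, tolerance = 0.01)
  expect_lt(zt$p_value, 0.001)
  sw <- compare_correlations(0.45, 960, 0.72, 960)
  expect_equal(sw$z, -zt$z)
  expect_equal(sw$p_value, zt$p_value)
})

test_that("Steel-Dwass exact path agrees with an independent permutation oracle", {
  fixtures <- list(
    list(c(1, 2, 3), c(101, 102, 103), c(201, 202, 203)),
    list(c(1.2, 3.4, 2.2, 4.1), c(3.0, 5.5, 4.4, 6.1)),
    list(c(5, 8, 2, 9, 4), c(7, 3, 6, 10, 1)),
    list(c(1, 5, 3), c(2, 6, 4), c(10, 12, 11))
  )
  for (g in fixtures) {
    res <- steel_dwass(g)
    expect_equal(res$method, rep("exact", nrow(res)))
    expect_equal(res$p_adj, oracle_steel_dwass(g), tolerance = 1e-9)
  }
  # the well-separated three-group fixture: all pairs clearly low, and ordered
  # consistently with the asymptotic path
  sep <- fixtures[[1]]
  ex <- steel_dwass(sep, method = "exact")
  as <- steel_dwass(sep, method = "asymptotic")
  expect_true(all(ex$p_adj < 0.3))
  expect_equal(order(ex$p_adj), order(as$p_adj))
})

test_that("identical groups give adjusted p of 1", {
  res <- steel_dwass(list(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(res$p_adj, 1, tolerance = 1e-9)
})

test_that("large samples switch to the studentised-range approximation", {
  set.seed(5)
  g <- list(rnorm(40), rnorm(40) + 1, rnorm(40) + 2)
  res <- steel_dwass(g)
  expect_equal(unique(res$method), "asymptotic")
  expect_true(all(res$p_adj < 0.01))
  expect_error(steel_dwass(list(1, 2)), "n >= 2")
})

test_that("regression recovers exact and noisy lines", {
  exact <- fit_line(1:10, 2 * (1:10) + 1)
  td <- tidy(exact)
  expect_equal(td$estimate, c(1, 2), tolerance = 1e-12)
  expect_equal(td$std.error, c(0, 0), tolerance = 1e-10)
  expect_equal(glance(exact)$r.squared, 1)
  set.seed(14)
  n <- 960
  x <- rnorm(n, 30, 4)
  y <- 6 + 0.81 * x + rnorm(n, sd = 3)
  noisy <- tidy(fit_line(x, y))
  expect_lt(abs(noisy$estimate[2] - 0.81), 3 * noisy$std.error[2])
  expect_error(fit_line(rep(2, 10), rnorm(10)), "constant predictor")
})

test_that("ANCOVA separates slopes and intercepts as designed", {
  set.seed(27)
  n <- 960
  x <- rnorm(n, 30, 4)
  same <- data.frame(x = x, y = 5 + x + rnorm(n))
  idres <- ancova_compare(same, same)
  expect_equal(idres$p_value[idres$term == "slope"], 1)
  # slopes 0.81 vs 0.36 at realistic noise: overwhelmingly significant
  for (rep in 1:5) {
    a <- data.frame(x = x, y = 6 + 0.81 * x + rnorm(n, sd = 3))
    b <- data.frame(x = x, y = 19.7 + 0.36 * x + rnorm(n, sd = 3))
    res <- ancova_compare(a, b)
    expect_lt(res$p_value[res$term == "slope"], 0.001)
  }
  # parallel lines with different intercepts
  a <- data.frame(x = x, y = 2 + 0.8 * x + rnorm(n, sd = 1))
  b <- data.frame(x = x, y = 8 + 0.8 * x + rnorm(n, sd = 1))
  res <- ancova_compare(a, b)
  expect_gt(res$p_value[res$term == "slope"], 0.01)
  expect_lt(res$p_value[res$term == "intercept"], 1e-6)
})
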