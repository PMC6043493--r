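# MT saturation estimators: exact inversion of the rational FLASH model,
# invalid-voxel flagging, B1 mapping and correction, pipeline closure.

protocol_pair <- function(A, R1, delta = 0) {
  p <- flash_protocol()
  mk <- function(spec, d, mt) {
    a <- spec$alpha_deg * pi / 180
    flash_image(flash_signal(A, R1, spec$TR, a, d), spec$TR, spec$alpha_deg, mt)
  }
  list(t1w = mk(p$t1w, 0, FALSE), pdw = mk(p$pdw, 0, FALSE),
       mtw = mk(p$mtw, delta, TRUE))
}

test_that("the estimators invert the rational FLASH model exactly", {
  set.seed(7)
  n <- 200
  A <- runif(n, 200, 2000)
  R1 <- runif(n, 0.2, 2.5)
  delta <- runif(n, 0, 0.06)
  tri <- protocol_pair(A, R1, delta)
  r1app <- compute_r1app(tri$t1w, tri$pdw)
  aapp <- compute_aapp(tri$t1w, tri$pdw)
  dapp <- compute_delta_app(tri$mtw, aapp, r1app)
  expect_lt(max(abs(r1app - R1) / R1), 1e-10)
  expect_lt(max(abs(aapp - A) / A), 1e-10)
  expect_lt(max(abs(dapp - delta) / pmax(delta, 1e-6)), 1e-10)
})

test_that("degenerate voxel algebra is flagged, not propagated", {
  t1w <- flash_image(c(10, 10), 0.010, 13)
  # numerator zero: S_T1 a1/TR1 == S_PD a2/TR2
  a1 <- 13 * pi / 180; a2 <- 4 * pi / 180
  s_pd <- 10 * (a1 / 0.010) / (a2 / 0.024)
  pdw <- flash_image(c(s_pd, 10 * a2 / a1), 0.024, 4)
  r1 <- compute_r1app(t1w, pdw)
  expect_equal(r1[1], 0)
  expect_true(is.na(r1[2]))  # denominator zero: S_PD/a2 == S_T1/a1
  expect_true(all(is.na(compute_aapp(flash_image(c(0, 0), 0.010, 13),
                                     flash_image(c(0, 0), 0.024, 4)))))
  expect_error(compute_r1app(t1w, flash_image(c(1, 1), 0.010, 13)), "singular")
  expect_error(compute_r1app(t1w, flash_image(c(1, 1), 0.024, 4, mt_pulse = TRUE)),
               "non-MT")
})

test_that("saturation estimate is invariant to a global receive scale", {
  tri <- protocol_pair(1000, 1.1, 0.035)
  scale_img <- function(img, c) { img$signal <- img$signal * c; img }
  d1 <- compute_delta_app(tri$mtw, compute_aapp(tri$t1w, tri$pdw),
                          compute_r1app(tri$t1w, tri$pdw))
  tri2 <- lapply(tri, scale_img, c = 3.7)
  d2 <- compute_delta_app(tri2$mtw, compute_aapp(tri2$t1w, tri2$pdw),
                          compute_r1app(tri2$t1w, tri2$pdw))
  expect_equal(d1, d2, tolerance = 1e-12)
  # Aapp itself is homogeneous of degree 1
  expect_equal(compute_aapp(tri2$t1w, tri2$pdw),
               3.7 * compute_aapp(tri$t1w, tri$pdw), tolerance = 1e-12)
})

test_that("a zero-saturation MT image gives delta_app = 0 and S_MT = 0 is invalid", {
  tri <- protocol_pair(1500, 0.9, 0)
  aapp <- compute_aapp(tri$t1w, tri$pdw)
  r1app <- compute_r1app(tri$t1w, tri$pdw)
  expect_equal(compute_delta_app(tri$mtw, aapp, r1app), 0, tolerance = 1e-10)
  zero_mt <- flash_image(0, 0.024, 4, mt_pulse = TRUE)
  expect_true(is.na(compute_delta_app(zero_mt, aapp[1], r1app[1])))
})

test_that("residual B1 correction follows the stated factor and guards its pole", {
  expect_equal(correct_b1(0.03, 1), 0.03)
  expect_equal(correct_b1(0.0366, 1.1, window = c(0.5, 1.5)),
               0.0366 * 0.6 / (1 - 0.4 * 1.1))
  expect_equal(correct_b1(0.0366, 1.1), 0.039214, tolerance = 1e-4)
  expect_true(is.na(correct_b1(0.03, 2.5, window = c(0.5, 3))))  # pole
  expect_true(is.na(correct_b1(0.03, 1.6)))                       # window
})

test_that("dual-angle inversion recovers the local flip angle", {
  r <- 1 / (2 * cos(10 * pi / 180))
  expect_equal(dual_angle_b1(r, 1, 10), 1.0, tolerance = 1e-12)
  expect_equal(dual_angle_b1(1, 1, 60), 1.0, tolerance = 1e-12)   # r = 1 -> 60 deg
  expect_true(is.na(dual_angle_b1(0.49, 1, 10)))                  # out of domain
})

test_that("pipeline reproduces the true saturation map on a noise-free phantom", {
  ph <- build_phantom(small_config(seed = 3))
  mt <- suppressMessages(mtsat_pipeline(simulate_flash_triplet(ph)))
  brain <- ph$label_map > 0 & ph$label_map <= max(SMALL_CORT)
  expect_lt(max(abs(mt$mtsat - ph$delta_true)[brain]), 1e-12)
})

test_that("saturation is neutral to a smooth transmit field after dual-angle correction", {
  ph <- build_phantom(small_config(seed = 3, b1_range = c(0.9, 1.1)))
  mt <- suppressMessages(mtsat_pipeline(simulate_flash_triplet(ph)))
  brain <- ph$label_map > 0 & ph$label_map <= max(SMALL_CORT)
  expect_lt(max(abs(mt$mtsat - ph$delta_true)[brain]), 1e-6)
  expect_lt(max(abs(mt$b1 - ph$b1_map)), 1e-8)
  # the raw voxelwise inversion agrees in the noise-free case too
  mt_raw <- suppressMessages(mtsat_pipeline(simulate_flash_triplet(ph), b1_smooth = FALSE))
  expect_lt(max(abs(mt_raw$mtsat - ph$delta_true)[brain]), 1e-6)
})

test_that("white-matter mean saturation stays within the stochastic scale at protocol noise", {
  reps <- vapply(1:6, function(s) {
    cfg <- small_config(seed = 100 + s, noise_sigma = 0.01, b1_range = c(0.94, 1.06),
                        mvf_sd_by_class = c(wm = 0, subcortical_gm = 0, cortical_gm = 0),
                        subject_sd = 0, mtsat_noise_sd = 0)
    ph <- build_phantom(cfg)
    mt <- suppressMessages(mtsat_pipeline(simulate_flash_triplet(ph)))
    mean(mt$mtsat[ph$label_map %in% SMALL_WM], na.rm = TRUE)
  }, numeric(1))
  truth <- 0.0366  # WM saturation implied by the default class mean
  expect_lt(abs(mean(reps) - truth), 3 * sd(reps))
})
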