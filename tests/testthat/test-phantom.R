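# Synthetic phantom generator: determinism, class structure, noise model,
# FLASH forward simulation, and on-disk round trips.

test_that("identical configurations give bit-identical phantoms", {
  a <- build_phantom(small_config(seed = 11, noise_sigma = 0.01, b1_range = c(0.9, 1.1)))
  b <- build_phantom(small_config(seed = 11, noise_sigma = 0.01, b1_range = c(0.9, 1.1)))
  expect_identical(a$truth_mvf, b$truth_mvf)
  expect_identical(a$quantitative, b$quantitative)
  expect_identical(a$b1_map, b$b1_map)
  expect_identical(a$roi_info, b$roi_info)
})

test_that("degenerate class distributions put every voxel at the class mean", {
  cfg <- small_config(
    mvf_sd_by_class = c(wm = 0, subcortical_gm = 0, cortical_gm = 0),
    subject_sd = 0
  )
  ph <- build_phantom(cfg)
  wm_vox <- ph$truth_mvf[ph$label_map %in% SMALL_WM]
  expect_true(all(wm_vox == 0.3070))
  # exact class ordering with deterministic means
  m <- vapply(list(SMALL_WM, SMALL_SUB, SMALL_CORT),
              function(ids) mean(ph$truth_mvf[ph$label_map %in% ids]), numeric(1))
  expect_true(m[1] > m[2] && m[2] > m[3])
})

test_that("mean truth ordering WM > subcortical > cortical holds at defaults", {
  ph <- build_phantom(phantom_config(seed = 5, noise_sigma = 0))
  cls <- split(ph$roi_info$truth_mvf[ph$roi_info$tissue_class %in%
                                       c("wm", "subcortical_gm", "cortical_gm")],
               ph$roi_info$tissue_class[ph$roi_info$tissue_class %in%
                                          c("wm", "subcortical_gm", "cortical_gm")])
  expect_gt(mean(cls$wm), mean(cls$subcortical_gm))
  expect_gt(mean(cls$subcortical_gm), mean(cls$cortical_gm))
})

test_that("nonphysiological configurations are rejected", {
  expect_error(small_config(mvf_mean_by_class = c(wm = 0.45, subcortical_gm = 0.17,
                                                  cortical_gm = 0.10)),
               "nonphysiological")
  expect_error(small_config(b1_range = c(1.05, 1.2)), "b1_range")
  expect_error(phantom_config(grid_shape = c(16, 16, 16)), "cannot host")
})

test_that("phantom invariants hold: caps, partial volumes, finite maps", {
  ph <- build_phantom(small_config(seed = 9, noise_sigma = 0.01, b1_range = c(0.92, 1.08)))
  expect_true(all(ph$truth_mvf >= 0 & ph$truth_mvf <= 0.40))
  for (pv in ph$partial_volume) expect_true(all(pv >= 0 & pv <= 1))
  sums <- ph$partial_volume$wm + ph$partial_volume$gm + ph$partial_volume$csf
  expect_true(all(sums <= 1 + 1e-12))
  for (q in ph$quantitative) expect_true(all(is.finite(q)))
  expect_true(all(ph$quantitative$r1 > 0))
  expect_true(all(ph$b1_map >= 0.92 - 1e-12 & ph$b1_map <= 1.08 + 1e-12))
})

test_that("FLASH forward model matches direct evaluation and its small-angle limit", {
  a4 <- 4 * pi / 180
  expect_equal(flash_signal(1000, 1.0, 0.024, a4, 0.03),
               1000 * a4 * 0.024 / (a4^2 / 2 + 0.024 + 0.03))
  # delta = 0, alpha -> 0: signal becomes linear in alpha
  eps <- 1e-6
  expect_equal(flash_signal(1000, 1, 0.024, 2 * eps) /
                 flash_signal(1000, 1, 0.024, eps), 2, tolerance = 1e-9)
})

test_that("simulated dual-angle images encode the transmit field by construction", {
  ph <- build_phantom(small_config(seed = 2, b1_range = c(0.9, 1.1)))
  tri <- simulate_flash_triplet(ph)
  a <- 10 * pi / 180
  r <- tri$b1_pair$img_alpha / tri$b1_pair$img_2alpha
  expect_equal(r, sin(a * ph$b1_map) / sin(2 * a * ph$b1_map), tolerance = 1e-12)
  # uniform field at 1.1x nominal gives the stated constant ratio
  img_a <- array(sin(1.1 * a), c(4, 4, 4))
  img_2a <- array(sin(2.2 * a), c(4, 4, 4))
  expect_equal(unique(as.numeric(img_a / img_2a)), 1 / (2 * cos(1.1 * a)),
               tolerance = 1e-12)
})

test_that("rejecting non-positive protocol timing", {
  ph <- build_phantom(small_config())
  bad <- flash_protocol(); bad$t1w$TR <- 0
  expect_error(simulate_flash_triplet(ph, bad), "positive")
  bad2 <- flash_protocol(); bad2$pdw$alpha_deg <- -1
  expect_error(simulate_flash_triplet(ph, bad2), "positive")
})

test_that("additive noise variance scales as noise_sigma^2 times mean signal squared", {
  sigma <- 0.02
  ph <- build_phantom(small_config(seed = 21, noise_sigma = 0))
  clean <- simulate_flash_triplet(ph, noise_sigma = 0)
  noisy <- simulate_flash_triplet(ph, noise_sigma = sigma)
  resid <- as.numeric(noisy$pdw$signal - clean$pdw$signal)
  n <- length(resid) # > 1e4 iid draws
  expect_gt(n, 1e4)
  target <- (sigma * mean(clean$pdw$signal))^2
  se <- target * sqrt(2 / (n - 1))
  expect_lt(abs(var(resid) - target), 3 * se)
})

test_that("phantoms round-trip through NIfTI with one shared affine", {
  ph <- build_phantom(small_config(seed = 4, noise_sigma = 0.01))
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  back <- read_phantom(dir)
  expect_identical(back$truth_mvf, ph$truth_mvf)
  expect_identical(back$r1, ph$quantitative$r1)
  expect_identical(back$label_map, ph$label_map)
  expect_identical(back$meta$seed, ph$config$seed)
  affines <- lapply(list.files(dir, pattern = "nii.gz$", full.names = TRUE),
                    function(f) RNifti::xform(RNifti::niftiHeader(f)))
  for (a in affines[-1]) expect_equal(unclass(a), unclass(affines[[1]]))
})
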