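# Four-compartment forward model, lookup-grid construction and inversion.

test_that("pure free-water and pure cellular states reproduce their fixed parameters", {
  expect_equal(effective_parameters(c(0, 0, 1, 0)),
               c(r1 = 0.24, r2 = 0.87, pd = 100))
  expect_equal(effective_parameters(c(0, 0, 0, 1)),
               c(r1 = 0.24, r2 = 0.87, pd = 100))
  p <- compartment_params(cellular = c(r1 = 0.6, r2 = 12, pd = 90))
  expect_equal(effective_parameters(c(0, 1, 0, 0), p),
               c(r1 = 0.6, r2 = 12, pd = 90))
})

test_that("forward model is strictly monotone in myelin with proportional water split", {
  wp <- c(0.9, 0.07, 0.03)
  v <- seq(0, 0.40, by = 0.005)
  st <- cbind(v, (1 - v) %o% wp)
  eff <- effective_parameters(st)
  expect_true(all(diff(eff[, "r1"]) > 0))
  expect_true(all(diff(eff[, "r2"]) > 0))
  expect_true(all(diff(eff[, "pd"]) < 0))
  # the two-state example: 0.10 vs 0.30 myelin
  two <- effective_parameters(rbind(c(0.1, 0.9 * wp), c(0.3, 0.7 * wp)))
  expect_true(two[2, "r1"] > two[1, "r1"])
  expect_true(two[2, "r2"] > two[1, "r2"])
  expect_true(two[2, "pd"] < two[1, "pd"])
})

test_that("invalid states are rejected", {
  expect_error(effective_parameters(c(0.5, 0.6, 0, 0)), "sum to 1")
  expect_error(effective_parameters(c(-0.1, 1.1, 0, 0)), "\\[0, 1\\]")
})

test_that("lookup enumeration matches an independent composition oracle", {
  for (step in c(0.5, 0.25, 0.05)) {
    grid <- build_lookup(step = step)
    oracle <- enumerate_compositions(step)
    expect_equal(nrow(grid$states), nrow(oracle))
    expect_equal(nrow(grid$states), choose(round(1 / step) + 3, 3))
    expect_equal(sum(grid$admissible), sum(oracle[, 1] <= 0.40 + 1e-9))
  }
  # the coarsest grid, counted exhaustively: 10 candidates, 6 admissible
  g <- build_lookup(step = 0.5)
  expect_equal(nrow(g$states), 10)
  expect_equal(sum(g$admissible), 6)
})

test_that("stored lookup triples re-evaluate identically under the forward model", {
  grid <- build_lookup(step = 0.1)
  expect_equal(grid$triples, effective_parameters(grid$states, grid$params))
})

test_that("lookup step is validated", {
  expect_error(build_lookup(step = 0), "step")
  expect_error(build_lookup(step = 0.6), "step")
  expect_error(build_lookup(step = 0.03), "integer")
})

test_that("a triple lying exactly on a candidate returns that candidate's myelin fraction", {
  grid <- build_lookup(step = 0.05)
  idx <- which(grid$admissible)[c(5, 40, 100)]
  maps <- list(r1 = grid$triples[idx, 1], r2 = grid$triples[idx, 2],
               pd = grid$triples[idx, 3])
  expect_equal(as.numeric(estimate_mvf(maps, grid)),
               unname(grid$states[idx, "v_my"]))
})

test_that("projection never exceeds the 40 percent cap, even for adversarial inputs", {
  grid <- build_lookup(step = 0.02)
  wp <- c(0.96, 0.03, 0.01)
  high <- effective_parameters(c(0.5, 0.5 * wp))
  adversarial <- list(
    r1 = c(high[["r1"]], 50, 0.01, 10),
    r2 = c(high[["r2"]], 500, 0.01, 200),
    pd = c(high[["pd"]], 0, 150, -5)
  )
  est <- estimate_mvf(adversarial, grid)
  expect_true(all(est <= 0.40 + 1e-12))
  # non-finite voxels are flagged invalid, not guessed
  est2 <- estimate_mvf(list(r1 = c(1, NA), r2 = c(10, 10), pd = c(70, 70)), grid)
  expect_true(is.na(est2[2]) && is.finite(est2[1]))
})

test_that("noise-free round trip recovers myelin within one grid step, and refinement never hurts", {
  wp <- c(0.96, 0.03, 0.01)
  set.seed(42)
  v <- runif(200, 0, 0.40)
  st <- cbind(v, (1 - v) %o% wp)
  tr <- effective_parameters(st)
  maps <- list(r1 = tr[, 1], r2 = tr[, 2], pd = tr[, 3])
  err <- function(step) max(abs(estimate_mvf(maps, build_lookup(step = step)) - v))
  e10 <- err(0.10); e05 <- err(0.05); e025 <- err(0.025)
  expect_lte(e10, 0.10 + 1e-12)
  expect_lte(e05, 0.05 + 1e-12)
  expect_lte(e025, 0.025 + 1e-12)
  expect_lte(e05, e10 + 1e-12)
  expect_lte(e025, e05 + 1e-12)
})

test_that("contrast synthesis evaluates the spin-echo equation", {
  csf <- list(r1 = 0.24, r2 = 0.87, pd = 100)
  expect_equal(synthesize_contrast(csf, 0.5, 0.01),
               100 * (1 - exp(-0.12)) * exp(-0.0087))
  expect_equal(synthesize_contrast(csf, 4.5, 0.1),
               100 * (1 - exp(-1.08)) * exp(-0.087))
  # saturation-recovery limit: TE = 0, long TR -> proton density
  expect_equal(synthesize_contrast(csf, 1000, 0), 100, tolerance = 1e-12)
  expect_error(synthesize_contrast(csf, 0, 0.01), "TR")
  expect_error(synthesize_contrast(csf, 0.5, -1), "TE")
})
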