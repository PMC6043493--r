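# Shared fixtures: small phantom configurations and independent oracles.

small_config <- function(seed = 3, noise_sigma = 0, b1_range = c(1, 1), ...) {
  phantom_config(
    grid_shape = c(32L, 32L, 32L),
    n_wm_rois = 6L, n_subcortical_rois = 2L, n_cortical_rois = 4L,
    noise_sigma = noise_sigma, b1_range = b1_range, seed = seed, ...
  )
}

# tissue ROI labels of small_config phantoms
SMALL_WM <- 1:6
SMALL_SUB <- 7:8
SMALL_CORT <- 9:12
SMALL_EYE <- 13L
SMALL_MUSCLE <- 14L

# Independent enumeration of 4-part compositions of 1 at a given step,
# written with expand.grid rather than the package's recursion.
enumerate_compositions <- function(step) {
  n <- round(1 / step)
  g <- expand.grid(i = 0:n, j = 0:n, k = 0:n)
  g <- g[g$i + g$j + g$k <= n, ]
  cbind(g$i, g$j, g$k, n - g$i - g$j - g$k) / n
}

# Independent Steel-Dwass oracle: exhaustive max-T permutation enumeration
# in plain R (recursive combination walk), kept separate from the package's
# C++ path.
oracle_pair_z <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  r <- rank(pooled)
  W <- sum(r[seq_along(a)])
  E <- length(a) * (n + 1) / 2
  tt <- table(pooled)
  V <- length(a) * length(b) / 12 * (n + 1 - sum(tt^3 - tt) / (n * (n - 1)))
  if (V <= 0) 0 else (W - E) / sqrt(V)
}

oracle_steel_dwass <- function(groups) {
  k <- length(groups)
  sizes <- lengths(groups)
  pool <- unlist(groups, use.names = FALSE)
  prs <- utils::combn(k, 2)
  zobs <- apply(prs, 2, function(ij) abs(oracle_pair_z(groups[[ij[1]]], groups[[ij[2]]])))
  assignments <- list()
  walk <- function(remaining, acc) {
    g <- length(acc) + 1L
    if (g > k) {
      assignments[[length(assignments) + 1L]] <<- acc
      return(invisible())
    }
    cmb <- utils::combn(remaining, sizes[g])
    for (j in seq_len(ncol(cmb))) {
      walk(setdiff(remaining, cmb[, j]), c(acc, list(cmb[, j])))
    }
  }
  walk(seq_along(pool), list())
  maxz <- vapply(assignments, function(asg) {
    gs <- lapply(asg, function(ii) pool[ii])
    max(apply(prs, 2, function(ij) abs(oracle_pair_z(gs[[ij[1]]], gs[[ij[2]]]))))
  }, numeric(1))
  vapply(zobs, function(z) mean(maxz >= z - 1e-9), numeric(1))
}

# Brute-force Spearman via explicit rank enumeration (average ranks)
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
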