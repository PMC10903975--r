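test_that("gray-matter mask thresholds strictly above the cutoff", {
  p <- array(c(0.2, 0.3, 0.31, 0.9), c(4, 1, 1))
  m <- gm_mask(p)
  expect_equal(c(m), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(sum(gm_mask(array(1, c(3, 3, 3)))), 27)
  expect_error(gm_mask(array(1.2, c(2, 2, 2))), "\\[0, 1\\]")
  expect_error(gm_mask(array(0.1, c(3, 3, 3))), "fewer than 2")
})

test_that("phantom gray-matter mask recovers the planted compartment", {
  sp <- small_phantom_spec()
  m <- gm_mask(sp$atlas$gm_prob, 0.3)
  gm_true <- grepl("^(stg|pcu|gm)", sp$atlas$labels)
  expect_equal(c(m), c(gm_true))
  # hub regions are a subset of the gray-matter mask
  expect_true(all(m[sp$atlas$hub]))
})

test_that("degree centrality handles identical, negated and constant series", {
  nt <- 40
  s <- sin(seq_len(nt))
  x <- cbind(s, s + 0, s * 1)          # three identical non-constant series
  arr <- array(t(x), c(3, 1, 1, nt))
  mask <- array(TRUE, c(3, 1, 1))
  dc <- degree_centrality(arr, mask)
  expect_equal(dc$values[mask], c(2, 2, 2))

  x2 <- cbind(s, s, -s)                 # the negation correlates at -1
  arr2 <- array(t(x2), c(3, 1, 1, nt))
  dc2 <- degree_centrality(arr2, mask)
  expect_equal(dc2$values[mask], c(1, 1, 0))

  x3 <- cbind(s, s, rep(1, nt))         # constant voxel gets degree 0
  arr3 <- array(t(x3), c(3, 1, 1, nt))
  expect_warning(dc3 <- degree_centrality(arr3, mask), "constant")
  expect_equal(dc3$values[mask], c(1, 1, 0))
})

test_that("blockwise degree centrality equals the brute-force pairwise count", {
  fx <- random_series_array(100, 50, seed = 13)
  dc <- degree_centrality(fx$arr, fx$mask, block_size = 7)
  expect_equal(dc$values[fx$mask], dc_bruteforce(fx$x))
  # raw values are integers within [0, V-1]
  vals <- dc$values[fx$mask]
  expect_true(all(vals == round(vals)))
  expect_true(all(vals >= 0 & vals <= 49))
})

test_that("lowering the degree threshold never decreases any count", {
  fx <- random_series_array(60, 40, seed = 3)
  hi <- degree_centrality(fx$arr, fx$mask, r_threshold = 0.3)$values[fx$mask]
  lo <- degree_centrality(fx$arr, fx$mask, r_threshold = 0.1)$values[fx$mask]
  expect_true(all(lo >= hi))
})

test_that("duplicating a voxel raises the pair's degree by exactly one", {
  fx <- random_series_array(80, 30, seed = 9)
  base <- degree_centrality(fx$arr, fx$mask)$values[fx$mask]
  xdup <- cbind(fx$x, fx$x[, 30])
  arr <- array(t(xdup), c(31, 1, 1, 80))
  mask <- array(TRUE, c(31, 1, 1))
  dup <- degree_centrality(arr, mask)$values[mask]
  expect_equal(dup[30], base[30] + 1)
  expect_equal(dup[31], base[30] + 1)
  expect_equal(dup[1:29], base[1:29] +
                 as.integer(cor(fx$x[, 1:29], fx$x[, 30]) >= 0.25))
})

test_that("fast ECM is uniform for identical series", {
  nt <- 30
  s <- cos(seq_len(nt))
  arr <- array(rep(s, each = 5), c(5, 1, 1, nt))
  mask <- array(TRUE, c(5, 1, 1))
  ec <- fast_ecm(arr, mask)
  expect_equal(ec$values[mask], rep(1 / sqrt(5), 5), tolerance = 1e-9)
})

test_that("implicit fast ECM equals the dense eigendecomposition", {
  for (seed in 1:5) {
    nv <- sample(c(60, 120, 200), 1)
    fx <- random_series_array(130, nv, seed = seed)
    ec <- fast_ecm(fx$arr, fx$mask)
    expect_lt(max(abs(ec$values[fx$mask] - ec_dense_oracle(fx$x))), 1e-6)
  }
})

test_that("fast ECM output is nonnegative with unit Euclidean norm", {
  fx <- random_series_array(70, 90, seed = 77)
  ec <- fast_ecm(fx$arr, fx$mask)
  v <- ec$values[fx$mask]
  expect_true(all(v >= 0))
  expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
  expect_true(ec$provenance$iterations >= 1)
})

test_that("map standardization centres, scales, or applies atanh", {
  fx <- random_series_array(50, 30, seed = 2)
  dc <- degree_centrality(fx$arr, fx$mask)
  z <- standardize_map(dc)
  expect_equal(mean(z$values[fx$mask]), 0, tolerance = 1e-12)
  expect_equal(sd(z$values[fx$mask]), 1, tolerance = 1e-12)
  expect_true(z$standardized)

  const <- dc; const$values[const$mask] <- 3
  expect_error(standardize_map(const), "constant")

  rmap <- dc; rmap$values[rmap$mask] <- 0.5
  fz <- standardize_map(rmap, method = "fisher")
  expect_equal(fz$values[fz$mask][1], atanh(0.5))
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
})

test_that("Gaussian smoothing: unit-sum kernel, identity limit, impulse shape", {
  mask <- array(TRUE, c(15, 15, 15))
  uni <- new_map_for_test(array(2, c(15, 15, 15)), mask)
  sm <- smooth_map(uni, fwhm_mm = 6, voxel_size_mm = 3.31)
  expect_lt(max(abs(sm$values[mask] - 2)), 1e-10)

  tiny <- smooth_map(uni, fwhm_mm = 0.5, voxel_size_mm = 3.31)
  expect_equal(tiny$values, uni$values)
  expect_error(smooth_map(uni, fwhm_mm = -1), "positive")

  # central impulse reproduces the sampled separable Gaussian kernel
  imp_vals <- array(0, c(15, 15, 15)); imp_vals[8, 8, 8] <- 1
  imp <- new_map_for_test(imp_vals, mask)
  fwhm <- 6; vox <- 2
  smi <- smooth_map(imp, fwhm_mm = fwhm, voxel_size_mm = vox)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / vox
  off <- -3:3
  k1 <- exp(-off^2 / (2 * sigma^2))
  half <- max(1, ceiling(4 * sigma))
  kfull <- exp(-(-half:half)^2 / (2 * sigma^2)); kfull <- kfull / sum(kfull)
  expected_center <- kfull[half + 1]^3
  expect_equal(smi$values[8, 8, 8], expected_center, tolerance = 1e-10)
  expect_equal(smi$values[9, 8, 8] / smi$values[8, 8, 8],
               exp(-1 / (2 * sigma^2)), tolerance = 1e-10)
})

test_that("smoothing respects the mask boundary", {
  mask <- array(FALSE, c(9, 9, 9)); mask[3:7, 3:7, 3:7] <- TRUE
  vals <- array(NA_real_, c(9, 9, 9)); vals[mask] <- 1
  m <- new_map_for_test(vals, mask)
  sm <- smooth_map(m, fwhm_mm = 6, voxel_size_mm = 3)
  # a constant in-mask map stays constant: out-of-mask voxels don't dilute
  expect_lt(max(abs(sm$values[mask] - 1)), 1e-10)
  expect_true(all(is.na(sm$values[!mask])))
})
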