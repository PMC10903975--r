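# small synthetic map sets: subjects x voxels with a design tibble
make_map_set <- function(n_per_group = c(12, 10, 14), n_vox = 150, seed = 1,
                         effect_voxels = integer(0), effect = 0) {
  set.seed(seed)
  groups <- rep(c("CN", "Obj-SCD", "MCI"), times = n_per_group)
  n <- length(groups)
  design <- tibble::tibble(
    group = groups,
    age = rnorm(n, 72, 6), sex = rbinom(n, 1, 0.5),
    education = rnorm(n, 16, 2.5), mean_fd = abs(rnorm(n, 0.2, 0.05))
  )
  y <- matrix(rnorm(n * n_vox), n, n_vox)
  if (length(effect_voxels) > 0) {
    y[groups == "Obj-SCD", effect_voxels] <-
      y[groups == "Obj-SCD", effect_voxels] + effect
  }
  list(y = y, design = design)
}

test_that("voxel-wise ANCOVA F equals an independent two-model fit per voxel", {
  ms <- make_map_set(n_vox = 60, seed = 2)
  mask <- array(TRUE, c(60, 1, 1))
  sm <- voxelwise_ancova(ms$y, ms$design, mask = mask)
  expect_equal(sm$df1, 2)
  expect_equal(sm$df2, nrow(ms$y) - 7)
  set.seed(3)
  for (v in sample(60, 20)) {
    d <- ms$design; d$val <- ms$y[, v]
    fit1 <- lm(val ~ group + age + sex + education + mean_fd, data = d)
    fit0 <- lm(val ~ age + sex + education + mean_fd, data = d)
    a <- anova(fit0, fit1)
    expect_equal(sm$f[v], a$F[2], tolerance = 1e-10)
  }
})

test_that("rank-deficient ANCOVA designs are reported", {
  ms <- make_map_set(n_vox = 10, seed = 4)
  ms$design$dup <- ms$design$age
  mask <- array(TRUE, c(10, 1, 1))
  expect_error(voxelwise_ancova(ms$y, ms$design, mask = mask), "rank-deficient")
})

test_that("a planted group effect concentrates F inside the affected voxels", {
  for (seed in 1:5) {
    ms <- make_map_set(n_vox = 300, seed = 100 + seed,
                       effect_voxels = 1:20, effect = 1.5)
    mask <- array(TRUE, c(300, 1, 1))
    sm <- voxelwise_ancova(ms$y, ms$design, mask = mask)
    expect_gt(max(sm$f[1:20]), quantile(sm$f[21:300], 0.99))
  }
})

test_that("connected-component labelling respects the lattice connectivity", {
  d <- c(6, 6, 4)
  # two diagonal-touching voxels: one cluster under 26, two under 6
  vox <- c(
    which(array(seq_len(prod(d)), d) == 1)[1],       # (1,1,1)
    (1 - 1) * 36 + (2 - 1) * 6 + 2                   # (2,2,1) linear index
  )
  arr <- array(FALSE, d); arr[1, 1, 1] <- TRUE; arr[2, 2, 1] <- TRUE
  vox <- which(arr)
  lab26 <- objscd:::label_components(vox, d, 26)
  lab6 <- objscd:::label_components(vox, d, 6)
  expect_equal(length(unique(lab26)), 1)
  expect_equal(length(unique(lab6)), 2)

  # a solid 2x2x2 block plus an isolated voxel: two components, extents 8 and 1
  arr2 <- array(FALSE, d); arr2[1:2, 1:2, 1:2] <- TRUE; arr2[5, 5, 3] <- TRUE
  lab <- objscd:::label_components(which(arr2), d, 26)
  expect_equal(sort(tabulate(lab)), c(1, 8))
})

test_that("cluster correction finds a planted blob and is seed-deterministic", {
  d <- c(10, 10, 6)
  mask <- array(TRUE, d)
  blob <- array(FALSE, d); blob[3:5, 3:5, 2:4] <- TRUE
  set.seed(9)
  groups <- rep(c("CN", "Obj-SCD", "MCI"), times = c(10, 10, 10))
  design <- tibble::tibble(group = groups, age = rnorm(30, 72, 6),
                           sex = rbinom(30, 1, 0.5),
                           education = rnorm(30, 16, 2), mean_fd = runif(30, 0.1, 0.3))
  y <- matrix(rnorm(30 * prod(d)), 30, prod(d))
  y[groups == "Obj-SCD", c(blob)] <- y[groups == "Obj-SCD", c(blob)] + 2
  sm <- voxelwise_ancova(y, design, mask = mask)
  cr <- cluster_correct(sm, n_perm = 199, seed = 5)
  expect_gt(nrow(cr$clusters), 0)
  top <- cr$clusters[1, ]
  expect_true(top$significant)
  # the top cluster overlaps the planted blob substantially
  top_vox <- which(cr$labels == top$cluster)
  expect_gt(mean(top_vox %in% which(blob)), 0.5)

  cr2 <- cluster_correct(sm, n_perm = 199, seed = 5)
  expect_identical(cr$clusters$p_corrected, cr2$clusters$p_corrected)
  cr3 <- cluster_correct(sm, n_perm = 199, seed = 6)
  expect_false(identical(cr$null_max_extent, cr3$null_max_extent))
})

test_that("null data yield no suprathreshold clusters or non-significant ones", {
  ms <- make_map_set(n_per_group = c(8, 8, 8), n_vox = 200, seed = 12)
  mask <- array(TRUE, c(200, 1, 1))
  sm <- voxelwise_ancova(ms$y, ms$design, mask = mask)
  expect_warning(cr <- cluster_correct(sm, n_perm = 99, seed = 1), "low")
  if (nrow(cr$clusters) > 0) {
    expect_true(all(cr$clusters$extent <= 3))
  }
})

test_that("ROI means equal the brute-force average over listed voxels", {
  set.seed(8)
  y <- matrix(rnorm(5 * 40), 5, 40)
  idx <- c(3, 17, 22)
  means <- extract_roi_means(y, idx)
  oracle <- sapply(1:5, function(i) mean(y[i, idx]))
  expect_equal(means, oracle)
  # single-voxel cluster: the voxel itself; constant map: the constant
  expect_equal(extract_roi_means(y, 7), y[, 7])
  expect_equal(extract_roi_means(matrix(3, 4, 10), c(2, 5)), rep(3, 4))
})

test_that("permutation null extents are exchangeable with the observed statistic", {
  # under a true null the observed max extent's rank among the null draws is
  # approximately uniform: check it is not systematically extreme
  ranks <- numeric(12)
  for (r in 1:12) {
    ms <- make_map_set(n_per_group = c(7, 7, 7), n_vox = 120, seed = 300 + r)
    mask <- array(TRUE, c(120, 1, 1))
    sm <- voxelwise_ancova(ms$y, ms$design, mask = mask)
    obs <- objscd:::max_cluster_extent(sm$f, mask,
                                       qf(0.01, sm$df1, sm$df2, lower.tail = FALSE), 26)
    suppressWarnings(cr <- cluster_correct(sm, voxel_p = 0.01, n_perm = 60,
                                           seed = r))
    ranks[r] <- mean(cr$null_max_extent >= obs)
  }
  expect_gt(mean(ranks), 0.15)
  expect_lt(mean(ranks), 0.95)
})
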