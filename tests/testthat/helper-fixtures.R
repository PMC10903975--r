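# shared fixtures: built once per test run, kept deliberately small

# small phantom for fast imaging tests
small_phantom_spec <- function(seed = 11, ...) {
  phantom_spec(grid = c(14, 14, 10), n_volumes = 60, seed = seed, ...)
}

# a cleaned run + mask cached across tests that only need "some" realistic input
.fixture_env <- new.env()

fixture_clean_run <- function() {
  if (is.null(.fixture_env$clean)) {
    sp <- small_phantom_spec()
    run <- generate_bold_run(sp, "FIX1", "CN", "baseline")
    .fixture_env$mask <- gm_mask(run$gm_prob)
    .fixture_env$clean <- preprocess_run(run, discard = 5)
  }
  list(clean = .fixture_env$clean, mask = .fixture_env$mask)
}

# random T x V series wrapped as a 4D array + full mask, for oracle tests
random_series_array <- function(n_t, n_v, seed = 1) {
  set.seed(seed)
  dims <- c(n_v, 1, 1)
  x <- matrix(rnorm(n_t * n_v), n_t, n_v)
  list(
    arr = array(t(x), c(dims, n_t)),
    mask = array(TRUE, dims),
    x = x
  )
}

# wrap a bare array as a centrality_map for smoothing/standardization tests
new_map_for_test <- function(values, mask) {
  objscd:::new_centrality_map(values, mask, "DC", list())
}

# brute-force degree centrality: double loop over voxel pairs
dc_bruteforce <- function(x, r_threshold = 0.25) {
  v <- ncol(x)
  dc <- integer(v)
  for (i in seq_len(v)) {
    for (j in seq_len(v)) {
      if (i == j) next
      if (cor(x[, i], x[, j]) >= r_threshold) dc[i] <- dc[i] + 1L
    }
  }
  dc
}

# dense eigendecomposition oracle for eigenvector centrality
ec_dense_oracle <- function(x) {
  a <- (1 + cor(x)) / 2
  e <- eigen(a, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  v / sqrt(sum(v^2))
}
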