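# Shared fixtures, built once per test session and cached in an environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# linear-generator SVF v(x) = A (x - c) on a cubic grid
linear_svf <- function(A, n = 24L) {
  ctr <- (n + 1) / 2
  pos <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  X <- as.matrix(pos) - matrix(ctr, nrow(pos), 3, byrow = TRUE)
  velocity_field(array(t(A %*% t(X)), c(n, n, n, 3L)))
}

# displacement field of the affine map x -> c + B (x - c)
affine_displacement <- function(B, n = 24L) {
  ctr <- (n + 1) / 2
  pos <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  X <- as.matrix(pos) - matrix(ctr, nrow(pos), 3, byrow = TRUE)
  array(t((B - diag(3)) %*% t(X)), c(n, n, n, 3L))
}

# per-voxel vector magnitude of a 4D field array
vec_mag <- function(v) {
  v <- unclass(v)
  sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)
}

interior_idx <- function(shape, margin = 4L) {
  m <- array(FALSE, shape)
  m[(margin + 1):(shape[1] - margin), (margin + 1):(shape[2] - margin),
    (margin + 1):(shape[3] - margin)] <- TRUE
  m
}

# the standard 32^3 known-warp registration fixture (heavy; cached)
get_reg_fixture <- function() cached("reg_fixture", function() registration_fixture())

get_reg_result <- function() {
  cached("reg_result", function() {
    fx <- get_reg_fixture()
    logdemons_register(fx$fixed, fx$moving, registration_config())
  })
}

# transport fixture plus its direct longitudinal registration (heavy; cached)
get_transport_fixture <- function() cached("transport_fixture", function() transport_fixture())

# small separable classification problem
separable_cohort <- function(n_per = 30L, d = 5L, gap = 3, seed = 3L) {
  set.seed(seed)
  H <- rbind(matrix(rnorm(n_per * d), n_per, d) + gap,
             matrix(rnorm(n_per * d), n_per, d) - gap)
  list(H = H, y = c(rep("MCIc", n_per), rep("MCIs", n_per)))
}
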