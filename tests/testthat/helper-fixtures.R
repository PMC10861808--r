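# fixtures are built in code; nothing binary ships with the tests

# random binary mask on an identity-spacing grid
rand_mask <- function(dims = c(8, 8, 8), p = 0.3, affine = diag(4)) {
  binary_mask(array(rbinom(prod(dims), 1, p), dims), affine)
}

# brute-force overlap coefficient / dice by explicit voxel loop
oc_oracle <- function(a, b) {
  na <- 0; nb <- 0; ni <- 0
  d <- dim(a$data)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    av <- a$data[i, j, k]; bv <- b$data[i, j, k]
    na <- na + av; nb <- nb + bv; ni <- ni + av * bv
  }
  if (min(na, nb) == 0) return(NA_real_)
  ni / min(na, nb)
}

dice_oracle <- function(a, b) {
  na <- sum(a$data); nb <- sum(b$data); ni <- sum(a$data * b$data)
  if (na + nb == 0) return(NA_real_)
  2 * ni / (na + nb)
}

# O(n^2) nearest-foreground distance oracle in world mm
distance_oracle <- function(mask) {
  fg <- world_coords_of_foreground(mask)
  d <- dim(mask$data)
  out <- array(NA_real_, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    p <- voxel_to_world(mask, c(i - 1, j - 1, k - 1))
    out[i, j, k] <- sqrt(min(rowSums(sweep(fg, 2, as.numeric(p))^2)))
  }
  out
}

# exhaustive sign-flip enumeration of the signed-rank two-sided p-value
wilcoxon_enum_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  obs_dev <- abs(V - mu)
  vs <- vapply(0:(2^n - 1), function(bits) {
    signs <- bitwAnd(bits, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  mean(abs(vs - mu) >= obs_dev - 1e-12)
}

# tiny fast phantom spec for generator tests
small_spec <- function(seed = 1, ...) {
  phantom_spec(grid_shape = c(32, 32, 32), tube_radius = 3, fan_radius = 5,
               ensemble_T = 6, n_responses = 6,
               class_distances = list(`+M1+` = c(0, 1.5),
                                      `-M1+` = c(4, 1.5),
                                      `-M1-` = c(9, 2)),
               seed = seed, ...)
}
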