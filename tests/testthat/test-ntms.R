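make_m1 <- function() {
  # M1 = x >= 4 half of an 8^3 grid, 1 mm isotropic
  arr <- array(0, c(8, 8, 8)); arr[5:8, , ] <- 1
  binary_mask(arr, diag(4), label = "M1")
}

rec <- function(x, amp, lat) {
  list(x_mm = x, y_mm = 4, z_mm = 4, amplitude_uv = amp, latency_ms = lat)
}

test_that("classify_response implements the class rules", {
  m1 <- make_m1()
  cases <- list(
    # inside M1 (x = 6), positive, physiological latency
    list(r = rec(6, 60, 20), want = "+M1+"),
    # exactly at the 50 uV threshold counts as positive
    list(r = rec(2, 50, 22), want = "-M1+"),
    # negative inside M1 is never mapped
    list(r = rec(6, 30, 21), want = "excluded"),
    # latency out of window
    list(r = rec(2, 30, 30), want = "excluded"),
    # latency boundaries are inclusive
    list(r = rec(2, 80, 18), want = "-M1+"),
    list(r = rec(2, 80, 26), want = "-M1+"),
    # negative outside M1
    list(r = rec(2, 49.9, 20), want = "-M1-"))
  for (cs in cases)
    expect_identical(classify_response(cs$r, m1), cs$want)
})

test_that("classification is total and positions off-grid warn + exclude", {
  m1 <- make_m1()
  expect_warning(k <- classify_response(rec(200, 60, 20), m1),
                 "registration")
  expect_identical(k, "excluded")
  set.seed(11)
  for (i in 1:50) {
    r <- rec(runif(1, 0, 7), runif(1, 0, 200), runif(1, 10, 35))
    expect_true(classify_response(r, m1) %in%
                  c("+M1+", "-M1+", "-M1-", "excluded"))
  }
  expect_error(classify_response(rec(2, -5, 20), m1), "non-negative")
})

test_that("threshold_export is strictly greater than zero", {
  arr <- array(0, c(3, 3, 3))
  arr[1, 1, 1] <- 1e-4   # tiny positive value is foreground
  arr[2, 1, 1] <- -3     # negative is background
  arr[3, 1, 1] <- 7.5
  m <- threshold_export(volume(arr))
  expect_equal(n_foreground(m), 2)
  expect_equal(m$data[1, 1, 1], 1)
  expect_equal(m$data[2, 1, 1], 0)
  expect_equal(n_foreground(threshold_export(volume(array(0, c(3, 3, 3))))), 0)
})

test_that("landmark removal and WM filtering are voxelwise AND", {
  set.seed(4)
  for (i in 1:5) {
    a <- rand_mask(c(8, 8, 8))
    b <- rand_mask(c(8, 8, 8))
    got <- remove_landmarks(a, b)
    # brute-force voxel loop
    want <- array(0, dim(a$data))
    for (ii in 1:8) for (jj in 1:8) for (kk in 1:8)
      want[ii, jj, kk] <- a$data[ii, jj, kk] * b$data[ii, jj, kk]
    expect_equal(got$data, want)
    expect_lte(n_foreground(got), n_foreground(a))  # monotone shrinkage
    expect_equal(wm_filter(a, b)$data, want)
  }
  full <- binary_mask(array(1, c(4, 4, 4)))
  sub <- rand_mask(c(4, 4, 4))
  expect_equal(remove_landmarks(sub, full)$data, sub$data)
  none <- binary_mask(array(0, c(4, 4, 4)))
  expect_equal(n_foreground(remove_landmarks(sub, none)), 0)
  # complementary WM reading drops WM voxels instead
  expect_equal(wm_filter(sub, none, keep_in_wm = FALSE)$data, sub$data)
})

test_that("rasterization: point-to-voxel, footprint radius, idempotence", {
  g <- grid_geometry(c(9, 9, 9), diag(4))
  one <- data.frame(x_mm = 4, y_mm = 4, z_mm = 4)
  rm0 <- rasterize_responses(one, g, "+M1+", radius = 0)
  expect_equal(n_foreground(rm0$mask), 1)
  expect_equal(rm0$n_responses, 1)

  # enumerate voxel centres within r of the point (independent oracle)
  count_within <- function(r) {
    off <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
    sum(sqrt(rowSums(off^2)) <= r)
  }
  # 1.2 mm: centre + 6 face neighbours (7-voxel cross)
  rm_cross <- rasterize_responses(one, g, "+M1+", radius = 1.2)
  expect_equal(n_foreground(rm_cross$mask), count_within(1.2))
  expect_equal(n_foreground(rm_cross$mask), 7)
  # 1.5 mm additionally reaches the 12 edge neighbours at sqrt(2) mm
  rm1 <- rasterize_responses(one, g, "+M1+", radius = 1.5)
  expect_equal(n_foreground(rm1$mask), count_within(1.5))
  expect_equal(n_foreground(rm1$mask), 19)

  two <- data.frame(x_mm = c(4, 4), y_mm = c(4, 4), z_mm = c(4, 4))
  rm2 <- rasterize_responses(two, g, "-M1+", radius = 0)
  expect_equal(n_foreground(rm2$mask), 1)
  expect_equal(rm2$n_responses, 2)

  empty <- rasterize_responses(NULL, g, "-M1-")
  expect_equal(n_foreground(empty$mask), 0)
  expect_equal(empty$n_responses, 0)
})

test_that("build_response_masks yields disjoint class masks and honours curation", {
  m1 <- make_m1()
  recs <- data.frame(
    x_mm = c(6, 6, 2, 2, 2, 1, 6),
    y_mm = c(2, 4, 2, 4, 6, 1, 6),
    z_mm = c(2, 4, 2, 4, 6, 1, 6),
    amplitude_uv = c(100, 60, 80, 20, 55, 90, 70),
    latency_ms = c(20, 22, 19, 21, 25, 40, 23),
    manually_excluded = c(0, 0, 0, 0, 0, 0, 1))
  masks <- build_response_masks(recs, m1)
  # record 6 excluded by latency, record 7 by curation
  expect_equal(masks[["+M1+"]]$n_responses, 2)
  expect_equal(masks[["-M1+"]]$n_responses, 2)
  expect_equal(masks[["-M1-"]]$n_responses, 1)
  inter <- masks[["+M1+"]]$mask$data * masks[["-M1+"]]$mask$data +
    masks[["+M1+"]]$mask$data * masks[["-M1-"]]$mask$data +
    masks[["-M1+"]]$mask$data * masks[["-M1-"]]$mask$data
  expect_equal(sum(inter), 0)  # pairwise disjoint

  # intracranial landmark removal shrinks, never grows
  icv <- binary_mask(array(0, c(8, 8, 8)) + 1)
  masks2 <- build_response_masks(recs, m1, intracranial = icv)
  for (kl in names(masks2))
    expect_lte(n_foreground(masks2[[kl]]$mask),
               n_foreground(masks[[kl]]$mask))
})
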