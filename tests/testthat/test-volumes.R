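test_that("volume construction enforces its invariants", {
  expect_error(volume(array(0, c(2, 2))), "3D")
  expect_error(volume(array(0, c(2, 2, 2)), matrix(0, 4, 4)), "last affine row")
  aff <- diag(4); aff[1, 1] <- 0
  expect_error(volume(array(0, c(2, 2, 2)), aff), "invertible")
  v <- volume(array(0, c(2, 3, 4)), diag(c(1, 1, 2, 1)))
  expect_equal(dim(v), c(2L, 3L, 4L))
  expect_equal(spacing(v), c(1, 1, 2))
})

test_that("spacing equals column norms of a rotated affine", {
  # 30-degree rotation about z with anisotropic scales: spacing must come
  # from column norms, not diagonal entries
  th <- pi / 6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  A <- rbind(cbind(R %*% diag(c(1, 1, 2)), c(10, -5, 3)), c(0, 0, 0, 1))
  v <- volume(array(0, c(4, 4, 4)), A)
  manual <- apply(A[1:3, 1:3], 2, function(cl) sqrt(sum(cl^2)))
  expect_equal(spacing(v), manual, tolerance = 1e-6)
  expect_equal(spacing(v), c(1, 1, 2), tolerance = 1e-6)
})

test_that("binary masks reject non-binary data and count foreground", {
  expect_error(binary_mask(array(0.5, c(2, 2, 2))), "exactly 0 or 1")
  m <- binary_mask(array(c(1, 0, 1, rep(0, 5)), c(2, 2, 2)))
  expect_equal(n_foreground(m), 2)
})

test_that("NIfTI round-trip is lossless", {
  dir <- withr::local_tempdir()
  # integer mask: bit-identical payload across write/read/write
  m <- rand_mask(c(4, 4, 4))
  f1 <- file.path(dir, "m.nii.gz")
  write_volume(m, f1)
  m2 <- read_volume(f1)
  expect_identical(m2$data, m$data)
  expect_equal(m2$affine, m$affine, tolerance = 1e-6)
  f2 <- file.path(dir, "m2.nii")
  write_volume(binary_mask(m2), f2)
  f3 <- file.path(dir, "m3.nii")
  write_volume(binary_mask(read_volume(f2)), f3)
  expect_identical(unname(tools::md5sum(f2)), unname(tools::md5sum(f3)))

  # float volume with a non-trivial affine
  aff <- diag(c(1, 1, 2, 1)); aff[1:3, 4] <- c(-12.5, 3.25, 7)
  v <- volume(array(runif(5 * 6 * 7), c(5, 6, 7)), aff)
  fv <- file.path(dir, "v.nii.gz")
  write_volume(v, fv)
  v2 <- read_volume(fv)
  expect_lt(max(abs(v2$data - v$data)), 1e-6)
  expect_equal(v2$affine, aff, tolerance = 1e-5)
})

test_that("reader squeezes trailing singleton and rejects true 4D", {
  dir <- withr::local_tempdir()
  arr4 <- array(runif(3 * 3 * 3 * 1), c(3, 3, 3, 1))
  f <- file.path(dir, "x.nii")
  cstconcord:::write_nifti_raw(arr4, diag(4), f)
  expect_message(v <- read_volume(f), "squeez")
  expect_equal(dim(v), c(3L, 3L, 3L))
  arr4b <- array(runif(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  f2 <- file.path(dir, "y.nii")
  cstconcord:::write_nifti_raw(arr4b, diag(4), f2)
  expect_error(read_volume(f2), "read_ensemble")
  expect_error(read_volume(file.path(dir, "absent.nii")), "exist")
})

test_that("our NIfTI files agree with an independent reader (nibabel)", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  dir <- withr::local_tempdir()
  aff <- diag(c(1, 1, 2, 1)); aff[1:3, 4] <- c(5, -4, 2.5)
  v <- volume(array(seq_len(24) / 24, c(2, 3, 4)), aff)
  f <- file.path(dir, "v.nii")
  write_volume(v, f)
  py <- file.path(dir, "check.py")
  writeLines(c(
    "import sys",
    "import nibabel as nib",
    "import numpy as np",
    "img = nib.load(sys.argv[1])",
    "d = np.asanyarray(img.dataobj)",
    "ref = np.array([[1,0,0,5],[0,1,0,-4],[0,0,2,2.5],[0,0,0,1]])",
    "print(d.shape, round(float(d.sum()), 9), np.allclose(img.affine, ref))"
  ), py)
  out <- system2("python", c(py, f), stdout = TRUE)
  expect_match(out, "\\(2, 3, 4\\) 12.5 True")
})

test_that("world_coords_of_foreground maps voxel centres through the affine", {
  empty <- binary_mask(array(0, c(3, 3, 3)))
  expect_equal(nrow(world_coords_of_foreground(empty)), 0)

  m <- binary_mask(array(c(1, rep(0, 26)), c(3, 3, 3)))
  expect_equal(unname(world_coords_of_foreground(m)[1, ]), c(0, 0, 0))

  aff <- diag(4); aff[1, 4] <- 10
  arr <- array(0, c(4, 4, 4)); arr[2, 1, 1] <- 1; arr[1, 3, 1] <- 1; arr[1, 1, 4] <- 1
  m2 <- binary_mask(arr, aff)
  pts <- world_coords_of_foreground(m2)
  # manual affine multiplication of the three 0-based indices
  manual <- rbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 3))
  manual[, 1] <- manual[, 1] + 10
  expect_equal(unname(pts), unname(manual))
})

test_that("resampling: identity, nearest preserves values, volumes survive", {
  v <- volume(array(runif(4 * 4 * 4), c(4, 4, 4)), diag(c(1, 1, 2, 1)))
  same <- resample_to_grid(v, v, "linear")
  expect_equal(same$data, v$data, tolerance = 1e-12)

  # binary 2 mm cube mask resampled to 1 mm: physical volume preserved.
  # Target centres sit half a voxel off the source boundaries (the generic
  # alignment; exact boundary/centre ties are a measure-zero pathology).
  aff2 <- diag(c(2, 2, 2, 1))
  arr <- array(0, c(8, 8, 8)); arr[3:5, 3:5, 3:5] <- 1  # 27 voxels = 216 mm3
  m <- binary_mask(arr, aff2)
  aff_t <- diag(4); aff_t[1:3, 4] <- 0.5
  tgt <- grid_geometry(c(16, 16, 16), aff_t)
  m1 <- resample_to_grid(m, tgt, "nearest")
  expect_true(is_binary_mask(m1))
  vol_mm3 <- n_foreground(m1) * prod(spacing(m1))
  expect_lt(abs(vol_mm3 - 216) / 216, 0.10)
  expect_true(all(m1$data %in% c(0, 1)))

  expect_error(resample_to_grid(m, tgt, "linear"), "nearest")

  # single foreground voxel lands within one output voxel diagonal
  arr1 <- array(0, c(6, 6, 6)); arr1[4, 3, 2] <- 1
  affs <- diag(c(2, 2, 2, 1)); affs[1:3, 4] <- c(1, 2, 3)
  ms <- binary_mask(arr1, affs)
  w <- world_coords_of_foreground(ms)[1, ]
  out <- resample_to_grid(ms, grid_geometry(c(14, 14, 14), diag(4)), "nearest")
  wout <- world_coords_of_foreground(out)
  dists <- sqrt(rowSums(sweep(wout, 2, w)^2))
  expect_true(all(dists <= sqrt(3) + 1e-9))

  # out-of-field fill is 0
  shifted <- grid_geometry(c(4, 4, 4), {
    a <- diag(4); a[1, 4] <- 100; a
  })
  far <- resample_to_grid(m, shifted, "nearest")
  expect_equal(n_foreground(far), 0)
})

test_that("grid mismatch errors point at resample_to_grid", {
  a <- rand_mask(c(4, 4, 4))
  b <- rand_mask(c(5, 5, 5))
  expect_error(overlap_coefficient(a, b), "resample_to_grid")
})
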