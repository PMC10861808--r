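#' 3D volume with a voxel-to-world affine
#'
#' A `volume` is the universal carrier for every volumetric quantity in the
#' package: binary masks, probability maps, uncertainty maps and distance
#' maps. It couples a 3D numeric array with a 4x4 voxel-to-world affine in
#' millimetres. Voxel indices are 0-based when mapped through the affine and
#' world coordinates refer to voxel centres; all distances are computed in
#' world space (mm).
#'
#' @param data 3D numeric array (each dimension >= 1).
#' @param affine 4x4 invertible voxel-to-world matrix, last row (0,0,0,1).
#' @return An object of class `volume` with elements `data` and `affine`.
#' @examples
#' v <- volume(array(0, c(4, 4, 4)), diag(4))
#' spacing(v)
#' @export
volume <- function(data, affine = diag(4)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got dimensions: ",
         paste(dim(data), collapse = "x"))
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be 4x4")
  if (any(abs(affine[4, ] - c(0, 0, 0, 1)) > 1e-9))
    stop("last affine row must be (0, 0, 0, 1)")
  det3 <- det(affine[1:3, 1:3])
  if (!is.finite(det3) || abs(det3) < 1e-12)
    stop("affine is not invertible (singular 3x3 block)")
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(sp <= 0)) stop("voxel spacing must be strictly positive")
  structure(list(data = data, affine = affine), class = "volume")
}

#' @export
dim.volume <- function(x) dim(x$data)

#' Per-axis voxel size in mm
#'
#' Column norms of the affine's 3x3 block.
#' @param vol A [volume()].
#' @return Numeric length-3 vector of spacings (mm).
#' @export
spacing <- function(vol) {
  stopifnot(inherits(vol, "volume"))
  sqrt(colSums(vol$affine[1:3, 1:3]^2))
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n",
              paste(class(x), collapse = "/"),
              paste(dim(x$data), collapse = "x"),
              paste(signif(spacing(x), 4), collapse = "x")))
  rng <- range(x$data)
  cat(sprintf("  data range [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Binary mask volume
#'
#' A `volume` whose voxels are restricted to \{0, 1\}. Used for tract masks,
#' intracranial/WM/M1 masks and rasterized nTMS response masks.
#'
#' @param x A `volume` or a 3D array of 0/1 (logical accepted).
#' @param affine Affine, used when `x` is a bare array.
#' @param label Optional role label (e.g. "tract", "M1", "response").
#' @return Object of class `c("binary_mask", "volume")`.
#' @export
binary_mask <- function(x, affine = diag(4), label = NULL) {
  if (inherits(x, "volume")) {
    dat <- x$data
    affine <- x$affine
  } else {
    dat <- x
  }
  if (is.logical(dat)) dat <- dat + 0
  storage.mode(dat) <- "double"
  if (!all(dat == 0 | dat == 1))
    stop("binary mask voxels must be exactly 0 or 1")
  v <- volume(dat, affine)
  class(v) <- c("binary_mask", "volume")
  attr(v, "label") <- label
  v
}

#' @rdname binary_mask
#' @export
is_binary_mask <- function(x) inherits(x, "binary_mask")

#' Number of foreground voxels of a mask
#' @param mask A [binary_mask()].
#' @export
n_foreground <- function(mask) {
  stopifnot(is_binary_mask(mask))
  sum(mask$data)
}

#' Do two volumes share a grid?
#'
#' Same array dimensions and the same affine within `tol`.
#' @param a,b Volumes.
#' @param tol Absolute tolerance on affine entries (mm).
#' @export
same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) <= tol
}

stop_grid_mismatch <- function(a, b, what) {
  stop(sprintf(
    paste0("%s require volumes on the same grid; got %s vs %s voxels.\n",
           "Affines:\n%s\nvs\n%s\n",
           "Use resample_to_grid() to align them first."),
    what,
    paste(dim(a$data), collapse = "x"), paste(dim(b$data), collapse = "x"),
    paste(capture.output(print(signif(a$affine, 6))), collapse = "\n"),
    paste(capture.output(print(signif(b$affine, 6))), collapse = "\n")),
    call. = FALSE)
}

assert_same_grid <- function(a, b, what = "this operation") {
  if (!same_grid(a, b)) stop_grid_mismatch(a, b, what)
  invisible(TRUE)
}

#' Map 0-based voxel indices to world coordinates (mm)
#'
#' @param vol A [volume()].
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based voxel indices;
#'   fractional indices are allowed.
#' @return n x 3 matrix of world points in mm (voxel centres).
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- rbind2mat(ijk)
  h <- cbind(ijk, 1) %*% t(vol$affine)
  h[, 1:3, drop = FALSE]
}

#' Map world coordinates (mm) to continuous 0-based voxel indices
#' @inheritParams voxel_to_world
#' @param xyz n x 3 matrix (or length-3 vector) of world points in mm.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- rbind2mat(xyz)
  h <- cbind(xyz, 1) %*% t(solve(vol$affine))
  h[, 1:3, drop = FALSE]
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == 3)
  x
}

#' World coordinates of all foreground voxels
#'
#' One point per foreground voxel, at the voxel centre mapped through the
#' affine, in deterministic array (column-major: i fastest) order.
#'
#' @param mask A [binary_mask()].
#' @return n x 3 matrix of world points (mm); 0 rows for an empty mask.
#' @export
world_coords_of_foreground <- function(mask) {
  stopifnot(is_binary_mask(mask))
  idx <- which(mask$data == 1)
  if (length(idx) == 0)
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z"))))
  ijk <- arrayInd(idx, dim(mask$data)) - 1  # 0-based
  out <- voxel_to_world(mask, ijk)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Resample a volume onto a target grid
#'
#' Pull-back resampling: every target voxel centre is mapped through the
#' target affine to world space and back through the source affine; the
#' source is interpolated there. Voxels that map outside the source extent
#' are filled with 0 (background semantics). Nearest-neighbour interpolation
#' never creates values absent from the input; binary masks must use it.
#' No reorientation is ever applied implicitly.
#'
#' @param vol Source [volume()].
#' @param target A `volume`, or a list with elements `dim` (length 3) and
#'   `affine` (4x4) describing the target geometry.
#' @param mode `"nearest"` or `"linear"`. `"linear"` is rejected for binary
#'   masks (it would manufacture intermediate values).
#' @return A `volume` (a `binary_mask` when the input was one) on the target
#'   grid.
#' @export
resample_to_grid <- function(vol, target, mode = c("nearest", "linear")) {
  mode <- match.arg(mode)
  stopifnot(inherits(vol, "volume"))
  if (inherits(target, "volume")) {
    tdim <- dim(target$data); taff <- target$affine
  } else {
    tdim <- as.integer(target$dim); taff <- as.matrix(target$affine)
  }
  if (is_binary_mask(vol) && mode == "linear")
    stop("linear interpolation is not allowed for binary masks; use mode = \"nearest\"")
  # compose: target ijk (0-based, homogeneous) -> source continuous ijk
  M <- solve(vol$affine) %*% taff
  nx <- tdim[1]; ny <- tdim[2]; nz <- tdim[3]
  n <- prod(tdim)
  i <- rep.int(seq_len(nx) - 1, times = ny * nz)
  j <- rep.int(rep(seq_len(ny) - 1, each = nx), times = nz)
  k <- rep(seq_len(nz) - 1, each = nx * ny)
  sx <- M[1, 1] * i + M[1, 2] * j + M[1, 3] * k + M[1, 4]
  sy <- M[2, 1] * i + M[2, 2] * j + M[2, 3] * k + M[2, 4]
  sz <- M[3, 1] * i + M[3, 2] * j + M[3, 3] * k + M[3, 4]
  sdim <- dim(vol$data)
  out <- numeric(n)
  if (mode == "nearest") {
    ri <- round(sx); rj <- round(sy); rk <- round(sz)
    ok <- ri >= 0 & ri <= sdim[1] - 1 &
          rj >= 0 & rj <= sdim[2] - 1 &
          rk >= 0 & rk <= sdim[3] - 1
    flat <- 1 + ri[ok] + sdim[1] * (rj[ok] + sdim[2] * rk[ok])
    out[ok] <- vol$data[flat]
  } else {
    fi <- floor(sx); fj <- floor(sy); fk <- floor(sz)
    wx <- sx - fi; wy <- sy - fj; wz <- sz - fk
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      ci <- fi + di; cj <- fj + dj; ck <- fk + dk
      w <- (if (di) wx else 1 - wx) *
           (if (dj) wy else 1 - wy) *
           (if (dk) wz else 1 - wz)
      ok <- ci >= 0 & ci <= sdim[1] - 1 &
            cj >= 0 & cj <= sdim[2] - 1 &
            ck >= 0 & ck <= sdim[3] - 1 & w > 0
      if (!any(ok)) next
      flat <- 1 + ci[ok] + sdim[1] * (cj[ok] + sdim[2] * ck[ok])
      out[ok] <- out[ok] + w[ok] * vol$data[flat]
    }
  }
  res <- volume(array(out, dim = tdim), taff)
  if (is_binary_mask(vol)) res <- binary_mask(res, label = attr(vol, "label"))
  res
}

#' Grid geometry helper
#'
#' Convenience constructor for the `target` argument of
#' [resample_to_grid()].
#' @param dim Length-3 integer vector of voxel counts.
#' @param affine 4x4 voxel-to-world matrix.
#' @export
grid_geometry <- function(dim, affine = diag(4)) {
  list(dim = as.integer(dim), affine = as.matrix(affine))
}
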