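#' @name nifti-io
#' @title Minimal NIfTI-1 input/output
#'
#' @description
#' The package carries its own compact NIfTI-1 reader/writer (no NIfTI
#' package is assumed to be installed). Both `.nii` and `.nii.gz` are
#' supported through R connections. The reader honours the sform when
#' present, falls back to the qform (quaternion decoding, including qfac),
#' and finally to a diagonal pixdim affine; `scl_slope`/`scl_inter` scaling
#' is applied. Byte order is auto-detected from `sizeof_hdr`. No
#' reorientation is ever applied: data and affine are returned exactly as
#' stored, so masks and volumes from the same session stay aligned.
#'
#' The writer emits single-file NIfTI-1 (`magic "n+1"`), sform only
#' (`sform_code = 2`), data at offset 352. Integer-valued volumes round-trip
#' bit-identically; floating point volumes are stored as float64 by default
#' so round-trip error is at machine precision.
NULL

NIFTI_TYPES <- list(
  `2`   = list(name = "uint8",   size = 1L, what = "integer", signed = FALSE),
  `4`   = list(name = "int16",   size = 2L, what = "integer", signed = TRUE),
  `8`   = list(name = "int32",   size = 4L, what = "integer", signed = TRUE),
  `16`  = list(name = "float32", size = 4L, what = "numeric", signed = TRUE),
  `64`  = list(name = "float64", size = 8L, what = "numeric", signed = TRUE),
  `256` = list(name = "int8",    size = 1L, what = "integer", signed = TRUE),
  `512` = list(name = "uint16",  size = 2L, what = "integer", signed = FALSE),
  `768` = list(name = "uint32",  size = 4L, what = "integer", signed = TRUE)
)

nifti_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

rb <- function(raw, off, what, n, size, signed = TRUE, endian = "little") {
  readBin(raw[(off + 1):(off + n * size)], what = what, n = n, size = size,
          signed = signed, endian = endian)
}

# Read a NIfTI-1 file into list(data, affine); data may be n-dimensional.
read_nifti_raw <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- nifti_con(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("not a NIfTI-1 file (truncated header): ", path)
  endian <- "little"
  if (rb(hdr, 0, "integer", 1, 4, endian = endian) != 348L) {
    endian <- "big"
    if (rb(hdr, 0, "integer", 1, 4, endian = endian) != 348L)
      stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("unsupported NIfTI magic '", magic, "' in ", path)
  if (magic == "ni1")
    stop("two-file NIfTI (.hdr/.img) is not supported: ", path)

  dim8 <- rb(hdr, 40, "integer", 8, 2, endian = endian)
  nd <- dim8[1]
  if (nd < 1 || nd > 7) stop("corrupt dim[0] = ", nd, " in ", path)
  shape <- dim8[2:(nd + 1)]
  datatype <- rb(hdr, 70, "integer", 1, 2, endian = endian)
  tp <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(tp)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rb(hdr, 76, "numeric", 8, 4, endian = endian)
  vox_offset <- rb(hdr, 108, "numeric", 1, 4, endian = endian)
  scl_slope <- rb(hdr, 112, "numeric", 1, 4, endian = endian)
  scl_inter <- rb(hdr, 116, "numeric", 1, 4, endian = endian)
  qform_code <- rb(hdr, 252, "integer", 1, 2, endian = endian)
  sform_code <- rb(hdr, 254, "integer", 1, 2, endian = endian)

  if (sform_code > 0) {
    srow <- rb(hdr, 280, "numeric", 12, 4, endian = endian)
    affine <- rbind(matrix(srow, nrow = 3, byrow = TRUE), c(0, 0, 0, 1))
  } else if (qform_code > 0) {
    b <- rb(hdr, 256, "numeric", 1, 4, endian = endian)
    cc <- rb(hdr, 260, "numeric", 1, 4, endian = endian)
    d <- rb(hdr, 264, "numeric", 1, 4, endian = endian)
    off <- rb(hdr, 268, "numeric", 3, 4, endian = endian)
    a <- sqrt(max(0, 1 - b^2 - cc^2 - d^2))
    R <- rbind(
      c(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc - a * d), 2 * (b * d + a * cc)),
      c(2 * (b * cc + a * d), a^2 + cc^2 - b^2 - d^2, 2 * (cc * d - a * b)),
      c(2 * (b * d - a * cc), 2 * (cc * d + a * b), a^2 + d^2 - b^2 - cc^2))
    qfac <- if (pixdim[1] == 0) 1 else pixdim[1]
    A <- R %*% diag(c(pixdim[2], pixdim[3], pixdim[4] * qfac))
    affine <- rbind(cbind(A, off), c(0, 0, 0, 1))
  } else {
    affine <- diag(c(pixdim[2:4], 1))
  }

  # skip extension bytes up to vox_offset (we ignore extensions)
  skip <- round(vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(shape)
  dat <- readBin(con, what = tp$what, n = n, size = tp$size,
                 signed = tp$signed, endian = endian)
  if (length(dat) < n)
    stop("truncated NIfTI data payload in ", path,
         " (expected ", n, " voxels, got ", length(dat), ")")
  if (datatype == 768L) { neg <- dat < 0; dat[neg] <- dat[neg] + 2^32 }
  dat <- as.double(dat)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && (scl_inter == 0 || !is.finite(scl_inter)))) {
    dat <- dat * scl_slope + ifelse(is.finite(scl_inter), scl_inter, 0)
  }
  list(data = array(dat, dim = shape), affine = affine,
       datatype = tp$name)
}

#' Read a 3D NIfTI volume
#'
#' 4D images with a trailing singleton dimension (x, y, z, 1) are squeezed
#' to 3D with a message; any other 4D (or higher) shape is an error, since
#' silently picking a frame is how masks and volumes get misaligned. Use
#' [read_ensemble()] for genuine 4D probability stacks.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [volume()].
#' @export
read_volume <- function(path) {
  raw <- read_nifti_raw(path)
  shape <- dim(raw$data)
  if (length(shape) == 4 && shape[4] == 1) {
    message("squeezing trailing singleton dimension of ", path,
            " (", paste(shape, collapse = "x"), " -> 3D)")
    raw$data <- array(raw$data, dim = shape[1:3])
    shape <- shape[1:3]
  }
  if (length(shape) != 3)
    stop("expected a 3D image, got ", paste(shape, collapse = "x"),
         " in ", path, "; 4D ensembles must be read with read_ensemble()")
  volume(raw$data, raw$affine)
}

nifti_datatype_for <- function(data, datatype) {
  if (datatype != "auto") return(datatype)
  if (all(data == round(data))) {
    if (min(data) >= 0 && max(data) <= 255) return("uint8")
    if (min(data) >= -32768 && max(data) <= 32767) return("int16")
    if (min(data) >= -2^31 && max(data) <= 2^31 - 1) return("int32")
  }
  "float64"
}

write_nifti_raw <- function(data, affine, path, datatype = "auto") {
  dt <- nifti_datatype_for(data, datatype)
  code <- switch(dt, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stop("unsupported write datatype: ", dt))
  tp <- NIFTI_TYPES[[as.character(code)]]
  shape <- dim(data)
  nd <- length(shape)
  dim8 <- integer(8); dim8[1] <- nd; dim8[2:(nd + 1)] <- shape
  dim8[(nd + 2):8] <- 1L
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  pixdim <- numeric(8); pixdim[1] <- 1; pixdim[2:4] <- sp
  if (nd >= 4) pixdim[5] <- 1

  con <- nifti_con(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(348L, con, size = 4, endian = "little")            # sizeof_hdr
  writeBin(raw(36), con)                                      # unused (4..39)
  writeBin(as.integer(dim8), con, size = 2, endian = "little")# dim
  writeBin(numeric(3), con, size = 4, endian = "little")      # intent_p1..3
  writeBin(0L, con, size = 2, endian = "little")              # intent_code
  writeBin(code, con, size = 2, endian = "little")            # datatype
  writeBin(as.integer(tp$size * 8), con, size = 2, endian = "little") # bitpix
  writeBin(0L, con, size = 2, endian = "little")              # slice_start
  writeBin(pixdim, con, size = 4, endian = "little")          # pixdim
  writeBin(352, con, size = 4, endian = "little")             # vox_offset
  writeBin(1, con, size = 4, endian = "little")               # scl_slope
  writeBin(0, con, size = 4, endian = "little")               # scl_inter
  writeBin(0L, con, size = 2, endian = "little")              # slice_end
  writeBin(as.raw(c(0, 2)), con)                              # slice_code, xyzt_units = mm
  writeBin(numeric(4), con, size = 4, endian = "little")      # cal_max..toffset
  writeBin(integer(2), con, size = 4, endian = "little")      # glmax, glmin
  desc <- charToRaw("cstconcord")
  writeBin(c(desc, raw(80 - length(desc))), con)              # descrip
  writeBin(raw(24), con)                                      # aux_file
  writeBin(c(0L, 2L), con, size = 2, endian = "little")       # qform=0, sform=2
  writeBin(numeric(6), con, size = 4, endian = "little")      # quatern/qoffset
  srow <- as.numeric(t(affine[1:3, ]))
  writeBin(srow, con, size = 4, endian = "little")            # srow_x/y/z
  writeBin(raw(16), con)                                      # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)               # magic
  writeBin(raw(4), con)                                       # no extensions
  dat <- as.vector(data)
  if (tp$what == "integer") {
    writeBin(as.integer(dat), con, size = tp$size, endian = "little")
  } else {
    writeBin(as.double(dat), con, size = tp$size, endian = "little")
  }
  invisible(path)
}

#' Write a volume as NIfTI-1
#'
#' @param vol A [volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param datatype `"auto"` (uint8/int16/int32 for integer-valued data,
#'   float64 otherwise) or one of `"uint8"`, `"int16"`, `"int32"`,
#'   `"float32"`, `"float64"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "auto") {
  stopifnot(inherits(vol, "volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir)
  write_nifti_raw(vol$data, vol$affine, path, datatype)
  invisible(path)
}

#' Read a probability ensemble
#'
#' Accepts either a directory containing one 3D NIfTI per stochastic pass
#' (sorted by filename) or a single 4D NIfTI with the passes along the 4th
#' axis.
#'
#' @param path Directory or 4D NIfTI file.
#' @return A [probability_ensemble()].
#' @export
read_ensemble <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.nii(\\.gz)?$",
                             full.names = TRUE))
    if (length(files) == 0) stop("no NIfTI files found in ", path)
    return(probability_ensemble(lapply(files, read_volume)))
  }
  raw <- read_nifti_raw(path)
  shape <- dim(raw$data)
  if (length(shape) != 4)
    stop("expected a 4D NIfTI or a directory of 3D files: ", path)
  members <- lapply(seq_len(shape[4]), function(t)
    volume(array(raw$data[, , , t], dim = shape[1:3]), raw$affine))
  probability_ensemble(members)
}

#' Write a probability ensemble as one 4D NIfTI
#' @param ens A [probability_ensemble()].
#' @param path Output path (`.nii`/`.nii.gz`).
#' @param datatype Passed to the writer; default float32 keeps files small
#'   (probabilities need < 1e-6 absolute precision only).
#' @export
write_ensemble <- function(ens, path, datatype = "float32") {
  stopifnot(inherits(ens, "probability_ensemble"))
  shape <- dim(ens$members[[1]]$data)
  arr <- array(0, c(shape, ens$T))
  for (t in seq_len(ens$T)) arr[, , , t] <- ens$members[[t]]$data
  write_nifti_raw(arr, ens$members[[1]]$affine, path, datatype)
  invisible(path)
}
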