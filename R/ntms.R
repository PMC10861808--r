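#' @name ntms-masks
#' @title nTMS motor-response masks
#'
#' @description
#' Motor evoked potentials recorded during navigated transcranial magnetic
#' stimulation (nTMS) are turned into three class-labelled binary masks on
#' the 1 mm isotropic export grid:
#' \describe{
#'   \item{`+M1+`}{positive responses (amplitude >= 50 uV) inside the
#'     primary motor cortex (M1) mask,}
#'   \item{`-M1+`}{positive responses outside M1,}
#'   \item{`-M1-`}{negative responses (amplitude < 50 uV) outside M1.}
#' }
#' Negative responses inside M1 are excluded (their interpretation is
#' biased, usually by muscles not mapped), as are responses with latency
#' outside the physiological hand-muscle window of 18-26 ms (inclusive).
#' Raw vendor exports additionally carry anatomical-landmark annotations
#' which are removed with the intracranial mask, and the final masks are
#' restricted to white-matter voxels.
NULL

RESPONSE_CLASSES <- c("+M1+", "-M1+", "-M1-")

#' Classify one stimulation response
#'
#' Total classification: every record maps to exactly one of `"+M1+"`,
#' `"-M1+"`, `"-M1-"` or `"excluded"`. A position falling outside the M1
#' volume's extent is excluded with a warning, since it signals a
#' registration problem upstream.
#'
#' @param rec A list/row with fields `x_mm`, `y_mm`, `z_mm` (world
#'   position), `amplitude_uv` (>= 0) and `latency_ms` (>= 0).
#' @param m1 [binary_mask()] of the primary motor cortex.
#' @param amp_threshold Positivity threshold in uV; amplitude greater than
#'   or equal to it is a positive response. Default 50.
#' @param latency_window Inclusive physiological latency window in ms;
#'   default `c(18, 26)`.
#' @return One of `"+M1+"`, `"-M1+"`, `"-M1-"`, `"excluded"`.
#' @export
classify_response <- function(rec, m1, amp_threshold = 50,
                              latency_window = c(18, 26)) {
  stopifnot(is_binary_mask(m1))
  amp <- rec$amplitude_uv; lat <- rec$latency_ms
  if (!is.finite(amp) || !is.finite(lat) || amp < 0 || lat < 0)
    stop("amplitude and latency must be finite and non-negative")
  if (lat < latency_window[1] || lat > latency_window[2]) return("excluded")
  ijk <- round(world_to_voxel(m1, c(rec$x_mm, rec$y_mm, rec$z_mm)))
  d <- dim(m1$data)
  if (any(ijk < 0) || any(ijk > d - 1)) {
    warning(sprintf(
      "response position (%.1f, %.1f, %.1f) mm falls outside the M1 volume; excluded (check registration)",
      rec$x_mm, rec$y_mm, rec$z_mm))
    return("excluded")
  }
  in_m1 <- m1$data[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1] == 1
  positive <- amp >= amp_threshold
  if (positive && in_m1) return("+M1+")
  if (positive && !in_m1) return("-M1+")
  if (!positive && !in_m1) return("-M1-")
  "excluded"  # negative inside M1
}

#' Threshold a raw nTMS export volume
#'
#' The vendor export encodes responses as positive intensities; every voxel
#' strictly greater than zero becomes foreground.
#'
#' @param raw_export A [volume()].
#' @return A [binary_mask()].
#' @export
threshold_export <- function(raw_export) {
  stopifnot(inherits(raw_export, "volume"))
  binary_mask((raw_export$data > 0) + 0, raw_export$affine,
              label = "response")
}

#' Remove anatomical-landmark annotations
#'
#' Vendor exports include registration landmarks (nasion, ears) outside the
#' head; intersecting with the intracranial mask removes them. Pure
#' voxelwise AND, so the foreground can only shrink.
#'
#' @param responses,intracranial [binary_mask()]s on the same grid.
#' @return A [binary_mask()].
#' @export
remove_landmarks <- function(responses, intracranial) {
  mask_and(responses, intracranial, "remove_landmarks")
}

#' Restrict responses to white matter
#'
#' Keeps response voxels inside the white-matter mask (voxelwise AND); this
#' is the reading consistent with the later distance-to-tract analysis.
#' `keep_in_wm = FALSE` gives the complementary reading (drop WM voxels).
#'
#' @param responses,wm [binary_mask()]s on the same grid.
#' @param keep_in_wm Keep (default) or remove WM voxels.
#' @return A [binary_mask()].
#' @export
wm_filter <- function(responses, wm, keep_in_wm = TRUE) {
  if (keep_in_wm) return(mask_and(responses, wm, "wm_filter"))
  assert_same_grid(responses, wm, "wm_filter")
  binary_mask(responses$data * (1 - wm$data), responses$affine,
              label = attr(responses, "label"))
}

mask_and <- function(a, b, what) {
  stopifnot(is_binary_mask(a), is_binary_mask(b))
  assert_same_grid(a, b, what)
  binary_mask(a$data * b$data, a$affine, label = attr(a, "label"))
}

#' Rasterize classified responses onto a grid
#'
#' With `radius = 0` the single voxel whose centre is nearest each response
#' point is set; with `radius > 0` every voxel whose centre lies within
#' `radius` mm of the point is set (the vendor export footprint is not
#' standardised, so the footprint is configurable). Rasterization is
#' idempotent: coincident records share voxels, while `n_responses` counts
#' records.
#'
#' @param records Data frame with columns `x_mm`, `y_mm`, `z_mm`, all of
#'   one class.
#' @param grid A [volume()] or [grid_geometry()] giving the 1 mm target
#'   grid.
#' @param klass Class label, one of `"+M1+"`, `"-M1+"`, `"-M1-"`.
#' @param radius Footprint radius in mm (default 0).
#' @return A `response_mask`: list with `mask` ([binary_mask()]), `klass`,
#'   `n_responses`.
#' @export
rasterize_responses <- function(records, grid, klass, radius = 0) {
  klass <- match.arg(klass, RESPONSE_CLASSES)
  if (inherits(grid, "volume")) {
    gdim <- dim(grid$data); gaff <- grid$affine
  } else {
    gdim <- grid$dim; gaff <- grid$affine
  }
  ref <- volume(array(0, gdim), gaff)
  dat <- array(0, gdim)
  n <- if (is.null(records)) 0L else nrow(records)
  if (n > 0) {
    pts <- as.matrix(records[, c("x_mm", "y_mm", "z_mm")])
    if (radius <= 0) {
      ijk <- round(world_to_voxel(ref, pts))
      ok <- ijk[, 1] >= 0 & ijk[, 1] <= gdim[1] - 1 &
            ijk[, 2] >= 0 & ijk[, 2] <= gdim[2] - 1 &
            ijk[, 3] >= 0 & ijk[, 3] <= gdim[3] - 1
      if (any(!ok))
        warning(sum(!ok), " response(s) fall outside the grid; dropped")
      dat[1 + ijk[ok, 1] + gdim[1] * (ijk[ok, 2] + gdim[2] * ijk[ok, 3])] <- 1
    } else {
      sp <- spacing(ref)
      half <- ceiling(radius / sp)
      for (r in seq_len(n)) {
        c_ijk <- world_to_voxel(ref, pts[r, ])
        lo <- pmax(floor(c_ijk - half), 0)
        hi <- pmin(ceiling(c_ijk + half), gdim - 1)
        if (any(lo > hi)) next
        ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
        box <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
        ctr <- voxel_to_world(ref, box)
        d2 <- rowSums((ctr - matrix(pts[r, ], nrow(ctr), 3,
                                    byrow = TRUE))^2)
        sel <- box[d2 <= radius^2, , drop = FALSE]
        if (nrow(sel))
          dat[1 + sel[, 1] + gdim[1] * (sel[, 2] + gdim[2] * sel[, 3])] <- 1
      }
    }
  }
  structure(list(mask = binary_mask(dat, gaff, label = "response"),
                 klass = klass, n_responses = n),
            class = "response_mask")
}

#' @export
print.response_mask <- function(x, ...) {
  cat(sprintf("<response_mask> class %s: %d records, %d foreground voxels\n",
              x$klass, x$n_responses, n_foreground(x$mask)))
  invisible(x)
}

#' Build the three classified response masks for one subject
#'
#' End-to-end per-subject construction: classify every record (excluding
#' manually curated ones), rasterize per class, remove landmarks with the
#' intracranial mask and restrict to white matter when those masks are
#' given. The three masks are pairwise disjoint by construction since each
#' record maps to exactly one class.
#'
#' @param records Data frame with columns `x_mm`, `y_mm`, `z_mm`,
#'   `amplitude_uv`, `latency_ms` and optionally `manually_excluded`
#'   (0/1 flag for human curation of false positives/negatives).
#' @param m1 M1 [binary_mask()].
#' @param grid Target 1 mm grid ([volume()] or [grid_geometry()]); defaults
#'   to the M1 grid.
#' @param intracranial,wm Optional [binary_mask()]s applied as
#'   [remove_landmarks()] and [wm_filter()].
#' @param amp_threshold,latency_window,radius See [classify_response()] and
#'   [rasterize_responses()].
#' @return Named list of three `response_mask` objects
#'   (`"+M1+"`, `"-M1+"`, `"-M1-"`).
#' @export
build_response_masks <- function(records, m1, grid = m1,
                                 intracranial = NULL, wm = NULL,
                                 amp_threshold = 50,
                                 latency_window = c(18, 26),
                                 radius = 0) {
  if (!is.null(records$manually_excluded))
    records <- records[!(records$manually_excluded %in% 1), , drop = FALSE]
  klass <- character(nrow(records))
  for (r in seq_len(nrow(records)))
    klass[r] <- classify_response(records[r, ], m1, amp_threshold,
                                  latency_window)
  out <- lapply(RESPONSE_CLASSES, function(kl) {
    rm <- rasterize_responses(records[klass == kl, , drop = FALSE],
                              grid, kl, radius)
    if (!is.null(intracranial))
      rm$mask <- remove_landmarks(rm$mask, intracranial)
    if (!is.null(wm)) rm$mask <- wm_filter(rm$mask, wm)
    rm
  })
  names(out) <- RESPONSE_CLASSES
  out
}
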