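#' Euclidean distance map to a binary mask
#'
#' Per-voxel Euclidean distance in mm to the nearest foreground voxel
#' centre (0 on foreground), honouring anisotropic voxel spacing. Computed
#' with the exact separable lower-envelope distance transform in C++.
#' For voxels outside the mask this equals the distance to the mask
#' boundary; voxels inside the mask get 0 (unsigned convention — the
#' response-versus-tract analysis only reads distances outside the tract).
#'
#' @param tract A non-empty [binary_mask()].
#' @return A [volume()] of distances (mm), class also `distance_map`.
#' @export
distance_map <- function(tract) {
  stopifnot(is_binary_mask(tract))
  if (n_foreground(tract) == 0)
    stop("distance to an empty mask is undefined")
  d2 <- edt_sq_cpp(as.integer(tract$data != 0), dim(tract$data),
                   spacing(tract))
  out <- volume(array(sqrt(d2), dim = dim(tract$data)), tract$affine)
  class(out) <- c("distance_map", class(out))
  out
}

# signed distance in mm: negative inside the mask, positive outside.
# Foreground voxels take -(distance to nearest background voxel centre),
# background voxels +(distance to nearest foreground voxel centre); the
# magnitude is therefore >= 1 voxel everywhere (no zero level set on the
# grid), which keeps strict thresholding of sigmoid profiles faithful to
# the generating mask.
signed_distance <- function(mask) {
  stopifnot(is_binary_mask(mask))
  fg <- mask$data != 0
  dims <- dim(mask$data); sp <- spacing(mask)
  d_out <- sqrt(edt_sq_cpp(as.integer(fg), dims, sp))
  d_in <- sqrt(edt_sq_cpp(as.integer(!fg), dims, sp))
  volume(array(d_out - d_in, dim = dims), mask$affine)
}

#' Pair uncertainty with distance at response voxels
#'
#' One (u, d) pair per foreground voxel of the response mask: the
#' segmentation uncertainty and the distance to the tract mask, both
#' sampled at the response voxel itself, in deterministic array order.
#'
#' @param unc Uncertainty [volume()].
#' @param dist Distance [volume()] (from [distance_map()]).
#' @param responses A `response_mask` (from [rasterize_responses()]) or a
#'   bare [binary_mask()].
#' @return Data frame with columns `u`, `d` and `klass`.
#' @export
pair_uncertainty_distance <- function(unc, dist, responses) {
  mask <- if (inherits(responses, "response_mask")) responses$mask
          else responses
  klass <- if (inherits(responses, "response_mask")) responses$klass
           else NA_character_
  assert_same_grid(unc, dist, "pair_uncertainty_distance")
  u <- sample_at_mask(unc, mask)
  d <- sample_at_mask(dist, mask)
  data.frame(u = u, d = d,
             klass = rep(klass, length(u)),
             stringsAsFactors = FALSE)
}

#' Binned joint histogram of uncertainty versus distance
#'
#' Equal-width bins on the distance axis spanning \[0, max(d)\]; bins are
#' right-open except the last, so every pair falls in exactly one bin.
#' Per-bin mean and population standard deviation of the uncertainty
#' (the error bars of the familiar summary figure); empty bins are
#' reported with count 0 and NA statistics, never fabricated.
#'
#' @param pairs Data frame with columns `u` and `d` (>= 1 row).
#' @param n_bins Number of distance bins; default 30.
#' @return Object of class `joint_histogram`: list with `edges`
#'   (length n_bins + 1) and a data frame `bins` (columns `bin_lo_mm`,
#'   `bin_hi_mm`, `count`, `mean_unc`, `std_unc`).
#' @export
joint_histogram <- function(pairs, n_bins = 30) {
  if (nrow(pairs) < 1) stop("need at least one (u, d) pair")
  if (n_bins < 1) stop("n_bins must be >= 1")
  d <- pairs$d; u <- pairs$u
  dmax <- max(d); dmin <- 0
  if (dmax == min(d)) {
    warning("all distances identical; returning a single degenerate bin")
    edges <- c(min(d), min(d) + 1e-9)
    idx <- rep(1L, length(d))
    n_bins <- 1L
  } else {
    edges <- seq(dmin, dmax, length.out = n_bins + 1)
    width <- (dmax - dmin) / n_bins
    idx <- pmin(floor((d - dmin) / width) + 1L, n_bins)  # last bin closed
  }
  count <- tabulate(idx, nbins = n_bins)
  mean_unc <- rep(NA_real_, n_bins)
  std_unc <- rep(NA_real_, n_bins)
  for (b in which(count > 0)) {
    ub <- u[idx == b]
    mean_unc[b] <- mean(ub)
    std_unc[b] <- sqrt(mean((ub - mean(ub))^2))  # population sd; 0 for singletons
  }
  structure(list(
    edges = edges,
    bins = data.frame(bin_lo_mm = edges[-length(edges)],
                      bin_hi_mm = edges[-1],
                      count = count, mean_unc = mean_unc,
                      std_unc = std_unc)),
    class = "joint_histogram")
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat(sprintf("<joint_histogram> %d bins over [%.2f, %.2f] mm, %d pairs\n",
              nrow(x$bins), x$edges[1], x$edges[length(x$edges)],
              sum(x$bins$count)))
  invisible(x)
}

#' Uncertainty-distance correlation analysis
#'
#' The full second-experiment summary for a set of (u, d) pairs: the
#' 30-bin joint histogram, pooled Spearman rho/p over all pairs, the
#' bin-mean Spearman (rho over the per-bin mean uncertainties, for readers
#' of the histogram rather than the cloud), and the OLS linear trend.
#'
#' @param pairs Data frame with columns `u`, `d`.
#' @param n_bins Bins for the histogram (default 30).
#' @return List: `histogram`, `pooled` (rho/p/n), `binned` (rho/p/n over
#'   non-empty bin means, NULL when fewer than 3 such bins), `trend`
#'   (slope/intercept).
#' @export
uncertainty_distance_analysis <- function(pairs, n_bins = 30) {
  hist <- joint_histogram(pairs, n_bins)
  pooled <- spearman_cor(pairs$u, pairs$d)
  nb <- hist$bins[hist$bins$count > 0, ]
  binned <- NULL
  if (nrow(nb) >= 3 && stats::var(nb$mean_unc) > 0) {
    mids <- (nb$bin_lo_mm + nb$bin_hi_mm) / 2
    binned <- spearman_cor(nb$mean_unc, mids)
  }
  trend <- linear_trend(pairs$u, pairs$d)
  list(histogram = hist, pooled = pooled, binned = binned, trend = trend)
}
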