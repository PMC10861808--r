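#' Stochastic segmentation probability ensemble
#'
#' Holds the T probability volumes produced by stochastic inference passes
#' (test-time dropout and/or augmentation) of a segmentation model, all on
#' one shared grid. The networks themselves are out of scope: the ensemble
#' is consumed as given probability maps (one per pass, T = 20 in the
#' reference protocol).
#'
#' @param members List of [volume()]s with voxel values in \[0, 1\].
#' @return Object of class `probability_ensemble` with fields `members`
#'   and `T`.
#' @export
probability_ensemble <- function(members) {
  if (!is.list(members) || length(members) < 1)
    stop("`members` must be a non-empty list of volumes (T >= 1)")
  if (!all(vapply(members, inherits, logical(1), "volume")))
    stop("all ensemble members must be volumes")
  ref <- members[[1]]
  for (m in members[-1]) assert_same_grid(ref, m, "probability ensembles")
  for (i in seq_along(members)) {
    rng <- range(members[[i]]$data)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      stop(sprintf("member %d has values outside [0, 1]: range [%g, %g]",
                   i, rng[1], rng[2]))
  }
  structure(list(members = members, T = length(members)),
            class = "probability_ensemble")
}

#' @export
print.probability_ensemble <- function(x, ...) {
  cat(sprintf("<probability_ensemble> T = %d members, %s voxels\n",
              x$T, paste(dim(x$members[[1]]$data), collapse = "x")))
  invisible(x)
}

#' Voxelwise mean of an ensemble
#'
#' The arithmetic mean probability across the T members; this is the map
#' that gets thresholded at 0.5 to obtain the binary tract mask.
#'
#' @param ens A [probability_ensemble()].
#' @return A [volume()] of probabilities.
#' @export
ensemble_mean <- function(ens) {
  stopifnot(inherits(ens, "probability_ensemble"))
  acc <- ens$members[[1]]$data
  if (ens$T > 1) for (t in 2:ens$T) acc <- acc + ens$members[[t]]$data
  volume(acc / ens$T, ens$members[[1]]$affine)
}

#' Threshold a probability volume into a binary mask
#'
#' Strictly-greater comparison: a voxel exactly at `tau` is background.
#' "Threshold at 0.5" does not fix the tie case, so the strict rule is
#' adopted and documented; it only matters on sets of measure zero for
#' continuous probabilities.
#'
#' @param prob [volume()] with values in \[0, 1\].
#' @param tau Threshold in \[0, 1\]; default 0.5.
#' @return A [binary_mask()].
#' @export
binarize <- function(prob, tau = 0.5) {
  stopifnot(inherits(prob, "volume"))
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0 || tau > 1)
    stop("`tau` must be a single probability in [0, 1]")
  binary_mask((prob$data > tau) + 0, prob$affine, label = "tract")
}

#' Voxelwise uncertainty of an ensemble
#'
#' Two standard summaries of the spread of the T stochastic passes:
#' \describe{
#'   \item{`std`}{population standard deviation across members (divide by
#'     T, not T-1: the passes are the full ensemble, not a sample).}
#'   \item{`entropy`}{binary entropy of the ensemble mean,
#'     \eqn{-p \log_2 p - (1-p)\log_2(1-p)} with \eqn{0 \log 0 := 0};
#'     bounded by 1 bit.}
#' }
#' The downstream distance-correlation analysis is estimator-agnostic; the
#' choice is recorded in the `estimator` attribute and in pipeline reports.
#'
#' @param ens A [probability_ensemble()].
#' @param estimator `"std"` (default, requires T >= 2) or `"entropy"`.
#' @return A [volume()] of non-negative uncertainties with attribute
#'   `estimator`.
#' @export
uncertainty_map <- function(ens, estimator = c("std", "entropy")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(ens, "probability_ensemble"))
  m <- ensemble_mean(ens)
  if (estimator == "std") {
    if (ens$T < 2)
      stop("std uncertainty needs T >= 2 members (got T = ", ens$T, ")")
    acc <- (ens$members[[1]]$data - m$data)^2
    for (t in 2:ens$T) acc <- acc + (ens$members[[t]]$data - m$data)^2
    u <- sqrt(acc / ens$T)
  } else {
    p <- m$data
    u <- array(0, dim = dim(p))
    inner <- p > 0 & p < 1
    pi_ <- p[inner]
    u[inner] <- -pi_ * log2(pi_) - (1 - pi_) * log2(1 - pi_)
  }
  out <- volume(u, m$affine)
  attr(out, "estimator") <- estimator
  out
}

#' Sample a scalar field at mask foreground voxels
#'
#' One value per foreground voxel of `where`, in deterministic array
#' (column-major) order — the same order as
#' [world_coords_of_foreground()].
#'
#' @param field A [volume()] (e.g. uncertainty or distance map).
#' @param where A [binary_mask()] on the same grid.
#' @return Numeric vector, length = foreground count.
#' @export
sample_at_mask <- function(field, where) {
  stopifnot(inherits(field, "volume"), is_binary_mask(where))
  assert_same_grid(field, where, "sample_at_mask")
  field$data[which(where$data == 1)]
}
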