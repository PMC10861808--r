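#' Phantom cohort specification
#'
#' Parameters of the synthetic world used to exercise the full pipeline in
#' the absence of shareable clinical data. The phantom emulates, at 1 mm
#' isotropic resolution: a tubular tract mask along a smooth random curve
#' (fanning near the top, like a corticospinal tract approaching the motor
#' cortex), an ensemble of T stochastic probability maps whose variability
#' concentrates near the mask boundary, and three response classes whose
#' distance-to-tract distributions are ordered +M1+ < -M1+ < -M1-.
#'
#' All numeric defaults are emulation parameters of the synthetic world
#' (the clinical protocol fixes only T = 20 passes, the 1 mm grid and the
#' qualitative class geometry); they are exposed here and stamped into
#' generated metadata.
#'
#' @param grid_shape Voxel counts, default `c(96, 96, 96)`.
#' @param spacing Isotropic voxel size in mm, default 1.
#' @param tube_radius Tract tube radius in mm, default 4.
#' @param fan_radius Radius at the top of the tract (cortical fanning),
#'   default 8 mm.
#' @param fan_frac Fraction of the track length (from the top) over which
#'   the radius widens, default 0.2.
#' @param boundary_tau Sigmoid softness of the probability profile across
#'   the tract surface, in mm; default 1.5.
#' @param ensemble_T Number of stochastic passes, default 20.
#' @param deform_sigma Amplitude (mm, sd) of the smooth random displacement
#'   applied to the signed distance field per pass; default 1.
#' @param deform_smoothness Correlation length (mm, Gaussian sd) of the
#'   displacement field; default 6.
#' @param noise_sigma Voxelwise probability noise sd per pass (clipped to
#'   \[0, 1\]); default 0.05.
#' @param n_responses Stimulation responses per class, default 15.
#' @param class_distances Named list of `c(mean, sd)` in mm for the
#'   distance-to-tract targets: `+M1+` draws |Normal(0, 2)|, `-M1+`
#'   Normal(6, 2) truncated at 0, `-M1-` Normal(14, 4) truncated at 0.
#' @param seed Integer master seed; identical spec + seed gives
#'   bit-identical phantoms.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96), spacing = 1,
                         tube_radius = 4, fan_radius = 8, fan_frac = 0.2,
                         boundary_tau = 1.5, ensemble_T = 20,
                         deform_sigma = 1, deform_smoothness = 6,
                         noise_sigma = 0.05, n_responses = 15,
                         class_distances = list(
                           `+M1+` = c(0, 2),
                           `-M1+` = c(6, 2),
                           `-M1-` = c(14, 4)),
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape), spacing = spacing,
               tube_radius = tube_radius, fan_radius = fan_radius,
               fan_frac = fan_frac, boundary_tau = boundary_tau,
               ensemble_T = as.integer(ensemble_T),
               deform_sigma = deform_sigma,
               deform_smoothness = deform_smoothness,
               noise_sigma = noise_sigma,
               n_responses = as.integer(n_responses),
               class_distances = class_distances,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  pos <- c("spacing", "tube_radius", "fan_radius", "boundary_tau",
           "deform_smoothness")
  for (f in pos) if (spec[[f]] <= 0) stop("`", f, "` must be > 0")
  if (spec$deform_sigma < 0 || spec$noise_sigma < 0)
    stop("noise amplitudes must be >= 0")
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 8))
    stop("grid_shape must be 3 values, each >= 8")
  if (spec$fan_radius < spec$tube_radius)
    stop("fan_radius must be >= tube_radius")
  cd <- spec$class_distances
  if (!all(RESPONSE_CLASSES %in% names(cd)))
    stop("class_distances must name all of ", paste(RESPONSE_CLASSES,
                                                    collapse = ", "))
  mu <- vapply(cd[RESPONSE_CLASSES], `[`, numeric(1), 1)
  if (!(mu[1] < mu[2] && mu[2] < mu[3]))
    stop("class distance means must be ordered +M1+ < -M1+ < -M1-")
  if (any(vapply(cd, `[`, numeric(1), 2) < 0))
    stop("class distance sds must be >= 0")
  half_extent <- min(spec$grid_shape[1:2]) / 2 * spec$spacing
  if (spec$fan_radius + 3 > half_extent)
    stop("radii too large for the grid (fan_radius + margin exceeds ",
         "half the in-plane extent)")
  invisible(spec)
}

# run expr with a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed %% 2147483647)
  eval.parent(substitute(expr))
}

phantom_affine <- function(spec) diag(c(rep(spec$spacing, 3), 1))

# world-coordinate arrays of the phantom grid (voxel centres, mm)
phantom_coords <- function(spec) {
  d <- spec$grid_shape; sp <- spec$spacing
  list(x = array(rep((0:(d[1] - 1)) * sp, times = d[2] * d[3]), d),
       y = array(rep(rep((0:(d[2] - 1)) * sp, each = d[1]),
                     times = d[3]), d),
       z = array(rep((0:(d[3] - 1)) * sp, each = d[1] * d[2]), d))
}

#' Generate a synthetic tract mask
#'
#' A connected tube following a smooth random centreline from the bottom to
#' the top face of the grid, with radius `tube_radius` widening linearly to
#' `fan_radius` over the top `fan_frac` of the track. The mask is the
#' sub-zero level set of min over centreline samples of
#' (distance to sample - local radius).
#'
#' @param spec A [phantom_spec()].
#' @param centerline Optional override: a function of `t` in \[0, 1\]
#'   returning a length-2 vector `(x, y)` in mm (used e.g. for a straight
#'   cylinder whose volume is known analytically).
#' @return A [binary_mask()] with attribute `centerline` (sampled n x 3
#'   matrix, mm).
#' @export
generate_tract <- function(spec, centerline = NULL) {
  validate_phantom_spec(spec)
  d <- spec$grid_shape; sp <- spec$spacing
  with_seed(spec$seed, {
    cx0 <- (d[1] - 1) * sp / 2
    cy0 <- (d[2] - 1) * sp / 2
    margin <- spec$fan_radius + 2
    amp_budget <- min(d[1], d[2]) / 2 * sp - margin
    if (amp_budget <= 0) stop("radii too large for the grid")
    amp <- pmin(runif(4, 1, 4), amp_budget / 2)
    freq <- runif(4, 0.4, 1.2)
    phase <- runif(4, 0, 2 * pi)
    cl_fun <- if (is.null(centerline)) {
      function(t) cbind(
        cx0 + amp[1] * sin(2 * pi * freq[1] * t + phase[1]) +
              amp[2] * sin(2 * pi * freq[2] * t + phase[2]),
        cy0 + amp[3] * sin(2 * pi * freq[3] * t + phase[3]) +
              amp[4] * sin(2 * pi * freq[4] * t + phase[4]))
    } else {
      function(t) {
        xy <- t(vapply(t, centerline, numeric(2)))
        cbind(xy[, 1], xy[, 2])
      }
    }
    ns <- ceiling(1.5 * d[3])
    tt <- seq(0, 1, length.out = ns)
    cl <- cl_fun(tt)
    clz <- tt * (d[3] - 1) * sp
    rr <- rep(spec$tube_radius, ns)
    ramp <- tt > 1 - spec$fan_frac
    if (any(ramp))
      rr[ramp] <- spec$tube_radius +
        (spec$fan_radius - spec$tube_radius) *
        (tt[ramp] - (1 - spec$fan_frac)) / spec$fan_frac
    g <- phantom_coords(spec)
    best <- array(Inf, d)
    for (s in seq_len(ns)) {
      val <- sqrt((g$x - cl[s, 1])^2 + (g$y - cl[s, 2])^2 +
                  (g$z - clz[s])^2) - rr[s]
      best <- pmin(best, val)
    }
    mask <- binary_mask((best <= 0) + 0, phantom_affine(spec),
                        label = "tract")
    if (n_foreground(mask) == 0) stop("degenerate phantom: empty tract")
    attr(mask, "centerline") <- cbind(cl, clz)
    mask
  })
}

# Fourier transform of a (wrapped) Gaussian smoothing kernel
gauss_kernel_fft <- function(dims, spacing, smoothness_mm) {
  sig <- smoothness_mm / spacing  # in voxels
  k1 <- function(n) {
    x <- 0:(n - 1)
    dmin <- pmin(x, n - x)
    k <- exp(-dmin^2 / (2 * sig^2))
    k / sum(k)
  }
  K <- outer(outer(k1(dims[1]), k1(dims[2])), k1(dims[3]))
  stats::fft(K)
}

standardise_field <- function(sm) {
  s <- stats::sd(sm)
  if (s == 0) return(array(0, dim(sm)))
  sm / s
}

# smooth unit-variance random field: white noise convolved with a Gaussian
# kernel (FFT), then standardised
smooth_noise_field <- function(dims, spacing, smoothness_mm) {
  noise <- array(stats::rnorm(prod(dims)), dims)
  Kf <- gauss_kernel_fft(dims, spacing, smoothness_mm)
  sm <- Re(stats::fft(stats::fft(noise) * Kf, inverse = TRUE)) / prod(dims)
  standardise_field(sm)
}

# two independent smooth fields from one FFT round trip: convolution with a
# real kernel acts separately on the real and imaginary parts of a complex
# white-noise pack, so smoothing a + i*b smooths both at once
smooth_noise_pair <- function(dims, Kf) {
  n <- prod(dims)
  pack <- array(complex(real = stats::rnorm(n),
                        imaginary = stats::rnorm(n)), dims)
  sm <- stats::fft(stats::fft(pack) * Kf, inverse = TRUE) / n
  list(standardise_field(Re(sm)), standardise_field(Im(sm)))
}

#' Generate a stochastic probability ensemble for a tract
#'
#' Each of the T members is a sigmoid profile of the tract's signed
#' distance field, `plogis(-(sd + delta_t) / tau)`, where `delta_t` is an
#' independent smooth random displacement (Gaussian-correlated field,
#' sd `deform_sigma` mm) and voxelwise probability noise
#' (sd `noise_sigma`, clipped to \[0, 1\]) is added. By construction the
#' across-member standard deviation concentrates within roughly
#' `2 * (boundary_tau + deform_sigma)` mm of the tract surface.
#'
#' @param tract A [binary_mask()] from [generate_tract()].
#' @param spec A [phantom_spec()] (needs `ensemble_T >= 2`).
#' @return A [probability_ensemble()].
#' @export
generate_ensemble <- function(tract, spec) {
  validate_phantom_spec(spec)
  if (spec$ensemble_T < 2) stop("ensemble_T must be >= 2")
  sdist <- signed_distance(tract)$data
  sp <- spacing(tract)[1]
  with_seed(spec$seed + 1L, {
    dims <- dim(sdist)
    fields <- vector("list", spec$ensemble_T)
    if (spec$deform_sigma > 0) {
      Kf <- gauss_kernel_fft(dims, sp, spec$deform_smoothness)
      t <- 1L
      while (t <= spec$ensemble_T) {
        pair <- smooth_noise_pair(dims, Kf)
        fields[[t]] <- pair[[1]]
        if (t + 1L <= spec$ensemble_T) fields[[t + 1L]] <- pair[[2]]
        t <- t + 2L
      }
    }
    members <- vector("list", spec$ensemble_T)
    for (t in seq_len(spec$ensemble_T)) {
      sd_t <- sdist
      if (spec$deform_sigma > 0)
        sd_t <- sd_t + spec$deform_sigma * fields[[t]]
      p <- stats::plogis(-sd_t / spec$boundary_tau)
      if (spec$noise_sigma > 0) {
        p <- p + stats::rnorm(length(p), sd = spec$noise_sigma)
        p[p < 0] <- 0; p[p > 1] <- 1
      }
      members[[t]] <- volume(array(p, dims), tract$affine)
      fields[t] <- list(NULL)
    }
    probability_ensemble(members)
  })
}

#' Generate classified responses around a tract
#'
#' Synthetic M1 is the top `fan_frac`-plus-margin slab of the grid (where
#' the tract fans into "cortex"). For each class, `n_responses` voxels are
#' drawn whose distance-to-tract matches a draw from the class target
#' distribution (acceptance window +/- 0.5 mm, else the nearest achievable
#' unused voxel): `+M1+` inside the slab, `-M1+`/`-M1-` outside it. Masks
#' are pairwise disjoint; a synthetic intracranial mask (grid minus a
#' 1-voxel border) and an all-WM mask are attached so the nTMS processing
#' stages can run.
#'
#' @param tract A [binary_mask()].
#' @param spec A [phantom_spec()].
#' @return Named list of three `response_mask` objects with attributes
#'   `records` (response CSV rows), `m1`, `intracranial`, `wm`
#'   ([binary_mask()]s).
#' @export
generate_responses <- function(tract, spec) {
  validate_phantom_spec(spec)
  d <- dim(tract$data)
  dmap <- distance_map(tract)
  dv <- as.vector(dmap$data)
  g <- phantom_coords(spec)
  slab_z0 <- floor(0.8 * d[3])  # 0-based first slab slice
  kk <- array(rep(0:(d[3] - 1), each = d[1] * d[2]), d)
  interior <- array(TRUE, d)
  interior[c(1, d[1]), , ] <- FALSE
  interior[, c(1, d[2]), ] <- FALSE
  interior[, , c(1, d[3])] <- FALSE
  m1_arr <- (kk >= slab_z0) & interior
  regions <- list(`+M1+` = which(m1_arr),
                  `-M1+` = which(!m1_arr & interior),
                  `-M1-` = which(!m1_arr & interior))
  with_seed(spec$seed + 2L, {
    used <- logical(length(dv))
    masks <- list(); recs <- list()
    for (kl in RESPONSE_CLASSES) {
      mu <- spec$class_distances[[kl]][1]
      sdv <- spec$class_distances[[kl]][2]
      cand <- regions[[kl]]
      if (max(dv[cand]) < mu)
        stop("grid too small to realise the ", kl,
             " target distances (max achievable ",
             round(max(dv[cand]), 1), " mm < mean ", mu, " mm)")
      chosen <- integer(spec$n_responses)
      for (r in seq_len(spec$n_responses)) {
        repeat {
          draw <- stats::rnorm(1, mu, sdv)
          if (kl == "+M1+") draw <- abs(draw)
          if (draw >= 0) break
        }
        free <- cand[!used[cand]]
        if (length(free) == 0) stop("ran out of candidate voxels for ", kl)
        hit <- free[abs(dv[free] - draw) <= 0.5]
        vox <- if (length(hit) > 0) {
          if (length(hit) == 1) hit else sample(hit, 1)
        } else {
          free[which.min(abs(dv[free] - draw))]
        }
        used[vox] <- TRUE
        chosen[r] <- vox
      }
      amp <- if (kl == "-M1-") stats::runif(spec$n_responses, 5, 49.9)
             else stats::runif(spec$n_responses, 50, 800)
      recs[[kl]] <- data.frame(
        x_mm = g$x[chosen], y_mm = g$y[chosen], z_mm = g$z[chosen],
        amplitude_uv = amp,
        latency_ms = stats::runif(spec$n_responses, 18, 26),
        muscle = sample(c("APB", "FDI", "ADM"), spec$n_responses,
                        replace = TRUE),
        hemisphere = "left", manually_excluded = 0L, klass = kl,
        stringsAsFactors = FALSE)
      arr <- array(0, d); arr[chosen] <- 1
      masks[[kl]] <- structure(
        list(mask = binary_mask(arr, tract$affine, label = "response"),
             klass = kl, n_responses = spec$n_responses),
        class = "response_mask")
    }
    out <- masks
    attr(out, "records") <- do.call(rbind, recs)
    attr(out, "m1") <- binary_mask(m1_arr + 0, tract$affine, label = "M1")
    attr(out, "intracranial") <- binary_mask(interior + 0, tract$affine,
                                             label = "intracranial")
    attr(out, "wm") <- binary_mask(interior + 0, tract$affine,
                                   label = "WM")
    out
  })
}

#' Generate a full phantom subject
#'
#' Tract, probability ensemble and classified responses from one spec.
#' The three generators draw from independent streams salted from
#' `spec$seed`, so the subject is a pure function of the spec.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `phantom_subject`: `tract`, `ensemble`,
#'   `responses` (with `records`/`m1`/`wm`/`intracranial` attributes),
#'   `spec`.
#' @export
generate_subject <- function(spec) {
  tract <- generate_tract(spec)
  ens <- generate_ensemble(tract, spec)
  resp <- generate_responses(tract, spec)
  structure(list(tract = tract, ensemble = ens, responses = resp,
                 spec = spec),
            class = "phantom_subject")
}

subject_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 1000003 + i * 7919) %% 2147483647)
}

#' Generate a phantom cohort
#'
#' Derives one independent seed per subject from the master seed
#' (reproducible: identical master seed gives bit-identical cohorts) and
#' optionally writes the NIfTI/CSV tree the file-based pipeline consumes:
#' one directory per subject with the tract mask, per-pass probability
#' maps, response masks and records, and the M1/WM/intracranial masks,
#' plus a cohort-level `cohort.csv`.
#'
#' Volumes are not retained in memory (a default cohort would need
#' gigabytes); regenerate any subject with
#' `generate_subject(subject_spec(cohort, i))`.
#'
#' @param n_subjects Default 16.
#' @param base_spec A [phantom_spec()]; per-subject specs differ only in
#'   seed.
#' @param seed Master seed (default `base_spec$seed`).
#' @param out_dir Optional directory to write the cohort tree into.
#' @return List of class `phantom_cohort`: `metadata` (data frame),
#'   `base_spec`, `seeds`, `out_dir`.
#' @export
generate_cohort <- function(n_subjects = 16, base_spec = phantom_spec(),
                            seed = base_spec$seed, out_dir = NULL) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  seeds <- vapply(seq_len(n_subjects), function(i) subject_seed(seed, i),
                  integer(1))
  meta <- data.frame(subject_id = sprintf("sub-%02d", seq_len(n_subjects)),
                     seed = seeds,
                     n_responses_per_class = base_spec$n_responses,
                     ensemble_T = base_spec$ensemble_T,
                     stringsAsFactors = FALSE)
  cohort <- structure(list(metadata = meta, base_spec = base_spec,
                           seeds = seeds, out_dir = out_dir),
                      class = "phantom_cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_subjects)) {
      sub <- generate_subject(subject_spec(cohort, i))
      write_subject(sub, file.path(out_dir, meta$subject_id[i]))
    }
    utils::write.csv(meta, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
  }
  cohort
}

#' Per-subject spec of a cohort
#' @param cohort A `phantom_cohort`.
#' @param i Subject index.
#' @export
subject_spec <- function(cohort, i) {
  spec <- cohort$base_spec
  spec$seed <- cohort$seeds[i]
  spec
}

write_subject <- function(sub, dir) {
  dir.create(file.path(dir, "ensemble"), recursive = TRUE,
             showWarnings = FALSE)
  write_volume(sub$tract, file.path(dir, "tract.nii.gz"))
  for (t in seq_len(sub$ensemble$T))
    write_volume(sub$ensemble$members[[t]],
                 file.path(dir, "ensemble", sprintf("pass_%02d.nii.gz", t)),
                 datatype = "float32")
  for (kl in RESPONSE_CLASSES) {
    fn <- sprintf("responses_%s.nii.gz", class_slug(kl))
    write_volume(sub$responses[[kl]]$mask, file.path(dir, fn))
  }
  for (m in c("m1", "intracranial", "wm"))
    write_volume(attr(sub$responses, m),
                 file.path(dir, paste0(m, ".nii.gz")))
  utils::write.csv(attr(sub$responses, "records"),
                   file.path(dir, "responses.csv"), row.names = FALSE)
  invisible(dir)
}

class_slug <- function(kl) {
  c(`+M1+` = "pM1p", `-M1+` = "mM1p", `-M1-` = "mM1m")[[kl]]
}

# number of 26-connected components of a mask (used by generator tests)
n_components26 <- function(mask) {
  d <- dim(mask$data)
  fg <- which(mask$data == 1)
  if (length(fg) == 0) return(0L)
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  visited <- logical(length(mask$data))
  is_fg <- logical(length(mask$data)); is_fg[fg] <- TRUE
  ncomp <- 0L
  todo <- fg
  while (length(todo) > 0) {
    start <- todo[1]
    if (visited[start]) { todo <- todo[-1]; next }
    ncomp <- ncomp + 1L
    frontier <- start
    visited[start] <- TRUE
    while (length(frontier) > 0) {
      ijk <- arrayInd(frontier, d)
      nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(r)
        sweep(ijk, 2, off[r, ], "+")))
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
            nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      flat <- nb[, 1] + d[1] * (nb[, 2] - 1 + d[2] * (nb[, 3] - 1))
      flat <- unique(flat[is_fg[flat] & !visited[flat]])
      visited[flat] <- TRUE
      frontier <- flat
    }
    todo <- todo[!visited[todo]]
  }
  ncomp
}
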