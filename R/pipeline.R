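#' Bundled reference tables
#'
#' Two small CSVs ship with the package for validation and worked examples:
#' \describe{
#'   \item{`cohort`}{clinical/demographic characteristics of the reference
#'     16-patient motor-eloquent glioma cohort (age, sex, tumour location,
#'     hemisphere, volume, diagnosis with WHO grade).}
#'   \item{`overlap`}{the per-subject published-style concordance values for
#'     that cohort: overlap coefficients per method (UncSeg, TractSeg) and
#'     response class, and the between-method Dice.}
#' }
#' These are printed summary tables, not imaging data (the underlying
#' images are not shareable); they drive the exact-reproduction checks.
#'
#' @param which `"cohort"` or `"overlap"`.
#' @return A data frame.
#' @export
reference_table <- function(which = c("cohort", "overlap")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("reference_", which, ".csv"),
                      package = "cstconcord", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Reference overlap table in long format
#'
#' Reshapes the wide per-subject reference overlap CSV into a
#' [concordance_table()] keyed by (subject, method, klass).
#' @return A `concordance_table`.
#' @export
reference_concordance <- function() {
  wide <- reference_table("overlap")
  rows <- do.call(rbind, lapply(c("uncseg", "tractseg"), function(m) {
    do.call(rbind, lapply(RESPONSE_CLASSES, function(kl) {
      col <- paste0("oc_", m, "_", class_slug(kl))
      data.frame(subject = wide$subject, method = m, klass = kl,
                 oc = wide[[col]], stringsAsFactors = FALSE)
    }))
  }))
  concordance_table(rows)
}

#' Cohort characteristics summary
#'
#' Summarises a cohort metadata table: size, sex counts, age mean and
#' range, hemisphere shares, WHO-grade shares (parsed from the diagnosis
#' text) and histological-type shares. Percentages are of the full cohort;
#' rows whose diagnosis does not contain a parseable "WHO Grade <n>" are
#' flagged with a warning and excluded from the grade shares only. Tumour
#' locations are tabulated verbatim (no lobe-level rollup is attempted —
#' groupings like "Fronto-Insular" are genuinely ambiguous).
#'
#' @param table Data frame with columns `age`, `sex` (`M`/`F`),
#'   `hemisphere` (`Left`/`Right`), `diagnosis`, `tumor_location`.
#' @return List with `n`, `sex`, `age_mean`, `age_range`, `hemisphere_pct`,
#'   `who_grade_pct`, `histology_pct`, `location_counts`. Full precision;
#'   round at presentation time.
#' @export
cohort_summary <- function(table) {
  if (nrow(table) < 1) stop("empty cohort table")
  if (any(table$age <= 0)) stop("ages must be positive")
  n <- nrow(table)
  grade <- regmatches(table$diagnosis,
                      regexpr("WHO Grade [0-9]+", table$diagnosis))
  parsed <- grepl("WHO Grade [0-9]+", table$diagnosis)
  if (any(!parsed))
    warning(sum(!parsed), " row(s) with unparseable WHO grade excluded ",
            "from grade shares")
  gnum <- sub("WHO Grade ", "", regmatches(
    table$diagnosis, regexpr("WHO Grade [0-9]+", table$diagnosis)))
  histo <- ifelse(grepl("Oligodendroglioma", table$diagnosis,
                        ignore.case = TRUE), "Oligodendroglioma",
           ifelse(grepl("Glioblastoma", table$diagnosis,
                        ignore.case = TRUE), "Glioblastoma",
           ifelse(grepl("Astrocytoma", table$diagnosis,
                        ignore.case = TRUE), "Astrocytoma", "Other")))
  pct <- function(x) 100 * table(x) / n
  list(n = n,
       sex = table(table$sex),
       age_mean = mean(table$age),
       age_range = range(table$age),
       hemisphere_pct = pct(table$hemisphere),
       who_grade_pct = pct(gnum),  # of n, even if some rows unparseable
       histology_pct = pct(histo),
       location_counts = table(table$tumor_location))
}

#' Analyse a synthetic phantom cohort end-to-end
#'
#' Runs the full analysis on an in-memory phantom cohort, one subject at a
#' time (volumes are generated, analysed and discarded): ensemble mean ->
#' binary tract mask (threshold `tau`) -> uncertainty map -> per-class
#' overlap coefficients -> distance map of the binary mask -> pooled
#' (uncertainty, distance) pairs -> joint histogram, Spearman correlation
#' and linear trend.
#'
#' @param cohort A `phantom_cohort` from [generate_cohort()].
#' @param tau Binarisation threshold (default 0.5).
#' @param estimator Uncertainty estimator (default `"std"`).
#' @param n_bins Distance bins (default 30).
#' @param verbose Print per-subject progress.
#' @return List: `table` ([concordance_table()]), `ordering_ok` (logical
#'   per subject), `pairs` (pooled data frame with subject ids),
#'   `uncdist` ([uncertainty_distance_analysis()] result), `params`.
#' @export
analyze_cohort <- function(cohort, tau = 0.5, estimator = "std",
                           n_bins = 30, verbose = FALSE) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  n <- nrow(cohort$metadata)
  rows <- list(); pairs <- list(); ordering <- logical(n)
  for (i in seq_len(n)) {
    sid <- cohort$metadata$subject_id[i]
    if (verbose) message("analysing ", sid)
    sub <- generate_subject(subject_spec(cohort, i))
    res <- analyze_subject(sub, tau = tau, estimator = estimator)
    rows[[i]] <- data.frame(subject = sid, method = "phantom",
                            klass = RESPONSE_CLASSES, oc = res$oc,
                            stringsAsFactors = FALSE)
    ordering[i] <- oc_ordering_check(res$oc)
    res$pairs$subject <- sid
    pairs[[i]] <- res$pairs
    rm(sub)
  }
  tab <- concordance_table(do.call(rbind, rows))
  allpairs <- do.call(rbind, pairs)
  ud <- uncertainty_distance_analysis(allpairs, n_bins)
  list(table = tab, ordering_ok = ordering, pairs = allpairs,
       uncdist = ud,
       params = list(tau = tau, estimator = estimator, n_bins = n_bins))
}

#' Analyse one phantom subject
#'
#' @param sub A `phantom_subject` from [generate_subject()].
#' @inheritParams analyze_cohort
#' @return List: `oc` (named per-class overlap coefficients against the
#'   binarised ensemble mean), `dice_vs_truth` (binary mask vs generating
#'   tract), `pairs` (uncertainty/distance per response voxel), `cst`
#'   (the binary mask).
#' @export
analyze_subject <- function(sub, tau = 0.5, estimator = "std") {
  pmean <- ensemble_mean(sub$ensemble)
  cst <- binarize(pmean, tau)
  unc <- uncertainty_map(sub$ensemble, estimator)
  oc <- vapply(RESPONSE_CLASSES, function(kl)
    overlap_coefficient(cst, sub$responses[[kl]]$mask,
                        expect_b_smaller = TRUE), numeric(1))
  dmap <- distance_map(cst)
  pairs <- do.call(rbind, lapply(RESPONSE_CLASSES, function(kl)
    pair_uncertainty_distance(unc, dmap, sub$responses[[kl]])))
  list(oc = oc, dice_vs_truth = dice(cst, sub$tract), pairs = pairs,
       cst = cst)
}

#' Run the file-based pipeline on a cohort directory
#'
#' Consumes the layout written by [generate_cohort()] (or any tree with
#' the same structure): per-subject ensemble passes, response records CSV
#' and M1/WM/intracranial masks. Stages per subject: build response masks
#' from records (classification, rasterisation, landmark removal, WM
#' filter) -> aggregate ensemble -> overlap -> uncertainty vs distance.
#' Per-subject failures are isolated and logged: a failing subject yields
#' NA concordance rows, never aborts the cohort, and never fabricates a 0.
#'
#' @param dir Cohort directory containing `cohort.csv` and one
#'   sub-directory per subject.
#' @param out_dir Where to write `concordance.csv`, `histogram.csv` and
#'   `summary.json`; default `file.path(dir, "derived")`.
#' @param tau,estimator,n_bins,amp_threshold,latency_window,radius
#'   Analysis parameters (defaults: 0.5, `"std"`, 30, 50 uV, 18-26 ms,
#'   0 mm); every value is recorded in the report header.
#' @return The report list, invisibly (also serialised to `out_dir`).
#' @export
run_pipeline <- function(dir, out_dir = file.path(dir, "derived"),
                         tau = 0.5, estimator = "std", n_bins = 30,
                         amp_threshold = 50, latency_window = c(18, 26),
                         radius = 0) {
  meta <- utils::read.csv(file.path(dir, "cohort.csv"),
                          stringsAsFactors = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); pairs <- list(); failures <- character(0)
  for (i in seq_len(nrow(meta))) {
    sid <- meta$subject_id[i]
    sdir <- file.path(dir, sid)
    res <- tryCatch({
      m1 <- binary_mask(read_volume(file.path(sdir, "m1.nii.gz")))
      icv <- binary_mask(read_volume(file.path(sdir, "intracranial.nii.gz")))
      wm <- binary_mask(read_volume(file.path(sdir, "wm.nii.gz")))
      recs <- utils::read.csv(file.path(sdir, "responses.csv"),
                              stringsAsFactors = FALSE)
      resp <- build_response_masks(recs, m1, grid = m1,
                                   intracranial = icv, wm = wm,
                                   amp_threshold = amp_threshold,
                                   latency_window = latency_window,
                                   radius = radius)
      ens <- read_ensemble(file.path(sdir, "ensemble"))
      cst <- binarize(ensemble_mean(ens), tau)
      unc <- uncertainty_map(ens, estimator)
      dmap <- distance_map(cst)
      oc <- vapply(RESPONSE_CLASSES, function(kl)
        overlap_coefficient(cst, resp[[kl]]$mask,
                            expect_b_smaller = TRUE), numeric(1))
      pr <- do.call(rbind, lapply(RESPONSE_CLASSES, function(kl)
        pair_uncertainty_distance(unc, dmap, resp[[kl]])))
      list(oc = oc, pairs = pr)
    }, error = function(e) {
      warning("subject ", sid, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) {
      failures <- c(failures, sid)
      rows[[i]] <- data.frame(subject = sid, method = "phantom",
                              klass = RESPONSE_CLASSES, oc = NA_real_,
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(subject = sid, method = "phantom",
                              klass = RESPONSE_CLASSES, oc = res$oc,
                              stringsAsFactors = FALSE)
      if (nrow(res$pairs)) {
        res$pairs$subject <- sid
        pairs[[length(pairs) + 1]] <- res$pairs
      }
    }
  }
  tab <- do.call(rbind, rows)
  allpairs <- if (length(pairs)) do.call(rbind, pairs) else NULL
  ud <- if (!is.null(allpairs) && nrow(allpairs) >= 3)
    uncertainty_distance_analysis(allpairs, n_bins) else NULL
  report <- list(
    tool = paste0("cstconcord ",
                  as.character(utils::packageVersion("cstconcord"))),
    params = list(tau = tau, estimator = estimator, n_bins = n_bins,
                  amp_threshold_uv = amp_threshold,
                  latency_window_ms = latency_window,
                  rasterize_radius_mm = radius,
                  oc_definition = "intersection over min (Szymkiewicz-Simpson)",
                  wilcoxon_zeros = "dropped"),
    n_subjects = nrow(meta), failed_subjects = failures,
    concordance = tab,
    spearman_pooled = if (!is.null(ud))
      ud$pooled[c("rho", "p_value", "n")] else NULL,
    spearman_binned = if (!is.null(ud) && !is.null(ud$binned))
      ud$binned[c("rho", "p_value", "n")] else NULL,
    trend = if (!is.null(ud)) ud$trend else NULL)
  utils::write.csv(tab, file.path(out_dir, "concordance.csv"),
                   row.names = FALSE)
  if (!is.null(ud))
    utils::write.csv(ud$histogram$bins,
                     file.path(out_dir, "histogram.csv"),
                     row.names = FALSE)
  jsonlite::write_json(report[setdiff(names(report), "concordance")],
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
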