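#' Overlap coefficient (Szymkiewicz-Simpson) of two binary masks
#'
#' \deqn{OC(A, B) = |A \cap B| / \min(|A|, |B|)}
#'
#' Symmetric; 1 exactly when the smaller set is fully enclosed by the
#' larger, 0 exactly when the sets are disjoint. Note the implemented
#' formula is intersection-over-minimum: the often-quoted phrasing
#' "union over the smaller set" is inconsistent with this range (union/min
#' is always >= 1) and with both boundary behaviours, so the subset/disjoint
#' semantics are taken as authoritative.
#'
#' In tract-vs-response comparisons the response mask is expected to be the
#' smaller set; a warning (not an error) is raised when that expectation is
#' violated, since OC is still well defined.
#'
#' @param a,b [binary_mask()]s on the same grid.
#' @param expect_b_smaller Warn if `|b| > |a|` (set when `b` is the
#'   response mask). Default `FALSE`.
#' @return OC in \[0, 1\], or `NA` when either mask is empty (undefined,
#'   never silently 0).
#' @export
overlap_coefficient <- function(a, b, expect_b_smaller = FALSE) {
  stopifnot(is_binary_mask(a), is_binary_mask(b))
  assert_same_grid(a, b, "overlap_coefficient")
  na <- sum(a$data); nb <- sum(b$data)
  if (min(na, nb) == 0) return(NA_real_)
  if (expect_b_smaller && nb > na)
    warning("expected the second mask (responses) to be the smaller set; |b| = ",
            nb, " > |a| = ", na)
  sum(a$data * b$data) / min(na, nb)
}

#' Dice coefficient of two binary masks
#'
#' \deqn{Dice(A, B) = 2 |A \cap B| / (|A| + |B|)}
#'
#' @param a,b [binary_mask()]s on the same grid.
#' @return Dice in \[0, 1\]; `NA` when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(is_binary_mask(a), is_binary_mask(b))
  assert_same_grid(a, b, "dice")
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0) return(NA_real_)
  2 * sum(a$data * b$data) / (na + nb)
}

#' Per-subject concordance table
#'
#' Long-format table of overlap coefficients keyed by
#' (subject, method, class), the per-subject analogue of a published
#' cohort OC table, plus optional between-method Dice values.
#'
#' @param rows Data frame with columns `subject`, `method`, `klass`, `oc`
#'   (and optionally `dice`).
#' @return Object of class `concordance_table` (a data frame).
#' @export
concordance_table <- function(rows) {
  need <- c("subject", "method", "klass", "oc")
  if (!all(need %in% names(rows)))
    stop("concordance table needs columns: ", paste(need, collapse = ", "))
  key <- interaction(rows$subject, rows$method, rows$klass, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (subject, method, klass) keys in concordance table")
  bad <- !is.na(rows$oc) & (rows$oc < 0 | rows$oc > 1)
  if (any(bad)) stop("OC values outside [0, 1]")
  structure(as.data.frame(rows), class = c("concordance_table",
                                           "data.frame"))
}

#' Cohort mean and sd of OC for one method/class
#'
#' Arithmetic mean and sample standard deviation over subjects with a
#' defined (non-NA) value; dispersion uses the sample (n-1) convention,
#' which is what reproduces published cohort summaries of this form.
#' The median is also returned, since "0.00" summaries of heavily
#' zero-inflated columns are sometimes medians.
#'
#' @param table A [concordance_table()].
#' @param method,klass Key to aggregate.
#' @return List with `mean`, `sd`, `median`, `n`.
#' @export
cohort_mean_oc <- function(table, method, klass) {
  v <- table$oc[table$method == method & table$klass == klass]
  v <- v[!is.na(v)]
  if (length(v) == 0)
    stop("no defined OC values for method '", method, "', class '", klass, "'")
  list(mean = mean(v),
       sd = if (length(v) > 1) stats::sd(v) else 0,
       median = stats::median(v),
       n = length(v))
}

#' Monotone OC pattern check for one subject
#'
#' TRUE iff OC(+M1+) >= OC(-M1+) >= OC(-M1-), with strictness required only
#' where values differ beyond `tol` (ties, typically at 0, are allowed).
#' This is the expected anatomical pattern: positive responses in M1 sit on
#' the tract, negative responses far from it.
#'
#' @param oc Named (or ordered) numeric length 3: OC for +M1+, -M1+, -M1-.
#' @param tol Tie tolerance; default 1e-9.
#' @return Logical, or `NA` if any value is missing.
#' @export
oc_ordering_check <- function(oc, tol = 1e-9) {
  if (length(oc) != 3) stop("need exactly the three class OC values")
  if (anyNA(oc)) return(NA)
  oc[1] >= oc[2] - tol && oc[2] >= oc[3] - tol
}
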