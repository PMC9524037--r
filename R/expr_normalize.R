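#' Negative-control background subtraction
#'
#' Per sample, a background threshold is estimated from the
#' negative-control probes as `mean + k * sd` (k = 2 by default, a
#' common convention for hybridization-count panels; the appropriate k
#' is assay-specific and exposed here as a parameter).  Counts at or
#' below the threshold become 0; counts above it are reduced by the
#' threshold.  Results are never negative.  A matrix without
#' negative-control rows is returned unchanged with a warning.
#'
#' @param m An [expression_matrix()].
#' @param k Multiplier on the negative-control standard deviation.
#' @return An [expression_matrix()] with background removed; per-sample
#'   thresholds in attribute `"background_threshold"`.
#' @export
background_subtract <- function(m, k = 2) {
  stopifnot(inherits(m, "expression_matrix"))
  if (!length(m$negative_controls)) {
    warning("no negative-control rows: background subtraction skipped")
    return(m)
  }
  neg <- m$counts[m$negative_controls, , drop = FALSE]
  thr <- apply(neg, 2, mean) + k * apply(neg, 2, stats::sd)
  if (length(m$negative_controls) == 1L) thr <- neg[1, ] + 0  # sd undefined -> mean only
  thr[is.na(thr)] <- apply(neg, 2, mean)[is.na(thr)]
  counts <- pmax(sweep(m$counts, 2, thr), 0)
  out <- expression_matrix(counts, m$groups, m$housekeeping, m$negative_controls)
  attr(out, "background_threshold") <- thr
  out
}

#' Geometric-mean housekeeping normalization
#'
#' Scales each sample by `f_s = G_ref / G_s`, where `G_s` is the
#' geometric mean of the sample's housekeeping-gene counts and `G_ref`
#' the geometric mean of all `G_s`.  After normalization every sample's
#' housekeeping geometric mean equals `G_ref`, removing library-size /
#' assay-input differences under the assumption that the housekeeping
#' panel is unregulated.  Idempotent (factors become 1 on a second
#' pass) and invariant to rescaling any single sample's raw counts.
#'
#' @param m An [expression_matrix()]; every housekeeping gene must have
#'   a strictly positive count in every sample (a zero makes the
#'   geometric mean degenerate and raises an error naming the gene and
#'   sample).
#' @return An [expression_matrix()] of normalized counts with the
#'   per-sample scale factors in attribute `"norm_factors"`.
#' @export
normalize_housekeeping <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  hk <- m$counts[m$housekeeping, , drop = FALSE]
  if (any(hk <= 0)) {
    bad <- which(hk <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("housekeeping gene '%s' has nonpositive count in sample '%s'",
                 rownames(hk)[bad[1]], colnames(hk)[bad[2]]))
  }
  g_s <- exp(colMeans(log(hk)))
  g_ref <- exp(mean(log(g_s)))
  f <- g_ref / g_s
  out <- expression_matrix(sweep(m$counts, 2, f, `*`), m$groups,
                           m$housekeeping, m$negative_controls)
  attr(out, "norm_factors") <- f
  out
}
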