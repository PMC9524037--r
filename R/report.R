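#' Significance stars for a p-value
#'
#' The conventional annotation: `****` p < 0.0001, `***` p < 0.001,
#' `**` p < 0.01, `*` p < 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of annotations.
#' @export
signif_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.0001) "****"
    else if (pi < 0.001) "***"
    else if (pi < 0.01) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Standard error of the mean
#' @param x Numeric vector (length >= 2).
#' @return `sd(x) / sqrt(length(x))`.
#' @export
sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Group comparison of a field-level measure
#'
#' Summarizes one measure (e.g. plaque count per field) across
#' experimental groups as mean +/- SEM, and tests group differences
#' with a one-way ANOVA followed by Tukey's range test for all pairwise
#' comparisons; with exactly two groups an unpaired Student t-test is
#' used instead.  Significance stars follow [signif_stars()].
#'
#' @param values Numeric vector of per-field measurements.
#' @param groups Group label per measurement (>= 2 groups, each with
#'   >= 2 values; a smaller group is an error naming it).
#' @param measure Name of the measure (for reporting).
#' @return A list of class `group_comparison`: `measure`, `summary`
#'   (group, n, mean, sem), `test` (`"anova"` or `"t"`), `statistic`
#'   (F or t), `p_value`, `stars`, and for ANOVA a `pairwise` data
#'   frame of Tukey-adjusted comparisons with stars.
#' @export
compare_groups <- function(values, groups, measure = "measure") {
  groups <- as.factor(as.character(groups))
  if (length(values) != length(groups))
    stop("`values` and `groups` lengths differ")
  n_per <- tabulate(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(n_per < 2L))
    stop("group '", levels(groups)[which(n_per < 2L)[1]], "' has fewer than 2 values")
  summ <- data.frame(
    group = levels(groups), n = n_per,
    mean = as.vector(tapply(values, groups, mean)),
    sem = as.vector(tapply(values, groups, sem)), row.names = NULL)
  if (nlevels(groups) == 2L) {
    if (stats::var(values) == 0) {
      # all observations identical: no evidence of a difference
      out <- list(measure = measure, summary = summ, test = "t",
                  statistic = 0, p_value = 1,
                  stars = "ns", pairwise = NULL)
    } else {
      tt <- stats::t.test(values ~ groups, var.equal = TRUE)
      out <- list(measure = measure, summary = summ, test = "t",
                  statistic = unname(tt$statistic), p_value = tt$p.value,
                  stars = signif_stars(tt$p.value), pairwise = NULL)
    }
  } else if (stats::var(values) == 0) {
    pw <- t(utils::combn(levels(groups), 2))
    pw <- data.frame(comparison = paste0(pw[, 2], "-", pw[, 1]), diff = 0,
                     p_adj = 1, stars = "ns")
    out <- list(measure = measure, summary = summ, test = "anova",
                statistic = 0, p_value = 1, stars = "ns", pairwise = pw)
  } else {
    d <- data.frame(y = values, g = groups)
    fit <- stats::aov(y ~ g, data = d)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    pw <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                     p_adj = tk[, "p adj"], stars = signif_stars(tk[, "p adj"]),
                     row.names = NULL)
    out <- list(measure = measure, summary = summ, test = "anova",
                statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
                stars = signif_stars(an[["Pr(>F)"]][1]), pairwise = pw)
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison of '%s' (%s test): statistic = %.4g, p = %.4g %s\n",
              x$measure, x$test, x$statistic, x$p_value, x$stars))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-12s n=%2d  %.4g +/- %.4g\n", x$summary$group[i],
                x$summary$n[i], x$summary$mean[i], x$summary$sem[i]))
  if (!is.null(x$pairwise)) {
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("  %-24s p_adj = %.4g %s\n", x$pairwise$comparison[i],
                  x$pairwise$p_adj[i], x$pairwise$stars[i]))
  }
  invisible(x)
}
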