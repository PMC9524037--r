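#' Fold-change / ANOVA-Tukey differential expression
#'
#' For each endogenous gene, the fold change is the ratio of normalized
#' group means, `mean(groupA) / mean(groupB)` (linear scale), and the
#' p-value is the Tukey-adjusted pairwise comparison from a one-way
#' ANOVA fitted across *all* groups in the matrix.  When the matrix
#' holds exactly two groups a Welch t-test is used instead (no family
#' to adjust over).  Both p-values are returned (`p_tukey`, `p_welch`);
#' `p_value` is the primary one.  Genes are classed with strict
#' thresholds: `up` if FC > `fc_up` and p < `alpha`, `down` if FC <
#' `fc_down` and p < `alpha`, otherwise `ns` — so FC exactly at a
#' threshold is not significant.
#'
#' A zero group-B mean leaves FC undefined: the record is flagged
#' (`flagged = TRUE`, class `NA`) and excluded from classing.  A zero
#' group-A mean (with nonzero B) gets a 0.5 pseudo-count on both means
#' for the ratio only, keeping log fold changes finite.
#'
#' @param m A normalized [expression_matrix()].
#' @param contrast Character `c(groupA, groupB)`: FC > 1 means higher
#'   in `groupA`.
#' @param fc_up,fc_down Fold-change thresholds (defaults 1.5 and 0.66).
#' @param alpha Significance level (default 0.05).
#' @return Data frame of class `de_table`: `gene`, `fold_change`,
#'   `p_value`, `p_tukey`, `p_welch`, `class` (`up` / `down` / `ns`),
#'   `flagged`, plus `mean_a`, `mean_b`.  Each group must have >= 2
#'   samples.
#' @export
differential_expression <- function(m, contrast, fc_up = 1.5, fc_down = 0.66,
                                    alpha = 0.05) {
  stopifnot(inherits(m, "expression_matrix"))
  if (length(contrast) != 2L || !all(contrast %in% levels(m$groups)))
    stop("`contrast` must name two groups present in the matrix")
  if (any(tabulate(m$groups) < 2L))
    stop("every group needs >= 2 samples")
  genes <- endogenous_genes(m)
  counts <- m$counts[genes, , drop = FALSE]
  grp <- m$groups
  a <- contrast[1]; b <- contrast[2]
  in_a <- grp == a; in_b <- grp == b
  multi <- nlevels(grp) > 2L
  # TukeyHSD names pairs "lvl2-lvl1" in level order
  pair_fwd <- paste0(b, "-", a); pair_rev <- paste0(a, "-", b)

  n_g <- nrow(counts)
  fc <- p_tuk <- p_wel <- rep(NA_real_, n_g)
  mean_a <- rowMeans(counts[, in_a, drop = FALSE])
  mean_b <- rowMeans(counts[, in_b, drop = FALSE])
  gdf <- data.frame(g = grp)
  for (i in seq_len(n_g)) {
    y <- counts[i, ]
    if (multi && stats::var(y) > 0) {
      fit <- stats::aov(y ~ g, data = cbind(gdf, y = y))
      tk <- stats::TukeyHSD(fit)$g
      row <- if (pair_fwd %in% rownames(tk)) pair_fwd else pair_rev
      p_tuk[i] <- tk[row, "p adj"]
    }
    ya <- y[in_a]; yb <- y[in_b]
    if (stats::var(ya) + stats::var(yb) > 0)
      p_wel[i] <- stats::t.test(ya, yb)$p.value
  }
  fc <- ifelse(mean_b > 0,
               ifelse(mean_a > 0, mean_a / mean_b, (mean_a + 0.5) / (mean_b + 0.5)),
               NA_real_)
  flagged <- mean_b == 0
  p <- if (multi) p_tuk else p_wel
  cls <- rep("ns", n_g)
  cls[!flagged & !is.na(p) & fc > fc_up & p < alpha] <- "up"
  cls[!flagged & !is.na(p) & fc < fc_down & p < alpha] <- "down"
  cls[flagged] <- NA_character_
  out <- data.frame(gene = genes, fold_change = fc, p_value = p,
                    p_tukey = p_tuk, p_welch = p_wel, class = cls,
                    flagged = flagged, mean_a = mean_a, mean_b = mean_b,
                    row.names = NULL)
  attr(out, "contrast") <- contrast
  attr(out, "thresholds") <- c(fc_up = fc_up, fc_down = fc_down, alpha = alpha)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Directional fold-change reversal statistic
#'
#' Given a classed disease-contrast DE table (e.g. disease vs control)
#' and a treatment-contrast DE table (e.g. treated vs disease) over the
#' same genes, counts how many disease DEGs (class `up` or `down`) have
#' a treatment fold change pointing in the *opposite* direction —
#' `sign(log FC_treatment) != sign(log FC_disease)`.  Direction only:
#' no significance requirement is placed on the treatment contrast.  A
#' treatment FC of exactly 1 (log FC 0) is not a reversal.
#'
#' @param disease Classed `de_table` for the disease contrast.
#' @param treatment `de_table` for the treatment contrast, covering the
#'   same genes (any gene present in only one table is an error).
#' @return A list of class `reversal_summary`: `n_deg`, `n_reversed`,
#'   `fraction`, and the per-gene `genes` data frame.
#' @export
reversal_analysis <- function(disease, treatment) {
  stopifnot(inherits(disease, "de_table"), inherits(treatment, "de_table"))
  only <- c(setdiff(disease$gene, treatment$gene),
            setdiff(treatment$gene, disease$gene))
  if (length(only))
    stop("genes present in only one contrast: ",
         paste(utils::head(only, 5), collapse = ", "))
  tr <- treatment[match(disease$gene, treatment$gene), ]
  deg <- !is.na(disease$class) & disease$class %in% c("up", "down")
  ld <- log(disease$fold_change[deg])
  lt <- log(tr$fold_change[deg])
  reversed <- !is.na(lt) & lt != 0 & sign(lt) != sign(ld)
  n_deg <- sum(deg)
  genes <- data.frame(gene = disease$gene[deg],
                      class_disease = disease$class[deg],
                      fc_disease = disease$fold_change[deg],
                      fc_treatment = tr$fold_change[deg],
                      reversed = reversed)
  structure(
    list(n_deg = n_deg, n_reversed = sum(reversed),
         fraction = if (n_deg > 0) sum(reversed) / n_deg else NA_real_,
         genes = genes),
    class = "reversal_summary")
}

#' @export
print.reversal_summary <- function(x, ...) {
  cat(sprintf("reversal_summary: %d of %d DEGs reversed (%.1f%%)\n",
              x$n_reversed, x$n_deg, 100 * x$fraction))
  invisible(x)
}

#' Volcano-plot table
#'
#' Converts a classed DE table to the coordinates a volcano plot
#' consumes: `log2_fc = log2(fold_change)` and `neg_log10_p =
#' -log10(p_value)`.  Flagged records (undefined fold change) are
#' dropped.
#'
#' @param records A `de_table`.
#' @return Data frame with `gene`, `log2_fc`, `neg_log10_p`, `class`.
#' @export
volcano_table <- function(records) {
  stopifnot(inherits(records, "de_table"))
  keep <- !records$flagged
  data.frame(gene = records$gene[keep],
             log2_fc = log2(records$fold_change[keep]),
             neg_log10_p = -log10(records$p_value[keep]),
             class = records$class[keep], row.names = NULL)
}
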