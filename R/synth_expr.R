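#' Specification of a synthetic grouped count matrix
#'
#' Describes a negative-binomial simulation of a multiplexed expression
#' panel: a baseline mean per gene, per-group planted effects on the
#' log2 scale, per-sample library-size factors (log-normal, so
#' housekeeping normalization has something to remove), an additive
#' Poisson background shared by all probes, and negative-control probe
#' rows carrying background only.
#'
#' Groups are ordered; the first group is the reference (all planted
#' effects are expressed relative to it).  Housekeeping genes always
#' carry zero planted effect in every group — they respond to the
#' library factor only.  The canonical three-group layout used
#' throughout this package is `control`, `disease`, `treated`:
#' `n_up` genes are planted up in disease vs control
#' (`up_log2fc`), and of these a fraction `reversal_fraction` is planted
#' to move back down under treatment (treated vs disease log2 effect
#' `reversed_log2fc` < 0) while the rest keep drifting up
#' (`nonreversed_log2fc` > 0).
#'
#' @param n_genes Number of endogenous genes (housekeeping included).
#' @param housekeeping Housekeeping gene names (default the 10-gene
#'   panel of [default_housekeeping()]).
#' @param groups Named integer vector of per-group sample counts, in
#'   order (first = reference); every count must be >= 2.
#' @param effects Optional genes x groups matrix of planted log2
#'   effects relative to the reference group (rownames = gene names,
#'   colnames = group names).  If `NULL` it is built from the
#'   `n_up`/`reversal_fraction` scenario below.
#' @param n_up Number of genes planted up in group 2 vs group 1.
#' @param up_log2fc Planted disease log2 fold change (default 3 — large,
#'   so downstream classification is exact).
#' @param reversal_fraction Fraction of planted-up genes whose treated
#'   vs disease effect has the opposite sign, in \[0, 1\].
#' @param reversed_log2fc,nonreversed_log2fc Treated-vs-disease log2
#'   effects for reversed / non-reversed planted genes.
#' @param dispersion Negative-binomial dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`.
#' @param baseline_mean Baseline expected count per gene.
#' @param libsize_sigma SD of the per-sample log-normal library factor.
#' @param background_mean Additive Poisson background per probe (also
#'   the mean of the negative-control rows).
#' @param n_negative Number of negative-control probe rows.
#' @param seed Integer seed.
#' @return An object of class `expr_sim_spec`.
#' @seealso [simulate_expression()]
#' @export
expr_sim_spec <- function(n_genes = 770L,
                          housekeeping = default_housekeeping(),
                          groups = c(control = 10L, disease = 10L, treated = 10L),
                          effects = NULL,
                          n_up = 99L, up_log2fc = 3,
                          reversal_fraction = 71 / 99,
                          reversed_log2fc = -1.5, nonreversed_log2fc = 0.75,
                          dispersion = 0.05, baseline_mean = 500,
                          libsize_sigma = 0.2, background_mean = 20,
                          n_negative = 6L, seed = 1L) {
  if (dispersion <= 0) stop("`dispersion` must be > 0")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("`groups` must be a named vector of sample counts")
  if (any(groups < 2L)) stop("every group needs >= 2 samples")
  if (reversal_fraction < 0 || reversal_fraction > 1)
    stop("`reversal_fraction` must be in [0, 1]")
  if (n_genes < length(housekeeping) + n_up)
    stop("`n_genes` too small for housekeeping set plus planted genes")
  if (baseline_mean <= 0) stop("`baseline_mean` must be > 0")
  if (libsize_sigma < 0 || background_mean < 0)
    stop("`libsize_sigma` and `background_mean` must be >= 0")
  gene_names <- c(housekeeping,
                  sprintf("Gene%04d", seq_len(n_genes - length(housekeeping))))
  if (is.null(effects)) {
    effects <- matrix(0, n_genes, length(groups),
                      dimnames = list(gene_names, names(groups)))
    if (n_up > 0) {
      planted <- setdiff(gene_names, housekeeping)[seq_len(n_up)]
      if (length(groups) >= 2L) effects[planted, 2L] <- up_log2fc
      if (length(groups) >= 3L) {
        n_rev <- round(reversal_fraction * n_up)
        rev_genes <- planted[seq_len(n_rev)]
        fwd_genes <- setdiff(planted, rev_genes)
        # group-3 effect is relative to reference: disease effect plus the
        # treated-vs-disease increment
        effects[rev_genes, 3L] <- up_log2fc + reversed_log2fc
        effects[fwd_genes, 3L] <- up_log2fc + nonreversed_log2fc
      }
    }
  } else {
    effects <- as.matrix(effects)
    if (nrow(effects) != n_genes || ncol(effects) != length(groups))
      stop("`effects` must be genes x groups")
    if (is.null(rownames(effects))) rownames(effects) <- gene_names
    if (is.null(colnames(effects))) colnames(effects) <- names(groups)
    gene_names <- rownames(effects)
  }
  if (any(effects[housekeeping, ] != 0))
    stop("housekeeping genes must carry zero planted effect")
  structure(
    list(n_genes = as.integer(n_genes), housekeeping = housekeeping,
         groups = groups, effects = effects, gene_names = gene_names,
         dispersion = dispersion, baseline_mean = baseline_mean,
         libsize_sigma = libsize_sigma, background_mean = background_mean,
         n_negative = as.integer(n_negative), seed = as.integer(seed)),
    class = "expr_sim_spec")
}

#' Simulate a grouped negative-binomial count matrix with ground truth
#'
#' Draws counts `NB(mu = baseline_mean * 2^effect * L_s, size =
#' 1/dispersion)` where `L_s` is the sample's log-normal library factor,
#' then adds Poisson background to every probe.  Negative-control rows
#' carry background only (no library scaling — background in a
#' hybridization assay is additive, not proportional to input).
#' Deterministic given `spec$seed`.
#'
#' @param spec An [expr_sim_spec()].
#' @return List with `matrix` (an [expression_matrix()]) and
#'   `ground_truth`: data frame per gene with planted per-group log2
#'   effects and logical flags `planted_up`, `planted_down` (group 2 vs
#'   1) and `planted_reversed` (group 3 vs 2 sign opposite to group 2
#'   vs 1), plus the drawn `library_factor` per sample.
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "expr_sim_spec"))
  set.seed(spec$seed)
  n_samp <- sum(spec$groups)
  group_of <- factor(rep(names(spec$groups), spec$groups),
                     levels = names(spec$groups))
  sample_names <- paste0(rep(names(spec$groups), spec$groups), "_",
                         unlist(lapply(spec$groups, seq_len)))
  lib <- exp(stats::rnorm(n_samp, 0, spec$libsize_sigma))

  mu <- spec$baseline_mean * 2^spec$effects[, as.integer(group_of), drop = FALSE]
  mu <- sweep(mu, 2, lib, `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
                   nrow(mu), ncol(mu))
  if (spec$background_mean > 0)
    counts <- counts + matrix(stats::rpois(length(counts), spec$background_mean),
                              nrow(counts), ncol(counts))
  neg_names <- character(0)
  if (spec$n_negative > 0) {
    neg_names <- sprintf("NEG_%s", LETTERS[seq_len(spec$n_negative)])
    neg <- matrix(stats::rpois(spec$n_negative * n_samp, max(spec$background_mean, 1)),
                  spec$n_negative, n_samp)
    counts <- rbind(counts, neg)
  }
  rownames(counts) <- c(spec$gene_names, neg_names)
  colnames(counts) <- sample_names

  eff <- spec$effects
  lfc_disease <- if (ncol(eff) >= 2L) eff[, 2L] - eff[, 1L] else rep(0, nrow(eff))
  lfc_treat <- if (ncol(eff) >= 3L) eff[, 3L] - eff[, 2L] else rep(0, nrow(eff))
  gt <- data.frame(
    gene = spec$gene_names,
    is_housekeeping = spec$gene_names %in% spec$housekeeping,
    log2fc_disease = unname(lfc_disease),
    log2fc_treatment = unname(lfc_treat),
    planted_up = unname(lfc_disease > 0),
    planted_down = unname(lfc_disease < 0),
    planted_reversed = unname(lfc_disease != 0 & lfc_treat != 0 &
                                sign(lfc_treat) != sign(lfc_disease)))
  m <- expression_matrix(counts, groups = as.character(group_of),
                         housekeeping = spec$housekeeping,
                         negative_controls = neg_names)
  list(matrix = m,
       ground_truth = list(genes = gt,
                           samples = data.frame(sample = sample_names,
                                                group = as.character(group_of),
                                                library_factor = lib)))
}
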