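#' The default housekeeping panel
#'
#' The ten reference genes whose geometric mean anchors normalization of
#' the mouse neuroinflammation panel.
#' @return Character vector of 10 gene symbols.
#' @export
default_housekeeping <- function() {
  c("Csnk2a2", "Ccdc127", "Xpnpep1", "Lars", "Supt7l",
    "Tada2b", "Aars", "Mto1", "Tbp", "Fam104a")
}

#' Gene-by-sample expression matrix with group labels
#'
#' Container for nonnegative count data from a multiplexed expression
#' panel: a genes x samples matrix, a sample-to-group map, a designated
#' housekeeping gene set and (optionally) negative-control probe rows
#' used for background subtraction.
#'
#' @param counts Numeric matrix (genes x samples), rownames = gene
#'   names, colnames = sample names, values >= 0.
#' @param groups Character or factor vector of group labels, one per
#'   sample (recycled names from `colnames(counts)` if unnamed).
#' @param housekeeping Character vector of housekeeping gene names; must
#'   be a subset of `rownames(counts)`.
#' @param negative_controls Character vector of row names that are
#'   negative-control probes (may be empty).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, groups,
                              housekeeping = default_housekeeping(),
                              negative_controls = character(0)) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have gene rownames and sample colnames")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (length(groups) != ncol(counts))
    stop("`groups` must give one label per sample")
  if (anyNA(groups)) stop("every sample must have a group")
  groups <- as.factor(as.character(groups))
  names(groups) <- colnames(counts)
  missing_hk <- setdiff(housekeeping, rownames(counts))
  if (length(missing_hk))
    stop("housekeeping genes absent from matrix: ", paste(missing_hk, collapse = ", "))
  missing_nc <- setdiff(negative_controls, rownames(counts))
  if (length(missing_nc))
    stop("negative-control rows absent from matrix: ", paste(missing_nc, collapse = ", "))
  structure(
    list(counts = counts, groups = groups, housekeeping = housekeeping,
         negative_controls = negative_controls),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  groups:", paste(sprintf("%s (n=%d)", levels(x$groups),
                                 tabulate(x$groups)), collapse = ", "), "\n")
  cat(sprintf("  housekeeping: %d genes; negative controls: %d rows\n",
              length(x$housekeeping), length(x$negative_controls)))
  invisible(x)
}

#' Endogenous (non-control) gene names of an expression matrix
#' @param m An `expression_matrix`.
#' @return Character vector of row names excluding negative controls.
#' @export
endogenous_genes <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  setdiff(rownames(m$counts), m$negative_controls)
}
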