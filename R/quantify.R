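#' Per-plaque and per-field measurements
#'
#' Measures every labelled plaque: area (`n_pixels * pixel_size^2`),
#' integrated intensity (sum of the source channel over the object's
#' pixels) and intensity-unweighted centroid (0-based pixel coords).
#' Field-level totals include the plaque count, total plaque area, the
#' percentage of the field area covered, total integrated intensity,
#' and mean fluorescence intensity computed both over plaque pixels
#' only and over the whole field (the two conventions in circulation
#' for "mean intensity"; both are emitted).
#'
#' @param plaques A [label_mask()] of segmented plaques.
#' @param intensity The source intensity channel (same shape).
#' @return A list of class `plaque_table`: `plaques` (one row per
#'   object: `id`, `area_um2`, `integrated_intensity`, `centroid_row`,
#'   `centroid_col`) and `field` (one row of totals).
#' @export
quantify_plaques <- function(plaques, intensity) {
  stopifnot(inherits(plaques, "label_mask"))
  if (!all(dim(plaques$labels) == dim(intensity)))
    stop("intensity channel and mask shapes differ")
  px <- plaques$pixel_size
  lab <- plaques$labels
  n <- n_objects(plaques)
  fa <- field_area_um2(dim(lab), px)
  if (n == 0L) {
    per <- data.frame(id = integer(0), area_um2 = numeric(0),
                      integrated_intensity = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0))
    fld <- data.frame(plaque_count = 0L, total_plaque_area_um2 = 0,
                      percent_area_covered = 0, total_intensity = 0,
                      mean_intensity_plaque_px = NA_real_,
                      mean_intensity_field = mean(intensity),
                      field_area_um2 = fa)
    return(structure(list(plaques = per, field = fld), class = "plaque_table"))
  }
  fg <- lab > 0L
  l <- lab[fg]
  npix <- tabulate(l, nbins = n)
  isum <- as.vector(rowsum(intensity[fg], l))
  idx <- which(fg, arr.ind = TRUE)
  crow <- as.vector(rowsum(idx[, 1] - 1, l)) / npix   # 0-based centres
  ccol <- as.vector(rowsum(idx[, 2] - 1, l)) / npix
  per <- data.frame(id = seq_len(n), area_um2 = npix * px^2,
                    integrated_intensity = isum,
                    centroid_row = crow, centroid_col = ccol)
  fld <- data.frame(plaque_count = n,
                    total_plaque_area_um2 = sum(per$area_um2),
                    percent_area_covered = sum(per$area_um2) / fa * 100,
                    total_intensity = sum(isum),
                    mean_intensity_plaque_px = sum(isum) / sum(npix),
                    mean_intensity_field = mean(intensity),
                    field_area_um2 = fa)
  structure(list(plaques = per, field = fld), class = "plaque_table")
}

#' @export
print.plaque_table <- function(x, ...) {
  cat(sprintf("plaque_table: %d plaque(s), %.2f um^2 total (%.3f%% of field)\n",
              x$field$plaque_count, x$field$total_plaque_area_um2,
              x$field$percent_area_covered))
  invisible(x)
}

#' Call marker-positive cells by nucleus / glial-signal overlap
#'
#' A detected nucleus is a positive glial cell iff its mask shares at
#' least one pixel with the glial-marker foreground (any-overlap rule —
#' the literal reading of overlap-based positivity; a `centroid` rule,
#' requiring the nucleus centroid itself to fall on glial foreground,
#' is available as an option).  All other nuclei are excluded.
#'
#' @param glial_mask A [label_mask()] (treated as binary foreground) of
#'   the glial channel.
#' @param nuclei A [label_mask()] of segmented nuclei.
#' @param marker Marker name recorded in the output (e.g. `"Iba1"`).
#' @param rule `"any_pixel"` (default) or `"centroid"`.
#' @return Data frame of class `cell_table`: one row per positive cell
#'   with `nucleus_label`, `centroid_row`, `centroid_col`, `marker`.
#' @export
detect_positive_cells <- function(glial_mask, nuclei, marker = "glial",
                                  rule = c("any_pixel", "centroid")) {
  rule <- match.arg(rule)
  stopifnot(inherits(glial_mask, "label_mask"), inherits(nuclei, "label_mask"))
  if (!all(dim(glial_mask$labels) == dim(nuclei$labels)))
    stop("glial and nuclei masks have incompatible shapes")
  if (glial_mask$pixel_size != nuclei$pixel_size)
    stop("glial and nuclei masks have incompatible calibrations")
  glial_fg <- glial_mask$labels > 0L
  lab <- nuclei$labels
  pos_labels <- integer(0)
  n <- n_objects(nuclei)
  if (n > 0L) {
    if (rule == "any_pixel") {
      overlap <- unique(lab[lab > 0L & glial_fg])
      pos_labels <- sort(overlap)
    } else {
      for (l in seq_len(n)) {
        idx <- which(lab == l, arr.ind = TRUE)
        cen <- round(colMeans(idx))
        if (glial_fg[cen[1], cen[2]]) pos_labels <- c(pos_labels, l)
      }
    }
  }
  rows <- lapply(pos_labels, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    data.frame(nucleus_label = l,
               centroid_row = mean(idx[, 1] - 1),
               centroid_col = mean(idx[, 2] - 1),
               marker = marker)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(nucleus_label = integer(0), centroid_row = numeric(0),
               centroid_col = numeric(0), marker = character(0))
  class(out) <- c("cell_table", "data.frame")
  out
}
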