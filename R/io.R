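#' Write a field image as multi-page TIFF with a YAML sidecar
#'
#' One grayscale page per channel, 16-bit.  Intensities are scaled by
#' `intensity_scale` into \[0, 1\] for storage (so values are quantized
#' to `intensity_scale / 65535` steps); the sidecar
#' (`<path>.yaml`) records channel names, calibration, metadata and the
#' scale so [read_field_tiff()] can restore original units.
#'
#' @param field A [field_image()].
#' @param path Output TIFF path.
#' @param intensity_scale Full-scale intensity mapped to 1.0; default
#'   the smallest power of two above the data maximum.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path, intensity_scale = NULL) {
  stopifnot(inherits(field, "field_image"))
  mx <- max(vapply(field$channels, max, numeric(1)), 1)
  if (is.null(intensity_scale)) intensity_scale <- 2^ceiling(log2(mx))
  pages <- lapply(field$channels, function(ch) pmin(ch / intensity_scale, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(channels = names(field$channels),
               pixel_size_um = field$pixel_size,
               field_id = field$field_id, region = field$region,
               group = field$group, intensity_scale = intensity_scale)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a field image written by [write_field_tiff()]
#'
#' Also reads any multi-page grayscale TIFF if channel names and
#' calibration are supplied explicitly.
#'
#' @param path TIFF path.
#' @param channels Channel names (default from the YAML sidecar).
#' @param pixel_size Micrometres per pixel (default from the sidecar).
#' @param intensity_scale Scale restoring original units (default from
#'   the sidecar, else 1).
#' @return A [field_image()].
#' @export
read_field_tiff <- function(path, channels = NULL, pixel_size = NULL,
                            intensity_scale = NULL) {
  meta <- list()
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) meta <- yaml::read_yaml(sidecar)
  if (is.null(channels)) channels <- meta$channels
  if (is.null(pixel_size)) pixel_size <- meta$pixel_size_um
  if (is.null(intensity_scale))
    intensity_scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  if (is.null(channels) || is.null(pixel_size))
    stop("channel names and pixel_size must come from the sidecar or arguments")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(channels))
    stop("TIFF has ", length(pages), " page(s) but ", length(channels),
         " channel name(s) given")
  chans <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p * intensity_scale
  })
  names(chans) <- channels
  field_image(chans, pixel_size,
              field_id = if (!is.null(meta$field_id)) meta$field_id else "field",
              region = if (!is.null(meta$region)) meta$region else NA_character_,
              group = if (!is.null(meta$group)) meta$group else NA_character_)
}

#' Write / read an expression matrix as CSV
#'
#' Counts go to one CSV (first column `gene`, one column per sample);
#' the sample-to-group map to a second CSV (`sample`, `group`).
#' Housekeeping genes and negative-control rows are identified on read
#' by the `housekeeping` argument and a rowname prefix (default
#' `"NEG_"`).
#'
#' @param m An [expression_matrix()].
#' @param counts_path,groups_path CSV paths.
#' @return `counts_path`, invisibly.
#' @export
write_expression_csv <- function(m, counts_path, groups_path) {
  stopifnot(inherits(m, "expression_matrix"))
  df <- data.frame(gene = rownames(m$counts), m$counts,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, counts_path, row.names = FALSE)
  utils::write.csv(data.frame(sample = colnames(m$counts),
                              group = as.character(m$groups)),
                   groups_path, row.names = FALSE)
  invisible(counts_path)
}

#' @rdname write_expression_csv
#' @param housekeeping Housekeeping gene names (default panel).
#' @param negative_prefix Rowname prefix marking negative-control rows.
#' @export
read_expression_csv <- function(counts_path, groups_path,
                                housekeeping = default_housekeeping(),
                                negative_prefix = "NEG_") {
  df <- utils::read.csv(counts_path, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  gr <- utils::read.csv(groups_path)
  if (!all(colnames(counts) %in% gr$sample))
    stop("samples missing from the group map: ",
         paste(setdiff(colnames(counts), gr$sample), collapse = ", "))
  groups <- gr$group[match(colnames(counts), gr$sample)]
  expression_matrix(counts, groups,
                    housekeeping = intersect(housekeeping, rownames(counts)),
                    negative_controls = grep(paste0("^", negative_prefix),
                                             rownames(counts), value = TRUE))
}
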