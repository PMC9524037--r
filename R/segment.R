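#' Otsu threshold of an intensity channel
#'
#' Global two-class Otsu threshold computed on a 256-level histogram of
#' the channel's intensity range.  Returns the threshold in the
#' channel's original intensity units; pixels strictly above it are
#' foreground.  A constant channel has no foreground and returns `Inf`.
#'
#' @param channel Nonnegative numeric matrix.
#' @return Scalar threshold (original units), or `Inf` if the channel
#'   is constant.
#' @export
otsu_threshold <- function(channel) {
  rng <- range(channel)
  if (diff(rng) == 0) return(Inf)
  scaled <- (channel - rng[1]) / diff(rng)
  thr01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256L)
  rng[1] + thr01 * diff(rng)
}

# union-find with path halving
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Label connected components of a binary mask
#'
#' 8-connectivity (edge- and corner-adjacent foreground pixels belong to
#' the same object) by default, built on 4-connected labelling with a
#' union-find merge of diagonally adjacent components.  Objects are
#' renumbered 1..N by the column-major scan position of each
#' component's first pixel, which makes labelling deterministic.
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @param pixel_size Micrometres per pixel.
#' @param connectivity 8 (default) or 4.
#' @return A [label_mask()].
#' @export
label_components <- function(mask, pixel_size, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("`connectivity` must be 4 or 8")
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)   # 4-connected
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  nmax <- max(lab)
  if (connectivity == 8L && nmax > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # \ diagonal
    a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]    # / diagonal
    keep1 <- a1 > 0L & b1 > 0L & a1 != b1
    keep2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                          cbind(a2[keep2], b2[keep2])))
    if (nrow(pairs)) {
      parent <- seq_len(nmax)
      for (k in seq_len(nrow(pairs))) {
        ra <- uf_find(parent, pairs[k, 1]); rb <- uf_find(parent, pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nmax), function(i) uf_find(parent, i), integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  relabel_scan_order(lab, pixel_size)
}

# renumber positive labels 1..N by first occurrence in column-major order
relabel_scan_order <- function(lab, pixel_size) {
  pos <- which(lab > 0L)
  if (length(pos)) {
    first_seen <- unique(lab[pos])            # order of first occurrence
    map <- integer(max(lab))
    map[first_seen] <- seq_along(first_seen)
    lab[pos] <- map[lab[pos]]
  }
  label_mask(lab, pixel_size)
}

#' Segment one channel into labelled objects
#'
#' Binary threshold (global Otsu by default, or a fixed value), then
#' 8-connected component labelling, then removal of objects smaller
#' than `min_area_um2`.  Surviving objects are renumbered 1..N in scan
#' order.  An all-background channel yields an empty mask (0 objects),
#' not an error.  Objects touching the field border are kept.
#'
#' @param channel Nonnegative numeric matrix.
#' @param pixel_size Micrometres per pixel.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Fixed threshold (original units), required when
#'   `method = "fixed"`; pixels strictly above it are foreground.
#' @param min_area_um2 Minimum object area in um^2 (objects strictly
#'   smaller are removed); >= 0.
#' @param connectivity Component connectivity, 8 (default) or 4.
#' @return A [label_mask()] with the applied threshold stored in
#'   attribute `"threshold"`.
#' @export
segment_channel <- function(channel, pixel_size,
                            method = c("otsu", "fixed"), threshold = NULL,
                            min_area_um2 = 0, connectivity = 8L) {
  method <- match.arg(method)
  if (any(channel < 0)) stop("channel intensities must be >= 0")
  if (min_area_um2 < 0) stop("`min_area_um2` must be >= 0")
  thr <- switch(method,
                otsu = otsu_threshold(channel),
                fixed = {
                  if (is.null(threshold)) stop("`threshold` required for method = 'fixed'")
                  threshold
                })
  mask <- label_components(channel > thr, pixel_size, connectivity)
  if (min_area_um2 > 0 && n_objects(mask) > 0) {
    area <- tabulate(mask$labels[mask$labels > 0L]) * pixel_size^2
    drop <- which(area < min_area_um2)
    if (length(drop)) {
      lab <- mask$labels
      lab[lab %in% drop] <- 0L
      mask <- relabel_scan_order(lab, pixel_size)
    }
  }
  attr(mask, "threshold") <- thr
  mask
}
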