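#' Specification of a synthetic confocal scene
#'
#' Describes one ground-truth field: disk-shaped amyloid plaques, glial
#' cells (a soma disk rendered into the glial channel when the cell is
#' marker-positive, and a nucleus disk always rendered into the nuclear
#' channel) and additive Gaussian noise on a constant background.
#' Default geometry follows the acquisition this package targets:
#' 1024 x 1024 pixels at 0.63 um/pixel.
#'
#' Coordinates are 0-based pixel indices of disk centres; a pixel's
#' position is its centre, and a pixel belongs to a disk iff its centre
#' lies within the radius (no anti-aliasing), so disk areas have exact
#' pixel-counting oracles.
#'
#' @param field_shape Integer `c(rows, cols)` of the field.
#' @param pixel_size Micrometres per pixel (> 0).
#' @param plaques Data frame with columns `row`, `col` (0-based pixel
#'   coords of the centre), `radius_um`, `peak` (peak intensity, a.u.).
#'   Zero-row data frame for an empty scene.
#' @param cells Data frame with columns `row`, `col`, `soma_radius_um`,
#'   `nucleus_radius_um`, `marker_positive` (logical).
#' @param background_mean,background_sd Constant background level and the
#'   standard deviation of the additive Gaussian noise (intensities are
#'   clipped at 0 after noise).
#' @param soma_intensity,nucleus_intensity Rendered intensities of soma
#'   and nucleus disks (a.u.).
#' @param seed Integer seed; all randomness in [render_scene()] derives
#'   from it.
#' @return An object of class `scene_spec`.
#' @seealso [render_scene()], [random_scene_spec()]
#' @export
scene_spec <- function(field_shape = c(1024L, 1024L), pixel_size = 0.63,
                       plaques = empty_plaques(), cells = empty_cells(),
                       background_mean = 10, background_sd = 2,
                       soma_intensity = 120, nucleus_intensity = 150,
                       seed = 1L) {
  field_shape <- as.integer(field_shape)
  if (length(field_shape) != 2L || any(field_shape < 1L))
    stop("`field_shape` must be two positive integers")
  if (pixel_size <= 0) stop("`pixel_size` must be > 0")
  plaques <- as.data.frame(plaques)
  cells <- as.data.frame(cells)
  need_p <- c("row", "col", "radius_um", "peak")
  need_c <- c("row", "col", "soma_radius_um", "nucleus_radius_um", "marker_positive")
  if (!all(need_p %in% names(plaques)))
    stop("`plaques` needs columns: ", paste(need_p, collapse = ", "))
  if (!all(need_c %in% names(cells)))
    stop("`cells` needs columns: ", paste(need_c, collapse = ", "))
  if (nrow(plaques) && any(plaques$radius_um <= 0))
    stop("plaque radii must be > 0")
  if (nrow(cells) && any(cells$soma_radius_um <= 0 | cells$nucleus_radius_um <= 0))
    stop("cell radii must be > 0")
  if (nrow(cells) && any(cells$nucleus_radius_um > cells$soma_radius_um))
    stop("nucleus_radius_um must not exceed soma_radius_um")
  inside <- function(r, c) r >= 0 & r <= field_shape[1] - 1 & c >= 0 & c <= field_shape[2] - 1
  if (nrow(plaques) && !all(inside(plaques$row, plaques$col)))
    stop("plaque centres must lie inside the field")
  if (nrow(cells) && !all(inside(cells$row, cells$col)))
    stop("cell centres must lie inside the field")
  if (background_mean < 0 || background_sd < 0)
    stop("background parameters must be >= 0")
  structure(
    list(field_shape = field_shape, pixel_size = pixel_size,
         plaques = plaques, cells = cells,
         background_mean = background_mean, background_sd = background_sd,
         soma_intensity = soma_intensity, nucleus_intensity = nucleus_intensity,
         seed = as.integer(seed)),
    class = "scene_spec")
}

#' @rdname scene_spec
#' @export
empty_plaques <- function() {
  data.frame(row = numeric(0), col = numeric(0),
             radius_um = numeric(0), peak = numeric(0))
}

#' @rdname scene_spec
#' @export
empty_cells <- function() {
  data.frame(row = numeric(0), col = numeric(0),
             soma_radius_um = numeric(0), nucleus_radius_um = numeric(0),
             marker_positive = logical(0))
}

# pixel-centre disk rasterizer: TRUE where hypot(r - row0, c - col0) * px <= radius_um
disk_mask <- function(shape, row0, col0, radius_um, pixel_size) {
  r_px <- radius_um / pixel_size
  rows <- seq.int(0L, shape[1] - 1L)
  cols <- seq.int(0L, shape[2] - 1L)
  dr2 <- (rows - row0)^2
  dc2 <- (cols - col0)^2
  outer(dr2, dc2, `+`) <= r_px^2
}

#' Render a synthetic scene to a calibrated field image with ground truth
#'
#' Deterministically (given `spec$seed`) rasterizes the scene into three
#' channels: `plaque` (one disk per plaque at its stated peak intensity;
#' overlapping disks take the pixelwise maximum and are flagged as merged
#' in the ground truth), `glial` (soma disks of marker-positive cells
#' only) and `nuclear` (one nucleus disk per cell).  Additive Gaussian
#' noise (sd `background_sd`) on the constant background is applied to
#' every channel independently and clipped at 0.  Channels do not bleed
#' into each other.
#'
#' The ground truth records, for every planted object, its exact
#' continuous geometry, the rasterized pixel count of each plaque, and
#' for every cell the Euclidean distance from its centre to the nearest
#' plaque boundary circle (`dist_boundary_um`, unsigned) and to the
#' nearest plaque region (`dist_region_um`, 0 inside a plaque) — the
#' quantity that drives plaque association at a physical radius.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `field` (a [field_image()]) and
#'   `ground_truth` (list of data frames `plaques` and `cells`).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  sh <- spec$field_shape
  px <- spec$pixel_size
  base <- matrix(spec$background_mean, sh[1], sh[2])
  plaque_ch <- base
  glial_ch <- base
  nuclear_ch <- base

  pl <- spec$plaques
  n_pixels <- integer(nrow(pl))
  if (nrow(pl)) {
    for (i in seq_len(nrow(pl))) {
      m <- disk_mask(sh, pl$row[i], pl$col[i], pl$radius_um[i], px)
      n_pixels[i] <- sum(m)
      plaque_ch[m] <- pmax(plaque_ch[m], pl$peak[i])
    }
  }
  cl <- spec$cells
  if (nrow(cl)) {
    for (i in seq_len(nrow(cl))) {
      nm <- disk_mask(sh, cl$row[i], cl$col[i], cl$nucleus_radius_um[i], px)
      nuclear_ch[nm] <- pmax(nuclear_ch[nm], spec$nucleus_intensity)
      if (isTRUE(cl$marker_positive[i])) {
        sm <- disk_mask(sh, cl$row[i], cl$col[i], cl$soma_radius_um[i], px)
        glial_ch[sm] <- pmax(glial_ch[sm], spec$soma_intensity)
      }
    }
  }
  if (spec$background_sd > 0) {
    noise <- function(ch) pmax(ch + matrix(stats::rnorm(length(ch), 0, spec$background_sd),
                                           nrow(ch), ncol(ch)), 0)
    plaque_ch <- noise(plaque_ch); glial_ch <- noise(glial_ch); nuclear_ch <- noise(nuclear_ch)
  }

  # plaque ground truth: continuous geometry + merge flags
  merged <- rep(FALSE, nrow(pl))
  if (nrow(pl) > 1L) {
    for (i in seq_len(nrow(pl) - 1L)) for (j in seq.int(i + 1L, nrow(pl))) {
      d_um <- sqrt((pl$row[i] - pl$row[j])^2 + (pl$col[i] - pl$col[j])^2) * px
      if (d_um <= pl$radius_um[i] + pl$radius_um[j]) merged[c(i, j)] <- TRUE
    }
  }
  gt_plaques <- cbind(data.frame(id = seq_len(nrow(pl))), pl,
                      n_pixels = n_pixels, merged = merged)

  gt_cells <- cbind(data.frame(id = seq_len(nrow(cl))), cl)
  if (nrow(cl)) {
    if (nrow(pl)) {
      d_um <- outer(seq_len(nrow(cl)), seq_len(nrow(pl)),
                    function(i, j) sqrt((cl$row[i] - pl$row[j])^2 +
                                        (cl$col[i] - pl$col[j])^2) * px)
      bdry <- abs(sweep(d_um, 2, pl$radius_um))          # |dist to centre - radius|
      regn <- pmax(sweep(d_um, 2, pl$radius_um), 0)      # 0 inside the disk
      gt_cells$dist_boundary_um <- apply(bdry, 1, min)
      gt_cells$dist_region_um <- apply(regn, 1, min)
      gt_cells$nearest_plaque <- apply(regn, 1, which.min)  # ties -> lower id
    } else {
      gt_cells$dist_boundary_um <- Inf
      gt_cells$dist_region_um <- Inf
      gt_cells$nearest_plaque <- NA_integer_
    }
  } else {
    gt_cells$dist_boundary_um <- numeric(0)
    gt_cells$dist_region_um <- numeric(0)
    gt_cells$nearest_plaque <- integer(0)
  }

  field <- field_image(
    channels = list(plaque = plaque_ch, glial = glial_ch, nuclear = nuclear_ch),
    pixel_size = px)
  list(field = field, ground_truth = list(plaques = gt_plaques, cells = gt_cells))
}

#' Draw a random, well-separated scene specification
#'
#' Places `n_plaques` plaque disks and `n_cells` cells uniformly in the
#' field by rejection sampling so that plaques do not overlap each other
#' and cells do not overlap plaques or each other (minimum separation
#' `2 * soma radius + margin`).  Used to build ground-truth recovery
#' fixtures where every planted object must remain an isolated connected
#' component.
#'
#' @param seed Integer seed.
#' @param field_shape,pixel_size Field geometry (defaults as in
#'   [scene_spec()]).
#' @param n_plaques,n_cells Object counts.
#' @param plaque_radius_um Range (min, max) of plaque radii.
#' @param peak_intensity Range of plaque peak intensities.
#' @param soma_radius_um,nucleus_radius_um Cell geometry (um).
#' @param prop_positive Probability that a cell is marker-positive.
#' @param margin_um Extra separation between object envelopes.
#' @param ... Passed to [scene_spec()] (noise, intensities).
#' @return A [scene_spec()].
#' @export
random_scene_spec <- function(seed, field_shape = c(1024L, 1024L),
                              pixel_size = 0.63, n_plaques = 5L, n_cells = 25L,
                              plaque_radius_um = c(8, 20),
                              peak_intensity = c(80, 160),
                              soma_radius_um = 5, nucleus_radius_um = 3,
                              prop_positive = 0.7, margin_um = 4, ...) {
  set.seed(seed)
  ext_um <- (field_shape - 1) * pixel_size
  place <- function(n, radius_um, existing, clear_um) {
    # rejection-sample centres so each new object's envelope stays clear
    out <- data.frame(row = numeric(0), col = numeric(0), radius_um = numeric(0))
    if (n == 0L) return(out)
    max_pad <- (max(radius_um) + margin_um) / pixel_size
    if (2 * max_pad >= min(field_shape) - 1)
      stop("objects of radius ", max(radius_um), " um do not fit the field")
    tries <- 0L
    while (nrow(out) < n && tries < 20000L) {
      tries <- tries + 1L
      r_um <- stats::runif(1, radius_um[1], radius_um[length(radius_um)])
      pad <- (r_um + margin_um) / pixel_size
      row <- stats::runif(1, pad, field_shape[1] - 1 - pad)
      col <- stats::runif(1, pad, field_shape[2] - 1 - pad)
      all_prev <- rbind(existing[, c("row", "col", "radius_um")], out)
      ok <- TRUE
      if (nrow(all_prev)) {
        d_um <- sqrt((all_prev$row - row)^2 + (all_prev$col - col)^2) * pixel_size
        ok <- all(d_um > all_prev$radius_um + r_um + clear_um)
      }
      if (ok) out <- rbind(out, data.frame(row = row, col = col, radius_um = r_um))
    }
    if (nrow(out) < n)
      stop("could not place ", n, " objects without overlap; reduce counts or radii")
    out
  }
  pl <- place(n_plaques, plaque_radius_um,
              data.frame(row = numeric(0), col = numeric(0), radius_um = numeric(0)),
              clear_um = margin_um)
  pl$peak <- stats::runif(nrow(pl), peak_intensity[1], peak_intensity[2])
  cells <- place(n_cells, rep(soma_radius_um, 2), pl, clear_um = soma_radius_um + margin_um)
  cells <- data.frame(row = cells$row, col = cells$col,
                      soma_radius_um = rep(soma_radius_um, nrow(cells)),
                      nucleus_radius_um = rep(nucleus_radius_um, nrow(cells)),
                      marker_positive = stats::runif(nrow(cells)) < prop_positive)
  scene_spec(field_shape = field_shape, pixel_size = pixel_size,
             plaques = pl, cells = cells, seed = seed, ...)
}
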