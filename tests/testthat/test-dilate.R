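test_that("radius 0 dilation is the identity on foreground", {
  m <- random_label_mask(1)
  lab <- label_components(m, 0.63)
  z <- dilate_labels(lab, 0)
  expect_identical(z$labels, lab$labels)
})

test_that("single-pixel dilation matches the all-pairs distance oracle", {
  px <- 1
  m <- matrix(0L, 21, 21); m[11, 11] <- 1L
  lab <- label_mask(m, px)
  for (r in c(1, 2, 3.5)) {
    z <- dilate_labels(lab, r)
    bf <- brute_force_edt(m) <= r
    expect_identical(z$labels > 0, bf)
  }
})

test_that("physical radii are honoured at non-integer pixel distances", {
  # 20 um at 0.63 um/px thresholds the distance map at 31.746 px
  px <- 0.63
  m <- matrix(0L, 81, 81); m[41, 41] <- 1L
  z <- dilate_labels(label_mask(m, px), 20)
  d_px <- brute_force_edt(m)
  expect_identical(z$labels > 0, d_px <= 20 / 0.63)
  # 31 px along the axis is inside, 32 px outside
  expect_equal(z$labels[41, 41 + 31], 1L)
  expect_equal(z$labels[41 + 32, 41], 0L)
})

test_that("dilation equals morphological dilation by a Euclidean disk", {
  px <- 0.63
  for (s in 1:5) {
    m <- random_label_mask(s, shape = c(64L, 64L))
    lab <- label_components(m, px)
    for (r_um in c(0, 5, 20)) {
      z <- dilate_labels(lab, r_um)
      oracle <- disk_stamp_dilate(lab$labels > 0, r_um / px)
      expect_identical(z$labels > 0, oracle)
    }
  }
})

test_that("zone labels follow the nearest plaque, ties to the lower label", {
  px <- 1
  m <- matrix(0L, 11, 21)
  m[6, 3] <- 1L    # becomes label 1 (earlier column-major scan)
  m[6, 19] <- 2L   # label 2
  lab <- label_components(m, px)
  z <- dilate_labels(lab, 50)
  # midpoint column 11 is equidistant (8 px each) -> lower label wins
  expect_equal(z$labels[6, 11], 1L)
  expect_equal(z$labels[6, 10], 1L)
  expect_equal(z$labels[6, 12], 2L)
  # distance map attribute is the true EDT in um
  expect_equal(attr(z, "distance_um"), brute_force_edt(m) * px)
})

test_that("diameter interpretation halves the effective distance", {
  m <- matrix(0L, 41, 41); m[21, 21] <- 1L
  lab <- label_mask(m, 1)
  z_rad <- dilate_labels(lab, 10)
  z_dia <- dilate_labels(lab, 10, interpretation = "diameter")
  expect_identical(z_dia$labels, dilate_labels(lab, 5)$labels)
  expect_gt(sum(z_rad$labels > 0), sum(z_dia$labels > 0))
})

test_that("degenerate dilation inputs are handled", {
  expect_error(dilate_labels(label_mask(matrix(0L, 5, 5), 1), -1),
               "nonnegative")
  z <- dilate_labels(label_mask(matrix(0L, 5, 5), 1), 10)
  expect_equal(n_objects(z), 0)
  expect_true(all(attr(z, "distance_um") == Inf))
})

test_that("associated-cell counts are monotone in radius and conserved", {
  sp <- random_scene_spec(seed = 17, field_shape = c(256L, 256L),
                          n_plaques = 3, n_cells = 15, background_sd = 0)
  out <- render_scene(sp)
  f <- out$field
  plaques <- segment_channel(f$channels$plaque, sp$pixel_size)
  glia <- segment_channel(f$channels$glial, sp$pixel_size)
  nuclei <- segment_channel(f$channels$nuclear, sp$pixel_size)
  cells <- detect_positive_cells(glia, nuclei)
  prev <- -1L
  for (r in c(0, 5, 10, 20, 40, 80, 1000)) {
    a <- count_associated_cells(cells, nuclei,
                                dilate_labels(plaques, r))
    expect_gte(a$n_cells_associated, prev)
    # single-credit rule: per-plaque counts partition the associated set
    expect_equal(sum(a$per_plaque$n_cells), a$n_cells_associated)
    prev <- a$n_cells_associated
  }
  # at effectively infinite radius every positive cell is associated
  expect_equal(prev, nrow(cells))
})

test_that("association follows nucleus distance to the plaque boundary", {
  px <- 1
  # plaque disk radius 5 at (20,20); nucleus disk radius 2 centred 25 um
  # from the boundary -> min distance 23 um > 20: not associated
  mk_scene <- function(cell_row) {
    scene_spec(field_shape = c(120L, 120L), pixel_size = px,
               plaques = data.frame(row = 20, col = 20, radius_um = 5, peak = 100),
               cells = data.frame(row = cell_row, col = 20, soma_radius_um = 2,
                                  nucleus_radius_um = 2, marker_positive = TRUE),
               background_mean = 0, background_sd = 0, seed = 1)
  }
  run <- function(sp) {
    out <- render_scene(sp)
    f <- out$field
    plaques <- segment_channel(f$channels$plaque, px)
    glia <- segment_channel(f$channels$glial, px)
    nuclei <- segment_channel(f$channels$nuclear, px)
    cells <- detect_positive_cells(glia, nuclei)
    count_associated_cells(cells, nuclei, dilate_labels(plaques, 20))
  }
  far <- run(mk_scene(20 + 5 + 25))   # boundary distance 25 um
  expect_equal(far$n_cells_associated, 0)
  touch <- run(mk_scene(20 + 5 + 1))  # nucleus touches the plaque itself
  expect_equal(touch$n_cells_associated, 1)
  expect_equal(touch$per_plaque$n_cells, 1)
})

test_that("cells referencing absent nucleus labels are an error", {
  nuclei <- label_mask(matrix(0L, 10, 10), 1)
  zones <- dilate_labels(label_mask(matrix(0L, 10, 10), 1), 5)
  cells <- data.frame(nucleus_label = 3L, centroid_row = 1, centroid_col = 1,
                      marker = "x")
  class(cells) <- c("cell_table", "data.frame")
  expect_error(count_associated_cells(cells, nuclei, zones), "absent")
  # zones without a distance map are rejected
  raw_zones <- label_mask(matrix(0L, 10, 10), 1)
  empty_cells_tbl <- cells[0, ]
  expect_error(count_associated_cells(empty_cells_tbl, nuclei, raw_zones),
               "distance map")
})
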