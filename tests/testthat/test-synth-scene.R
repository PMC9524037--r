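test_that("empty noise-free scene renders constant background", {
  sp <- scene_spec(field_shape = c(32L, 32L), background_mean = 7,
                   background_sd = 0, seed = 1)
  out <- render_scene(sp)
  for (ch in out$field$channels)
    expect_true(all(ch == 7))
  expect_equal(nrow(out$ground_truth$plaques), 0)
  expect_equal(nrow(out$ground_truth$cells), 0)
})

test_that("rendered disk area matches the pixel-centre counting oracle", {
  px <- 0.63
  sp <- scene_spec(field_shape = c(128L, 128L), pixel_size = px,
                   plaques = data.frame(row = 63, col = 63, radius_um = 10,
                                        peak = 100),
                   background_mean = 0, background_sd = 0, seed = 1)
  out <- render_scene(sp)
  # oracle: count pixels whose centre lies within 10 um of the centre
  d2 <- outer(((0:127) - 63)^2, ((0:127) - 63)^2, `+`) * px^2
  oracle_pixels <- sum(d2 <= 10^2)
  rendered_pixels <- sum(out$field$channels$plaque > 0)
  expect_identical(rendered_pixels, oracle_pixels)
  expect_identical(out$ground_truth$plaques$n_pixels, oracle_pixels)
  # within one pixel-ring of the analytic disk area pi * 10^2
  expect_lt(abs(rendered_pixels * px^2 - pi * 100), 2 * pi * 10 * px)
})

test_that("rendering is deterministic given the seed", {
  sp <- random_scene_spec(seed = 42, field_shape = c(160L, 160L),
                          n_plaques = 2, n_cells = 6,
                          plaque_radius_um = c(4, 8))
  a <- render_scene(sp)
  b <- render_scene(sp)
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$ground_truth, b$ground_truth)
  # a different seed perturbs the noise
  sp2 <- sp; sp2$seed <- 43L
  expect_false(identical(render_scene(sp2)$field$channels$plaque,
                         a$field$channels$plaque))
})

test_that("channels carry only their own objects", {
  sp <- scene_spec(field_shape = c(64L, 64L), pixel_size = 1,
                   plaques = data.frame(row = 16, col = 16, radius_um = 5,
                                        peak = 100),
                   cells = data.frame(row = 48, col = 48, soma_radius_um = 4,
                                      nucleus_radius_um = 2,
                                      marker_positive = c(TRUE)),
                   background_mean = 0, background_sd = 0, seed = 1)
  out <- render_scene(sp)
  ch <- out$field$channels
  expect_true(all(ch$plaque[40:60, 40:60] == 0))   # cell absent from plaque channel
  expect_true(all(ch$glial[1:30, 1:30] == 0))      # plaque absent from glial channel
  expect_gt(sum(ch$nuclear > 0), 0)
  # marker-negative cell renders a nucleus but no soma
  sp$cells$marker_positive <- FALSE
  out2 <- render_scene(scene_spec(field_shape = c(64L, 64L), pixel_size = 1,
                                  plaques = sp$plaques, cells = sp$cells,
                                  background_mean = 0, background_sd = 0,
                                  seed = 1))
  expect_true(all(out2$field$channels$glial == 0))
  expect_gt(sum(out2$field$channels$nuclear > 0), 0)
})

test_that("ground-truth cell distances agree with rasterized plaque boundaries", {
  # exact continuous distance to the plaque circle vs brute-force minimum
  # over boundary pixels of the rendered mask; they agree to within the
  # one-pixel discretization band of the raster
  for (s in 1:3) {
    sp <- random_scene_spec(seed = s, field_shape = c(160L, 160L),
                            n_plaques = 2, n_cells = 8,
                            background_mean = 0, background_sd = 0)
    out <- render_scene(sp)
    mask <- out$field$channels$plaque > 0
    lab <- flood_fill_label(mask)
    interior <- mask
    interior[-1, ] <- interior[-1, ] & mask[-nrow(mask), ]
    interior[-nrow(mask), ] <- interior[-nrow(mask), ] & mask[-1, ]
    interior[, -1] <- interior[, -1] & mask[, -ncol(mask)]
    interior[, -ncol(mask)] <- interior[, -ncol(mask)] & mask[, -1]
    bp <- which(mask & !interior, arr.ind = TRUE) - 1  # 0-based boundary pixels
    gt <- out$ground_truth$cells
    for (i in seq_len(nrow(gt))) {
      bf <- min(sqrt((bp[, 1] - gt$row[i])^2 + (bp[, 2] - gt$col[i])^2)) *
        sp$pixel_size
      expect_lt(abs(bf - gt$dist_boundary_um[i]), sp$pixel_size)
    }
  }
})

test_that("overlapping plaques are flagged as merged", {
  sp <- scene_spec(field_shape = c(64L, 64L), pixel_size = 1,
                   plaques = data.frame(row = c(20, 26, 50), col = c(20, 20, 50),
                                        radius_um = c(5, 5, 5),
                                        peak = c(100, 100, 100)),
                   background_mean = 0, background_sd = 0, seed = 1)
  out <- render_scene(sp)
  expect_equal(out$ground_truth$plaques$merged, c(TRUE, TRUE, FALSE))
})

test_that("invalid scene specifications are rejected", {
  expect_error(scene_spec(field_shape = c(32L, 32L),
                          plaques = data.frame(row = 40, col = 10,
                                               radius_um = 2, peak = 10)),
               "inside the field")
  expect_error(scene_spec(field_shape = c(32L, 32L),
                          cells = data.frame(row = 10, col = 10,
                                             soma_radius_um = 2,
                                             nucleus_radius_um = 3,
                                             marker_positive = TRUE)),
               "nucleus_radius_um")
  expect_error(scene_spec(pixel_size = 0), "pixel_size")
  expect_error(scene_spec(field_shape = c(32L, 32L),
                          plaques = data.frame(row = 1, col = 1,
                                               radius_um = -1, peak = 1)),
               "radii")
})
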