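# Generators: determinism, conservation, parameter convergence, degenerate
# settings, and exactness of the conditioned fixture totals.

test_that("identical params and seed give bit-identical EM scenes", {
  p <- sg_preset("em_interphase", n_cells = 3, seed = 42)
  a <- generate_em_scene(p)
  b <- generate_em_scene(p)
  expect_identical(a, b)
  c <- generate_em_scene(sg_preset("em_interphase", n_cells = 3, seed = 43))
  expect_false(identical(a, c))
})

test_that("EM generator honors degenerate and conditioned settings", {
  # cortical_probability 1: every granule within the shell
  p1 <- em_scene_params(n_cells = 2, granules_per_cell = 40,
                        cortical_probability = 1, seed = 9)
  for (sc in generate_em_scene(p1)) {
    d <- dist_to_polygon(sc$granules, sc$boundary)
    expect_true(all(d <= 500))
    expect_true(all(sc$ground_truth$in_shell_true))
  }
  # exact totals via the multinomial-conditioned path
  fx <- generate_em_scene(sg_preset("em_interphase_fixture"))
  expect_identical(sum(vapply(fx, function(s) nrow(s$granules), integer(1))),
                   227L)
  fx2 <- generate_em_scene(sg_preset("em_metaphase_fixture"))
  expect_identical(sum(vapply(fx2, function(s) nrow(s$granules), integer(1))),
                   376L)
  # one ground-truth record per granule, centroids inside the boundary
  for (sc in c(fx, fx2)) {
    expect_identical(nrow(sc$ground_truth), nrow(sc$granules))
    expect_true(all(mgcv::in.out(rbind(sc$boundary, sc$boundary[1L, ]),
                                 sc$granules)))
  }
  # invalid shell rejected
  expect_error(em_scene_params(shell_thickness_nm = 6000,
                               cell_radius_nm = 5000),
               "smaller than")
})

test_that("EM shell fraction converges to the placement probability", {
  p <- em_scene_params(n_cells = 1, granules_per_cell = 1000,
                       cortical_probability = 0.5, seed = 3)
  sc <- generate_em_scene(p)[[1]]
  frac <- mean(sc$ground_truth$in_shell_true)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.5 * 0.5 / 1000))
})

test_that("fluorescence scenes are deterministic with exact ground truth", {
  p <- fluor_scene_params(n_cells = 4, responder_probability = 0.5, seed = 21)
  a <- generate_fluorescence_scene(p)
  b <- generate_fluorescence_scene(p)
  expect_identical(a, b)
  expect_identical(nrow(a$truth$cells), 4L)
  expect_identical(length(a$truth$polygons), 4L)
  # every rendered cell occupies pixels in the truth label map
  expect_setequal(sort(unique(as.vector(a$truth$label_map[a$truth$label_map > 0]))),
                  1:4)
})

test_that("no responders and no noise give a uniform SgII background", {
  p <- fluor_scene_params(n_cells = 1, responder_probability = 0,
                          noise_sd = 0, background_mean = 7, seed = 2)
  out <- generate_fluorescence_scene(p)
  expect_true(all(out$scene$channels$SgII == 7))
  expect_false(out$truth$cells$responder_flag)
})

test_that("responder draws follow the class-specific probabilities", {
  p <- sg_preset("fluor_stimulated", n_cells = 100, seed = 7)
  out <- generate_fluorescence_scene(p)
  n_resp <- sum(out$truth$cells$responder_flag)
  # binomial sampling band around 81 per 100 interphase cells
  expect_lt(abs(n_resp - 81), 3 * sqrt(100 * 0.81 * 0.19) + 1)
  # metaphase surface means are scaled by the class factor
  p2 <- sg_preset("fluor_stimulated", n_cells = 40,
                  stage_classes = rep("metaphase", 40),
                  responder_probability = 1, seed = 3)
  tr <- generate_fluorescence_scene(p2)$truth$cells
  expect_true(all(tr$true_surface_mean_au == 30 * 0.61))
})

test_that("paired layout renders a shared ridge between touching cells", {
  p <- fluor_scene_params(n_cells = 2, cluster_layout = "paired",
                          responder_probability = 0, noise_sd = 0, seed = 6)
  out <- generate_fluorescence_scene(p)
  L <- out$truth$label_map
  bm <- classify_borders(make_label_map(L))
  shared <- c(bm$internal[["1"]], bm$internal[["2"]])
  expect_gt(length(shared), 0L)
  ring <- out$scene$channels$WGA >= 200
  # the shared border is covered by the bright ridge regardless of which
  # cell's membrane rendered it
  expect_true(all(ring[shared]))
})

test_that("track sets are deterministic and honor degenerate motion", {
  p <- sg_preset("tracks_anaphase", n_tracks = 6, seed = 11)
  a <- generate_track_set(p)
  expect_identical(a, generate_track_set(p))
  expect_identical(nrow(a$ground_truth), 6L)

  p0 <- track_set_params(n_tracks = 3, speed_mean_um_s = 0,
                         speed_sd_um_s = 0, localization_noise_nm = 0,
                         fraction_directed = 1, n_frames = 5, seed = 4)
  ts <- generate_track_set(p0)
  for (tr in split(ts$tracks, ts$tracks$track_id)) {
    expect_true(all(abs(diff(tr$row_px)) < 1e-12))
    expect_true(all(abs(diff(tr$col_px)) < 1e-12))
  }
})

test_that("a noiseless directed track steps exactly speed * dt", {
  p <- track_set_params(n_tracks = 1, speed_mean_um_s = 0.1,
                        speed_sd_um_s = 0, frame_interval_s = 1,
                        localization_noise_nm = 0, fraction_directed = 1,
                        on_skeleton_fraction = 0, curvature_sd_rad = 0,
                        n_frames = 10, pixel_size_nm = 100, seed = 5)
  ts <- generate_track_set(p)
  tr <- ts$tracks
  steps_nm <- sqrt(diff(tr$row_px)^2 + diff(tr$col_px)^2) * 100
  expect_equal(steps_nm, rep(100, 9), tolerance = 1e-9)
})

test_that("preset speed draws match the published velocity distribution", {
  ts <- generate_track_set(sg_preset("tracks_anaphase", n_tracks = 50,
                                     fraction_directed = 1, seed = 11))
  sp <- ts$ground_truth$true_speed_um_s
  expect_lt(abs(mean(sp) - 0.23), 2 * 0.09 / sqrt(50))
})

test_that("preset registry is total and immutable-by-copy", {
  expect_setequal(sg_preset_names(),
                  c("em_interphase", "em_metaphase", "em_interphase_fixture",
                    "em_metaphase_fixture", "fluor_stimulated",
                    "fluor_control", "tracks_anaphase", "tracks_cytokinesis"))
  expect_error(sg_preset("nope"), "unknown preset")
  a <- sg_preset("em_interphase")
  b <- sg_preset("em_interphase", cortical_probability = 0.2)
  expect_equal(a$cortical_probability, 0.70)
  expect_equal(b$cortical_probability, 0.2)
  expect_equal(sg_preset("em_metaphase")$cortical_probability, 0.13)
  expect_equal(sg_preset("fluor_stimulated")$responder_probability,
               c(interphase = 0.81, metaphase = 0.67))
  expect_equal(sg_preset("fluor_stimulated")$intensity_scale_by_class[["metaphase"]],
               0.61)
  expect_equal(sg_preset("tracks_cytokinesis")$speed_mean_um_s, 0.34)
})
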