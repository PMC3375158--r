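# Surface-mask construction and densitometry.

test_that("ribbon equals brute-force Chebyshev dilation on toy rasters", {
  # straight 1-px border segment of length 10 in an open field: the width-3
  # ribbon is 7 px wide with square end caps
  L <- matrix(0L, 30, 30)
  L[10, 8:17] <- 1L
  bm <- structure(list(outer = list(`1` = which(L == 1L)),
                       internal = list(`1` = integer()),
                       labels = L, dim = dim(L)),
                  class = "border_mask")
  mask <- build_surface_mask(bm, 3)
  ref <- brute_chebyshev_ribbon(which(L == 1L), 3, L, 1L)
  expect_setequal(mask$pixels[["1"]], ref)
  expect_identical(length(mask$pixels[["1"]]), 7L * 16L)  # (10+2*3) cols x 7 rows
  # width 0: the mask is exactly the outer border set
  m0 <- build_surface_mask(bm, 0)
  expect_setequal(m0$pixels[["1"]], which(L == 1L))
})

test_that("ribbons exclude every pixel of a touching neighbor", {
  L <- rect_labels(24, 24, list(list(rows = 6:18, cols = 4:11),
                                list(rows = 6:18, cols = 12:19)))
  bm <- classify_borders(make_label_map(L))
  mask <- build_surface_mask(bm, 3)
  for (k in c("1", "2")) {
    other <- if (k == "1") 2L else 1L
    expect_length(intersect(mask$pixels[[k]], which(L == other)), 0L)
    ref <- brute_chebyshev_ribbon(bm$outer[[k]], 3, L, as.integer(k))
    expect_setequal(mask$pixels[[k]], ref)
  }
})

test_that("cluster-internal and edge-touching cells are flagged unquantifiable", {
  # a cell fully surrounded by another has no outer border
  L <- matrix(0L, 30, 30)
  L[5:25, 5:25] <- 1L
  L[12:18, 12:18] <- 2L
  bm <- classify_borders(make_label_map(L))
  expect_length(bm$outer[["2"]], 0L)
  # cell 1 touches nothing but the image interior; cell at the edge is cut
  Le <- matrix(0L, 20, 20)
  Le[1:8, 1:8] <- 1L
  bme <- classify_borders(make_label_map(Le))
  me <- build_surface_mask(bme, 3)
  expect_true("1" %in% names(me$excluded))
  expect_match(me$excluded[["1"]], "edge")
  m <- build_surface_mask(bm, 3)
  expect_true("2" %in% names(m$excluded))
})

test_that("densitometry matches hand arithmetic on a toy image", {
  img <- matrix(0, 5, 5)
  img[cbind(c(1, 2, 3, 3, 4, 5), c(1, 2, 3, 4, 4, 5))] <- c(2, 4, 6, 8, 10, 12)
  L <- matrix(0L, 5, 5)
  L[cbind(c(1, 2, 3, 3, 4, 5), c(1, 2, 3, 4, 4, 5))] <- 1L
  mask <- structure(list(pixels = list(`1` = which(L == 1L)),
                         width_each_side = 0L, excluded = character(),
                         dim = c(5L, 5L)),
                    class = "surface_mask")
  rec <- measure_surface_intensity(sgii_scene(img), mask)
  expect_identical(rec$mask_area, 6L)
  expect_identical(rec$total_intensity, 42)
  expect_identical(rec$mean_intensity, 7)
  # a constant field measures its constant, whatever the mask
  recc <- measure_surface_intensity(sgii_scene(matrix(3.5, 5, 5)), mask)
  expect_identical(recc$mean_intensity, 3.5)
})

test_that("background subtraction and responder rules match hand counts", {
  stim <- data.frame(cell_id = 1:2, stage_class = "interphase",
                     condition = "stimulated", total_intensity = c(20, 5),
                     mask_area = c(10L, 10L), mean_intensity = c(2.0, 0.5))
  ctrl <- data.frame(mean_intensity = c(0.4, 0.6))
  out <- suppressMessages(subtract_background(stim, ctrl))
  expect_identical(attr(out, "background"), 0.5)
  expect_equal(out$corrected_mean, c(1.5, 0.0))
  expect_error(subtract_background(stim, ctrl[0, , drop = FALSE]),
               "background undefined")
  # responders: strictly positive corrected mean
  rec <- data.frame(cell_id = 1:3, stage_class = "interphase",
                    corrected_mean = c(-1, 0.2, 3))
  cl <- classify_responders(rec)
  expect_equal(cl$fractions$responder_fraction, 100 * 2 / 3)
  zero <- data.frame(cell_id = 1:4, stage_class = "metaphase",
                     corrected_mean = rep(0, 4))
  expect_equal(classify_responders(zero)$fractions$responder_fraction, 0)
})

test_that("population summary computes the class-relative intensity", {
  rec <- data.frame(
    cell_id = 1:4,
    stage_class = c("interphase", "interphase", "metaphase", "metaphase"),
    corrected_mean = c(2, 4, 1.5, 1.5),
    responder = TRUE)
  s <- summarize_population(rec)
  expect_equal(s$relative_intensity, 50)
  # identical class distributions: 100%
  rec2 <- rec
  rec2$corrected_mean <- c(2, 4, 2, 4)
  expect_equal(summarize_population(rec2)$relative_intensity, 100)
  # missing class: explicit NA
  s3 <- summarize_population(rec[rec$stage_class == "interphase", ])
  expect_true(is.na(s3$relative_intensity))
  expect_identical(s3$per_class$n_cells[s3$per_class$stage_class == "metaphase"],
                   0L)
})

test_that("mask splitting preserves totals and area-weighted means", {
  set.seed(31)
  img <- matrix(runif(400, 0, 10), 20, 20)
  px <- sample(400, 60)
  mk <- function(p) structure(
    list(pixels = list(`1` = sort(p)), width_each_side = 0L,
         excluded = character(), dim = c(20L, 20L)),
    class = "surface_mask")
  whole <- measure_surface_intensity(sgii_scene(img), mk(px))
  a <- measure_surface_intensity(sgii_scene(img), mk(px[1:25]))
  b <- measure_surface_intensity(sgii_scene(img), mk(px[26:60]))
  expect_equal(whole$total_intensity, a$total_intensity + b$total_intensity)
  expect_equal(whole$mean_intensity,
               (a$mean_intensity * a$mask_area + b$mean_intensity * b$mask_area) /
                 (a$mask_area + b$mask_area))
})

test_that("corrected means are equivariant under a global background shift", {
  out <- generate_fluorescence_scene(
    sg_preset("fluor_stimulated", n_cells = 6, seed = 17))
  ctrl <- generate_fluorescence_scene(
    sg_preset("fluor_control", n_cells = 4, seed = 18))
  shift <- function(sc, c) {
    sc$channels$SgII <- sc$channels$SgII + c
    sc
  }
  q0 <- suppressMessages(quantify_surface(out$scene, ctrl$scene))
  q1 <- suppressMessages(quantify_surface(shift(out$scene, 12.5),
                                          shift(ctrl$scene, 12.5)))
  expect_equal(q1$records$corrected_mean, q0$records$corrected_mean,
               tolerance = 1e-10)
})

test_that("raising SgII inside one ribbon only raises that cell's value", {
  out <- generate_fluorescence_scene(
    sg_preset("fluor_stimulated", n_cells = 4, seed = 19))
  ctrl <- generate_fluorescence_scene(
    sg_preset("fluor_control", n_cells = 4, seed = 20))
  ann <- out$scene$annotations
  lab <- segment_cells(out$scene, seeds = cbind(ann$seed_row, ann$seed_col))
  mask <- build_surface_mask(classify_borders(lab), 3)
  bumped <- out$scene
  bumped$channels$SgII[mask$pixels[["2"]]] <-
    bumped$channels$SgII[mask$pixels[["2"]]] + 5
  q0 <- suppressMessages(quantify_surface(out$scene, ctrl$scene))
  q1 <- suppressMessages(quantify_surface(bumped, ctrl$scene))
  delta <- q1$records$corrected_mean - q0$records$corrected_mean
  expect_gt(delta[q1$records$cell_id == 2], 0)
  expect_equal(delta[q1$records$cell_id != 2], rep(0, 3), tolerance = 1e-12)
})

test_that("noise-free synthetic control background equals the generator mean", {
  ctrl <- generate_fluorescence_scene(
    sg_preset("fluor_control", n_cells = 4, background_mean = 9, seed = 23))
  q <- suppressMessages(quantify_surface(ctrl$scene, ctrl$scene))
  expect_equal(q$background, 9, tolerance = 1e-10)
  expect_equal(q$records$corrected_mean, rep(0, 4), tolerance = 1e-10)
})
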