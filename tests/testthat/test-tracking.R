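# Detection, linking, track summaries, colocalization.

gauss_frame <- function(dim, centers, amp = 100, sigma = 1.5) {
  sgquant:::stamp_gaussians(matrix(0, dim[1], dim[2]),
                            centers[, 1], centers[, 2], amp, sigma)
}

test_that("blob detection finds rendered spots to subpixel accuracy", {
  expect_identical(nrow(detect_puncta(matrix(0, 40, 40), 1.5, 1)), 0L)
  ctr <- matrix(c(17.3, 22.6), 1)
  d <- detect_puncta(gauss_frame(c(40, 40), ctr), sigma_px = 1.5,
                     threshold = 5)
  expect_identical(nrow(d), 1L)
  expect_lt(max(abs(c(d$row_px, d$col_px) - ctr)), 0.5)
  # two spots 10 px apart resolve into two matched detections
  ctr2 <- rbind(c(15.2, 14.8), c(15.2, 24.8))
  d2 <- detect_puncta(gauss_frame(c(40, 40), ctr2), 1.5, 5)
  expect_identical(nrow(d2), 2L)
  d2 <- d2[order(d2$col_px), ]
  expect_lt(max(abs(cbind(d2$row_px, d2$col_px) - ctr2)), 0.5)
})

test_that("an unambiguous detection sequence links into one full track", {
  det <- data.frame(frame = 1:6, row_px = 10 + (0:5) * 2, col_px = 20)
  tr <- link_tracks(det, max_disp_px = 4)
  expect_identical(unique(tr$track_id), 1L)
  expect_identical(nrow(tr), 6L)
  # a long jump breaks the track at the first over-limit link
  det2 <- det
  det2$row_px[4:6] <- det2$row_px[4:6] + 30
  tr2 <- link_tracks(det2, max_disp_px = 4)
  expect_identical(max(tr2$track_id), 2L)
})

test_that("parallel tracks are recovered with all links correct", {
  ts <- generate_track_set(track_set_params(
    n_tracks = 2, speed_mean_um_s = 0.2, speed_sd_um_s = 0,
    fraction_directed = 1, on_skeleton_fraction = 0, curvature_sd_rad = 0,
    localization_noise_nm = 0, n_frames = 8, seed = 31))
  det <- ts$tracks[, c("frame", "row_px", "col_px")]
  # shuffle within frames: linking must be order invariant
  det_shuf <- det[withr::with_seed(1, sample(nrow(det))), ]
  tr <- link_tracks(det, max_disp_px = 6)
  tr_shuf <- link_tracks(det_shuf, max_disp_px = 6)
  expect_identical(max(tr$track_id), 2L)
  expect_equal(tr[order(tr$track_id, tr$frame), ],
               tr_shuf[order(tr_shuf$track_id, tr_shuf$frame), ],
               ignore_attr = TRUE)
  # every link connects points of one generating track
  key <- merge(tr, ts$tracks, by = c("frame", "row_px", "col_px"))
  expect_identical(length(unique(paste(key$track_id.x, key$track_id.y))), 2L)
})

test_that("conflicting nearest neighbors follow the mutual-NN rule", {
  # frame 1: a at (0,0), b at (0,10); frame 2: c at (0,4).
  # c's nearest is a and a's nearest is c -> link; b stays unlinked.
  det <- data.frame(frame = c(1, 1, 2),
                    row_px = c(5, 5, 5),
                    col_px = c(1, 11, 5))
  tr <- link_tracks(det, max_disp_px = 6)
  expect_identical(nrow(tr), 2L)
  expect_setequal(tr$col_px, c(1, 5))
  # brute-force optimal assignment on this 2x1 case picks the same pair
  d_ac <- 4; d_bc <- 6
  expect_lt(d_ac, d_bc)
})

test_that("track summaries match hand arithmetic", {
  tr <- data.frame(frame = 1:5, row_px = 10, col_px = 1:5)
  s <- summarize_track(tr, pixel_size_nm = 100, frame_interval_s = 1)
  expect_equal(s$mean_velocity_um_s, 0.1)
  expect_equal(s$straightness, 1)
  expect_true(s$directed)
  expect_equal(s$path_length_um, 0.4)
  # stationary track: zero velocity, straightness defined to 0, not directed
  st <- data.frame(frame = 1:4, row_px = 7, col_px = 7)
  ss <- summarize_track(st)
  expect_equal(ss$mean_velocity_um_s, 0)
  expect_equal(ss$straightness, 0)
  expect_false(ss$directed)
  # three detections can never be directed, however straight
  s3 <- summarize_track(tr[1:3, ], pixel_size_nm = 100)
  expect_false(s3$directed)
  # net-displacement variant
  zig <- data.frame(frame = 1:5, row_px = c(0, 1, 0, 1, 0), col_px = 0)
  expect_equal(summarize_track(zig, 100, 1, velocity = "net")$mean_velocity_um_s,
               0)
  expect_error(summarize_track(data.frame(frame = c(1, 3), row_px = 1,
                                          col_px = 1)),
               "consecutive")
})

test_that("velocity scales with calibration as required", {
  tr <- data.frame(frame = 1:6, row_px = seq(2, 12, 2), col_px = 3)
  v1 <- summarize_track(tr, 100, 1)$mean_velocity_um_s
  expect_equal(summarize_track(tr, 200, 1)$mean_velocity_um_s, 2 * v1)
  expect_equal(summarize_track(tr, 100, 2)$mean_velocity_um_s, v1 / 2)
})

test_that("colocalization fractions follow the skeleton geometry", {
  skel <- matrix(0L, 40, 40)
  skel[20, ] <- 1L  # straight horizontal filament
  on_tr <- data.frame(frame = 1:5, row_px = 20, col_px = seq(5, 25, 5))
  off_tr <- data.frame(frame = 1:5, row_px = 25, col_px = seq(5, 25, 5))
  expect_equal(mt_colocalization(on_tr, skel, 2), 1)
  expect_equal(mt_colocalization(off_tr, skel, 2), 0)  # 5 px offset
  expect_equal(mt_colocalization(on_tr, matrix(0L, 40, 40), 2), 0)
})

test_that("on-skeleton tracks separate cleanly from off-skeleton tracks", {
  ts <- generate_track_set(track_set_params(
    n_tracks = 30, speed_mean_um_s = 0.23, speed_sd_um_s = 0.05,
    fraction_directed = 1, on_skeleton_fraction = 0.5,
    localization_noise_nm = 20, n_frames = 12, seed = 41))
  summ <- summarize_tracks(ts$tracks, skeleton = ts$skeleton, radius_px = 2,
                           pixel_size_nm = 100, frame_interval_s = 1)
  m <- merge(summ, ts$ground_truth, by = "track_id")
  on_mean <- mean(m$mt_coloc_fraction[m$on_skeleton])
  off_mean <- mean(m$mt_coloc_fraction[!m$on_skeleton])
  expect_gte(on_mean - off_mean, 0.5)
})

test_that("directed velocity estimation is unbiased at low noise", {
  # consistency across replicate seeds on ground-truth-linked tracks
  errs <- vapply(1:20, function(i) {
    ts <- generate_track_set(track_set_params(
      n_tracks = 20, speed_mean_um_s = 0.23, speed_sd_um_s = 0.0,
      fraction_directed = 1, localization_noise_nm = 20,
      n_frames = 15, seed = 100 + i))
    summ <- summarize_tracks(ts$tracks, pixel_size_nm = 100,
                             frame_interval_s = 1)
    mean(summ$mean_velocity_um_s) - 0.23
  }, numeric(1))
  # noise inflates path length slightly; bias must stay below 5%
  expect_lt(mean(abs(errs)), 0.05 * 0.23)
})
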