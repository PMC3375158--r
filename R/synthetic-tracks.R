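#' Parameters for synthetic particle-track sets
#'
#' Describes a set of 2-D punctum trajectories: directed tracks move at a
#' constant per-track speed drawn from a Normal distribution truncated at
#' zero, along straight or gently curved paths, optionally constrained to
#' run along a synthetic filament skeleton (emulating granules transported
#' on spindle microtubules); non-directed tracks are isotropic Gaussian
#' random walks. Every reported position is perturbed by isotropic Gaussian
#' localization noise; the unperturbed truth is recorded per track.
#'
#' @param n_tracks number of tracks.
#' @param speed_mean_um_s,speed_sd_um_s directed-speed distribution, um/s.
#' @param frame_interval_s time between frames, seconds.
#' @param n_frames frames per track (>= 2).
#' @param localization_noise_nm s.d. of isotropic localization noise, nm.
#' @param fraction_directed probability a track is directed.
#' @param diffusive_step_sd_nm per-frame step s.d. for non-directed tracks.
#' @param on_skeleton_fraction probability a directed track runs along the
#'   filament skeleton.
#' @param pixel_size_nm camera calibration, nm per pixel.
#' @param field_px image field side length, pixels (square field).
#' @param curvature_sd_rad s.d. of the per-frame heading change of directed
#'   tracks (gentle curvature; 0 gives straight paths).
#' @param n_filaments number of straight filaments in the skeleton.
#' @param seed integer seed.
#' @return object of class `track_set_params`.
#' @export
track_set_params <- function(n_tracks = 50L,
                             speed_mean_um_s = 0.23,
                             speed_sd_um_s = 0.09,
                             frame_interval_s = 1,
                             n_frames = 20L,
                             localization_noise_nm = 20,
                             fraction_directed = 0.7,
                             diffusive_step_sd_nm = 50,
                             on_skeleton_fraction = 0.7,
                             pixel_size_nm = 100,
                             field_px = 512L,
                             curvature_sd_rad = 0.03,
                             n_filaments = 6L,
                             seed = 1L) {
  stopifnot(
    n_tracks >= 1L,
    speed_mean_um_s >= 0, speed_sd_um_s >= 0,
    frame_interval_s > 0, n_frames >= 2L,
    localization_noise_nm >= 0,
    fraction_directed >= 0, fraction_directed <= 1,
    diffusive_step_sd_nm >= 0,
    on_skeleton_fraction >= 0, on_skeleton_fraction <= 1,
    pixel_size_nm > 0, field_px >= 32L
  )
  structure(
    list(n_tracks = as.integer(n_tracks),
         speed_mean_um_s = speed_mean_um_s,
         speed_sd_um_s = speed_sd_um_s,
         frame_interval_s = frame_interval_s,
         n_frames = as.integer(n_frames),
         localization_noise_nm = localization_noise_nm,
         fraction_directed = fraction_directed,
         diffusive_step_sd_nm = diffusive_step_sd_nm,
         on_skeleton_fraction = on_skeleton_fraction,
         pixel_size_nm = pixel_size_nm,
         field_px = as.integer(field_px),
         curvature_sd_rad = curvature_sd_rad,
         n_filaments = as.integer(n_filaments),
         seed = as.integer(seed)),
    class = "track_set_params"
  )
}

#' Generate a synthetic track set with skeleton and ground truth
#'
#' @param params a [track_set_params()] object (or preset).
#' @return list with `tracks` (data frame: `track_id`, `frame`, `row_px`,
#'   `col_px`, noisy observed positions), `skeleton` (binary matrix,
#'   1 = filament), and `ground_truth` (per track: `track_id`,
#'   `true_speed_um_s`, `directed`, `on_skeleton`).
#' @examples
#' ts <- generate_track_set(sg_preset("tracks_anaphase", n_tracks = 5, seed = 11))
#' head(ts$tracks)
#' @export
generate_track_set <- function(params) {
  stopifnot(inherits(params, "track_set_params"))
  local_rng(params$seed, render_track_set(params))
}

render_track_set <- function(params) {
  n <- params$n_tracks
  fp <- params$field_px
  px <- params$pixel_size_nm

  # filament skeleton: straight lines through random points
  fil <- lapply(seq_len(params$n_filaments), function(i) {
    p0 <- stats::runif(2L, 0.15 * fp, 0.85 * fp)
    ang <- stats::runif(1L, 0, pi)
    list(p0 = p0, dir = c(sin(ang), cos(ang)))   # (row, col) direction
  })
  skeleton <- matrix(0L, fp, fp)
  for (f in fil) {
    tt <- seq(-fp, fp, by = 0.25)
    rr <- round(f$p0[1L] + tt * f$dir[1L])
    cc <- round(f$p0[2L] + tt * f$dir[2L])
    keep <- rr >= 1L & rr <= fp & cc >= 1L & cc <= fp
    skeleton[cbind(rr[keep], cc[keep])] <- 1L
  }

  directed <- stats::runif(n) < params$fraction_directed
  on_skel <- directed & (stats::runif(n) < params$on_skeleton_fraction)
  speeds <- numeric(n)
  speeds[directed] <- truncnorm0(sum(directed), params$speed_mean_um_s,
                                 params$speed_sd_um_s)

  # separated starting points on a jittered grid to keep linking unambiguous
  ncol_g <- ceiling(sqrt(n))
  spacing <- (fp - 80) / ncol_g
  grid <- expand.grid(gr = seq_len(ncol_g), gc = seq_len(ncol_g))[seq_len(n), ]
  start_row <- 40 + (grid$gr - 0.5) * spacing + stats::runif(n, -3, 3)
  start_col <- 40 + (grid$gc - 0.5) * spacing + stats::runif(n, -3, 3)

  step_px <- speeds * 1000 / px * params$frame_interval_s  # px per frame
  noise_px <- params$localization_noise_nm / px
  diff_px <- params$diffusive_step_sd_nm / px

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    nf <- params$n_frames
    pos <- matrix(0, nf, 2L)
    if (directed[i] && on_skel[i]) {
      f <- fil[[sample.int(length(fil), 1L)]]
      # project the start onto the filament, then move along it
      d <- f$dir
      t0 <- (start_row[i] - f$p0[1L]) * d[1L] + (start_col[i] - f$p0[2L]) * d[2L]
      p <- f$p0 + t0 * d
      sgn <- sample(c(-1, 1), 1L)
      for (k in seq_len(nf)) {
        pos[k, ] <- p + (k - 1L) * sgn * step_px[i] * d
      }
    } else if (directed[i]) {
      ang <- stats::runif(1L, 0, 2 * pi)
      p <- c(start_row[i], start_col[i])
      pos[1L, ] <- p
      for (k in 2:nf) {
        ang <- ang + stats::rnorm(1L, 0, params$curvature_sd_rad)
        p <- p + step_px[i] * c(sin(ang), cos(ang))
        pos[k, ] <- p
      }
    } else {
      steps <- matrix(stats::rnorm(2L * (nf - 1L), 0, diff_px), nf - 1L, 2L)
      pos <- rbind(c(start_row[i], start_col[i]),
                   c(start_row[i], start_col[i]) +
                     apply(steps, 2L, cumsum))
      if (nf == 2L) pos <- matrix(pos, 2L, 2L)
    }
    obs <- pos + matrix(stats::rnorm(2L * nf, 0, noise_px), nf, 2L)
    rows[[i]] <- data.frame(track_id = i, frame = seq_len(nf),
                            row_px = obs[, 1L], col_px = obs[, 2L],
                            true_row_px = pos[, 1L], true_col_px = pos[, 2L])
  }
  tracks <- do.call(rbind, rows)
  list(
    tracks = tracks,
    skeleton = skeleton,
    ground_truth = data.frame(
      track_id = seq_len(n),
      true_speed_um_s = speeds,
      directed = directed,
      on_skeleton = on_skel
    ),
    params = params
  )
}

# Normal truncated at zero via rejection (negligible mass below 0 for the
# presets; falls back to abs() after bounded retries).
truncnorm0 <- function(n, mean, sd) {
  if (n == 0L) return(numeric())
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:50) {
    neg <- x < 0
    if (!any(neg)) break
    x[neg] <- stats::rnorm(sum(neg), mean, sd)
  }
  abs(x)
}

#' Render a track set to time-lapse frames
#'
#' Produces one raster per frame with a Gaussian spot at each track's
#' observed position, for exercising the detection and linking stages.
#'
#' @param track_set output of [generate_track_set()].
#' @param spot_sigma_px Gaussian spot radius, px.
#' @param amplitude spot peak-proportional amplitude (a.u.).
#' @param background constant background level.
#' @param noise_sd additive Gaussian noise s.d. (applied with the
#'   generator's RNG discipline via `seed`).
#' @param seed seed for the noise draw.
#' @return list of numeric matrices, one per frame.
#' @export
render_track_frames <- function(track_set, spot_sigma_px = 1.5,
                                amplitude = 100, background = 0,
                                noise_sd = 0, seed = 1L) {
  fp <- track_set$params$field_px
  nf <- max(track_set$tracks$frame)
  local_rng(seed, {
    lapply(seq_len(nf), function(f) {
      sub <- track_set$tracks[track_set$tracks$frame == f, ]
      img <- matrix(background, fp, fp)
      img <- stamp_gaussians(img, sub$row_px, sub$col_px,
                             amplitude, spot_sigma_px)
      if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
      img
    })
  })
}
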