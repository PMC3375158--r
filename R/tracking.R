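#' Detect fluorescent puncta in a single frame
#'
#' Laplacian-of-Gaussian blob detection at a single scale: the frame is
#' convolved with a scale-normalized LoG kernel, local maxima of the
#' response above `threshold` are kept, and each peak position is refined
#' to subpixel precision by an intensity-weighted centroid over a small
#' window of the background-subtracted frame.
#'
#' @param frame 2-D numeric matrix.
#' @param sigma_px blob scale in pixels (> 0).
#' @param threshold minimum LoG response at a peak.
#' @return data frame of detections: `row_px`, `col_px` (subpixel),
#'   `intensity` (LoG response at the peak). May be empty.
#' @export
detect_puncta <- function(frame, sigma_px = 1.5, threshold = 1) {
  stopifnot(sigma_px > 0)
  resp <- log_response(frame, sigma_px)
  nr <- nrow(resp); nc <- ncol(resp)
  pk <- matrix(TRUE, nr, nc)
  Rp <- matrix(-Inf, nr + 2L, nc + 2L)
  Rp[2:(nr + 1L), 2:(nc + 1L)] <- resp
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    pk <- pk & (resp >= Rp[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc])
  }
  pk <- pk & (resp > threshold)
  idx <- which(pk, arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(row_px = numeric(), col_px = numeric(),
                      intensity = numeric()))
  }
  w <- max(2L, ceiling(2 * sigma_px))
  base <- stats::median(frame)
  refined <- t(apply(idx, 1L, function(p) {
    r0 <- max(1L, p[1L] - w); r1 <- min(nr, p[1L] + w)
    c0 <- max(1L, p[2L] - w); c1 <- min(nc, p[2L] + w)
    win <- frame[r0:r1, c0:c1] - base
    win[win < 0] <- 0
    s <- sum(win)
    if (s == 0) return(as.numeric(p))
    rr <- r0:r1; cc <- c0:c1
    c(sum(rowSums(win) * rr) / s, sum(colSums(win) * cc) / s)
  }))
  data.frame(row_px = refined[, 1L], col_px = refined[, 2L],
             intensity = resp[idx])
}

# negated, scale-normalized LoG filter response (positive on bright blobs)
log_response <- function(frame, sigma) {
  w <- ceiling(4 * sigma)
  x <- -w:w
  g2 <- outer(x^2, x^2, `+`)
  k <- (g2 - 2 * sigma^2) / sigma^4 * exp(-g2 / (2 * sigma^2))
  k <- -(k - mean(k)) * sigma^2
  as.matrix(EBImage::imageData(EBImage::filter2(EBImage::Image(frame), k)))
}

#' Link per-frame detections into tracks
#'
#' Greedy mutual-nearest-neighbor linking between consecutive frames:
#' a detection in frame f is linked to one in frame f+1 only when each is
#' the other's nearest neighbor and their distance is at most
#' `max_disp_px`. Unlinked detections start new tracks; a track ends at the
#' first frame without a link (no gap closing). Linking is independent of
#' the order of detections within a frame.
#'
#' @param detections data frame with columns `frame`, `row_px`, `col_px`
#'   (e.g. rbind-ed [detect_puncta()] outputs with a `frame` column added).
#' @param max_disp_px maximum link displacement, pixels (> 0).
#' @param pixel_size_nm,frame_interval_s calibration attached to the
#'   returned tracks.
#' @return data frame with columns `track_id`, `frame`, `row_px`, `col_px`;
#'   calibration stored in attributes `pixel_size_nm` and
#'   `frame_interval_s`. Only tracks with >= 2 detections are returned.
#' @export
link_tracks <- function(detections, max_disp_px,
                        pixel_size_nm = 100, frame_interval_s = 1) {
  stopifnot(max_disp_px > 0)
  need <- c("frame", "row_px", "col_px")
  if (!all(need %in% names(detections))) {
    stop("detections need columns: ", paste(need, collapse = ", "))
  }
  det <- detections[order(detections$frame, detections$row_px,
                          detections$col_px), ]
  frames <- sort(unique(det$frame))
  det$track_id <- NA_integer_
  next_id <- 1L
  by_frame <- split(seq_len(nrow(det)), det$frame)

  # start every first-frame detection as a track
  prev <- by_frame[[as.character(frames[1L])]]
  det$track_id[prev] <- seq_len(length(prev))
  next_id <- length(prev) + 1L

  if (length(frames) > 1L) {
    for (fi in seq_len(length(frames) - 1L)) {
      f <- frames[fi]; g <- frames[fi + 1L]
      cur <- by_frame[[as.character(g)]]
      linked_from <- rep(FALSE, length(prev))
      if (g == f + 1L && length(prev) && length(cur)) {
        D <- sqrt(outer(det$row_px[prev], det$row_px[cur], `-`)^2 +
                    outer(det$col_px[prev], det$col_px[cur], `-`)^2)
        nn_fwd <- apply(D, 1L, which.min)
        nn_bwd <- apply(D, 2L, which.min)
        for (a in seq_along(prev)) {
          b <- nn_fwd[a]
          if (nn_bwd[b] == a && D[a, b] <= max_disp_px) {
            det$track_id[cur[b]] <- det$track_id[prev[a]]
            linked_from[a] <- TRUE
          }
        }
      }
      if (length(cur)) {
        new <- which(is.na(det$track_id[cur]))
        if (length(new)) {
          det$track_id[cur[new]] <- next_id + seq_along(new) - 1L
          next_id <- next_id + length(new)
        }
      }
      prev <- cur
    }
  }
  keep <- det$track_id %in%
    as.integer(names(which(table(det$track_id) >= 2L)))
  out <- det[keep, c("track_id", "frame", "row_px", "col_px")]
  out$track_id <- match(out$track_id, sort(unique(out$track_id)))
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  attr(out, "pixel_size_nm") <- pixel_size_nm
  attr(out, "frame_interval_s") <- frame_interval_s
  out
}

#' Summarize one track's geometry and kinetics
#'
#' Path length is the sum of step lengths; the mean velocity is path length
#' over duration (the conventional average velocity of motile-organelle
#' measurements; a net-displacement variant is available via
#' `velocity = "net"`). Straightness is net displacement over path length
#' (0 for a stationary track). A track is classified as directed motion
#' when its straightness is at least `straightness_threshold` over at least
#' four detections.
#'
#' @param track data frame with `frame`, `row_px`, `col_px` rows of one
#'   track, in frame order.
#' @param pixel_size_nm,frame_interval_s calibration (defaults taken from
#'   attributes of `track` when present).
#' @param straightness_threshold directed-motion threshold (default 0.8).
#' @param velocity `"path"` (default) or `"net"`.
#' @return one-row data frame: `n_frames`, `path_length_um`,
#'   `net_displacement_um`, `straightness`, `duration_s`,
#'   `mean_velocity_um_s`, `directed`.
#' @export
summarize_track <- function(track, pixel_size_nm = NULL,
                            frame_interval_s = NULL,
                            straightness_threshold = 0.8,
                            velocity = c("path", "net")) {
  velocity <- match.arg(velocity)
  if (is.null(pixel_size_nm))
    pixel_size_nm <- attr(track, "pixel_size_nm") %||% 100
  if (is.null(frame_interval_s))
    frame_interval_s <- attr(track, "frame_interval_s") %||% 1
  n <- nrow(track)
  stopifnot(n >= 2L)
  if (any(diff(track$frame) != 1L)) stop("track frames must be consecutive")
  dr <- diff(track$row_px); dc <- diff(track$col_px)
  steps <- sqrt(dr^2 + dc^2)
  path_um <- sum(steps) * pixel_size_nm / 1000
  net_um <- sqrt((track$row_px[n] - track$row_px[1L])^2 +
                   (track$col_px[n] - track$col_px[1L])^2) *
    pixel_size_nm / 1000
  straight <- if (path_um > 0) net_um / path_um else 0
  duration <- (n - 1L) * frame_interval_s
  v <- (if (velocity == "path") path_um else net_um) / duration
  data.frame(
    n_frames = n,
    path_length_um = path_um,
    net_displacement_um = net_um,
    straightness = straight,
    duration_s = duration,
    mean_velocity_um_s = v,
    directed = straight >= straightness_threshold & n >= 4L
  )
}

#' Summaries for every track in a linked set
#'
#' @param tracks output of [link_tracks()] (or any data frame with
#'   `track_id`, `frame`, `row_px`, `col_px`).
#' @param skeleton optional binary filament raster; when given, a
#'   `mt_coloc_fraction` column is added via [mt_colocalization()].
#' @param radius_px colocalization radius in pixels (default 2: 200 nm at
#'   100 nm/px, the lower bound of the stated optical resolution).
#' @inheritParams summarize_track
#' @return data frame with one row per track (`track_id` plus the
#'   [summarize_track()] columns and optionally `mt_coloc_fraction`).
#' @export
summarize_tracks <- function(tracks, skeleton = NULL, radius_px = 2,
                             pixel_size_nm = NULL, frame_interval_s = NULL,
                             straightness_threshold = 0.8,
                             velocity = c("path", "net")) {
  velocity <- match.arg(velocity)
  if (is.null(pixel_size_nm))
    pixel_size_nm <- attr(tracks, "pixel_size_nm") %||% 100
  if (is.null(frame_interval_s))
    frame_interval_s <- attr(tracks, "frame_interval_s") %||% 1
  dt <- if (!is.null(skeleton)) skeleton_distance_map(skeleton) else NULL
  out <- do.call(rbind, lapply(split(tracks, tracks$track_id), function(tr) {
    s <- summarize_track(tr, pixel_size_nm, frame_interval_s,
                         straightness_threshold, velocity)
    s <- cbind(data.frame(track_id = tr$track_id[1L]), s)
    if (!is.null(dt)) {
      s$mt_coloc_fraction <- coloc_fraction_from_map(tr, dt, radius_px)
    }
    s
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of a track's detections near a filament skeleton
#'
#' Computes, via a distance transform of the skeleton raster, the fraction
#' of the track's detections whose distance to the nearest skeleton pixel
#' is at most `radius_px`. An empty skeleton gives fraction 0.
#'
#' @param track data frame with `row_px`, `col_px`.
#' @param skeleton binary matrix (nonzero = filament), same shape as the
#'   frames the track was detected in.
#' @param radius_px colocalization radius, pixels (>= 0).
#' @return scalar fraction in `[0, 1]`.
#' @export
mt_colocalization <- function(track, skeleton, radius_px = 2) {
  stopifnot(radius_px >= 0)
  if (sum(skeleton != 0) == 0L) return(0)
  coloc_fraction_from_map(track, skeleton_distance_map(skeleton), radius_px)
}

skeleton_distance_map <- function(skeleton) {
  if (sum(skeleton != 0) == 0L) {
    return(matrix(Inf, nrow(skeleton), ncol(skeleton)))
  }
  inv <- EBImage::Image((skeleton == 0) * 1)
  as.matrix(EBImage::imageData(EBImage::distmap(inv)))
}

coloc_fraction_from_map <- function(track, dmap, radius_px) {
  r <- pmin(pmax(round(track$row_px), 1L), nrow(dmap))
  c <- pmin(pmax(round(track$col_px), 1L), ncol(dmap))
  mean(dmap[cbind(r, c)] <= radius_px)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
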