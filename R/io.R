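#' Write a multichannel scene as multi-page TIFF with JSON sidecar
#'
#' One TIFF page per channel (32-bit float, intensities rescaled to the
#' recorded `intensity_range` so the round trip is lossless to float
#' precision), plus a `<path>.json` sidecar carrying channel names,
#' calibration and annotations.
#'
#' @param scene a `multichannel_scene`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "multichannel_scene"))
  rng <- range(unlist(lapply(scene$channels, range)))
  span <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(scene$channels, function(ch) (ch - rng[1L]) / span)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(
    channel_names = names(scene$channels),
    pixel_size_nm = scene$pixel_size_nm,
    intensity_range = rng,
    annotations = scene$annotations
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a multichannel scene from multi-page TIFF
#'
#' Channel names, calibration and annotations come from the JSON sidecar
#' when present; otherwise pages are named positionally WGA, Hoechst, SgII
#' and the default calibration is used with a warning.
#'
#' @param path TIFF path (sidecar expected at `<path>.json`).
#' @param default_pixel_size_nm calibration used when no sidecar exists.
#' @return a `multichannel_scene`.
#' @export
read_scene <- function(path, default_pixel_size_nm = 100) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!length(pages)) stop("no pages in ", path)
  dims <- lapply(pages, dim)
  if (!all(vapply(dims, identical, logical(1L), dims[[1L]]))) {
    stop("pages of ", path, " differ in shape")
  }
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    nm <- side$channel_names
    if (length(nm) != length(pages)) {
      stop(sprintf("sidecar declares %d channel(s) but TIFF has %d page(s)",
                   length(nm), length(pages)))
    }
    rng <- side$intensity_range
    pages <- lapply(pages, function(p) p * diff(rng) + rng[1L])
    ann <- side$annotations
    if (!is.null(ann) && !is.data.frame(ann)) ann <- as.data.frame(ann)
    if (!is.null(ann) && nrow(ann) == 0L) ann <- NULL
    multichannel_scene(stats::setNames(pages, nm),
                       pixel_size_nm = side$pixel_size_nm,
                       annotations = ann)
  } else {
    warning("no sidecar for ", path,
            "; using positional channel names and default calibration ",
            default_pixel_size_nm, " nm/px")
    nm <- c("WGA", "Hoechst", "SgII", paste0("ch", seq_along(pages)))[
      seq_along(pages)]
    multichannel_scene(stats::setNames(pages, nm),
                       pixel_size_nm = default_pixel_size_nm)
  }
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read granule scenes as boundary + granule CSV pairs
#'
#' Boundaries: columns `cell_id`, `stage_class`, `vertex_index`, `x_nm`,
#' `y_nm`. Granules: `cell_id`, `x_nm`, `y_nm` (plus `in_shell_true` when
#' ground truth is present).
#'
#' @param scenes list of `granule_scene` objects.
#' @param boundary_path,granule_path CSV output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_granule_scenes <- function(scenes, boundary_path, granule_path) {
  bnd <- do.call(rbind, lapply(scenes, function(s) {
    data.frame(cell_id = s$cell_id, stage_class = s$stage_class,
               vertex_index = seq_len(nrow(s$boundary)),
               x_nm = s$boundary[, 1L], y_nm = s$boundary[, 2L])
  }))
  grn <- do.call(rbind, lapply(scenes, function(s) {
    d <- data.frame(cell_id = s$cell_id,
                    x_nm = s$granules[, 1L], y_nm = s$granules[, 2L])
    if (!is.null(s$ground_truth)) d$in_shell_true <- s$ground_truth$in_shell_true
    d
  }))
  utils::write.csv(bnd, boundary_path, row.names = FALSE)
  utils::write.csv(grn, granule_path, row.names = FALSE)
  invisible(list(boundary_path = boundary_path, granule_path = granule_path))
}

#' @rdname write_granule_scenes
#' @param stage_class fallback class when the boundary file lacks the
#'   column.
#' @return `read_granule_scenes` returns a list of `granule_scene` objects.
#' @export
read_granule_scenes <- function(boundary_path, granule_path,
                                stage_class = NA_character_) {
  bnd <- utils::read.csv(boundary_path)
  grn <- utils::read.csv(granule_path)
  ids <- sort(unique(bnd$cell_id))
  lapply(ids, function(id) {
    b <- bnd[bnd$cell_id == id, ]
    b <- b[order(b$vertex_index), ]
    g <- grn[grn$cell_id == id, ]
    structure(
      list(cell_id = id,
           stage_class = if ("stage_class" %in% names(b))
             b$stage_class[1L] else stage_class,
           boundary = cbind(x = b$x_nm, y = b$y_nm),
           granules = cbind(x_nm = g$x_nm, y_nm = g$y_nm),
           ground_truth = if ("in_shell_true" %in% names(g))
             data.frame(cell_id = id, granule = seq_len(nrow(g)),
                        x_nm = g$x_nm, y_nm = g$y_nm,
                        in_shell_true = g$in_shell_true)),
      class = "granule_scene")
  })
}

#' Write / read track tables as CSV
#'
#' Columns: `track_id`, `frame`, `row_px`, `col_px`; calibration is stored
#' in a YAML params file alongside.
#'
#' @param tracks linked track data frame (see [link_tracks()]).
#' @param path CSV output path (a `<path>.yaml` params file is written too).
#' @return `path` invisibly (`read_tracks` returns the data frame with
#'   calibration attributes restored).
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks[, c("track_id", "frame", "row_px", "col_px")],
                   path, row.names = FALSE)
  yaml::write_yaml(
    list(pixel_size_nm = attr(tracks, "pixel_size_nm") %||% 100,
         frame_interval_s = attr(tracks, "frame_interval_s") %||% 1),
    paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  out <- utils::read.csv(path)
  yp <- paste0(path, ".yaml")
  if (file.exists(yp)) {
    y <- yaml::read_yaml(yp)
    attr(out, "pixel_size_nm") <- y$pixel_size_nm
    attr(out, "frame_interval_s") <- y$frame_interval_s
  }
  out
}
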