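#' Multichannel fluorescence scene container
#'
#' Holds registered 2-D channel rasters of equal shape, the physical
#' calibration, and optional per-cell annotations (stage class and a seed
#' point per cell, as supplied by the experimenter). Rasters are numeric
#' matrices indexed `[row, col]` with origin at the top-left, following R's
#' 1-based convention.
#'
#' @param channels named list of numeric matrices of identical dimensions.
#' @param pixel_size_nm physical pixel size, nm per pixel.
#' @param annotations optional data frame with columns `cell_id`,
#'   `stage_class`, `seed_row`, `seed_col` and optionally `condition`.
#' @return object of class `multichannel_scene`.
#' @export
multichannel_scene <- function(channels, pixel_size_nm = 100,
                               annotations = NULL) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(names(channels) == "")) {
    stop("channels must be a non-empty named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1L), dims[[1L]]))) {
    stop("all channels must share one shape")
  }
  stopifnot(pixel_size_nm > 0)
  if (!is.null(annotations)) {
    need <- c("cell_id", "stage_class", "seed_row", "seed_col")
    if (!all(need %in% names(annotations))) {
      stop("annotations need columns: ", paste(need, collapse = ", "))
    }
  }
  structure(
    list(channels = channels, pixel_size_nm = pixel_size_nm,
         annotations = annotations),
    class = "multichannel_scene"
  )
}

#' @export
print.multichannel_scene <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("multichannel_scene: %d x %d px, %g nm/px, channels: %s\n",
              d[1L], d[2L], x$pixel_size_nm,
              paste(names(x$channels), collapse = ", ")))
  if (!is.null(x$annotations)) {
    cat(sprintf("  %d annotated cells\n", nrow(x$annotations)))
  }
  invisible(x)
}

get_channel <- function(scene, name) {
  if (!name %in% names(scene$channels)) {
    stop("channel '", name, "' not present; have: ",
         paste(names(scene$channels), collapse = ", "))
  }
  scene$channels[[name]]
}
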