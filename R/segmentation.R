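#' Segment cells from the membrane (WGA) channel
#'
#' First stage of the surface-quantification protocol: the uniform membrane
#' stain is ridge-enhanced with a morphological top-hat, thresholded to a
#' ridge mask, and cell bodies are recovered by marker-controlled region
#' growing (EBImage's `propagate`, a watershed-style Voronoi flood on the
#' smoothed membrane image) inside the filled ridge foreground. Markers are
#' the supplied per-cell seed points when given (semi-automatic mode,
#' mirroring user-selected cells) or the connected interior basins enclosed
#' by the ridge otherwise. Regions smaller than `min_area` are merged into
#' background.
#'
#' When no ridge signal exceeds the threshold an empty segmentation is
#' returned with a warning rather than an error, matching the protocol's
#' tolerance of undetected borders; undetected or dropped structures are
#' tallied in the result's `warnings` field.
#'
#' @param scene a `multichannel_scene`.
#' @param membrane_channel channel name to segment on (default `"WGA"`).
#' @param seeds optional matrix/data frame of per-cell seed points
#'   (columns row, col), one per expected cell; label `k` corresponds to
#'   seed `k`.
#' @param min_area minimum region area in pixels (default 500).
#' @param smooth_sigma Gaussian smoothing sd (px) for the flood surface.
#' @param tophat_size diameter (px) of the top-hat disc; slightly larger
#'   than the expected ridge width.
#' @param ridge_threshold absolute threshold on the top-hat image; `NULL`
#'   (default) uses Otsu's threshold.
#' @return a `cell_label_map`: list with integer matrix `labels`
#'   (0 background, 1..K cells, 4-connected regions relabelled
#'   contiguously), `provenance` (parameters used) and `warnings`
#'   (character vector).
#' @export
segment_cells <- function(scene, membrane_channel = "WGA", seeds = NULL,
                          min_area = 500, smooth_sigma = 1.5,
                          tophat_size = 9, ridge_threshold = NULL) {
  m <- get_channel(scene, membrane_channel)
  warnings <- character()

  rng <- range(m)
  mn <- if (diff(rng) > 0) (m - rng[1L]) / diff(rng) else m * 0
  img <- EBImage::Image(mn)

  brush <- EBImage::makeBrush(odd_size(tophat_size), shape = "disc")
  th <- EBImage::whiteTopHat(img, brush)
  thr <- if (is.null(ridge_threshold)) EBImage::otsu(th, range = c(0, 1))
         else ridge_threshold / diff(rng)
  ridge <- th > thr

  if (sum(ridge) == 0) {
    warning("no ridge signal above threshold; returning empty segmentation")
    return(cell_label_map(matrix(0L, nrow(m), ncol(m)),
                          provenance = list(membrane_channel = membrane_channel,
                                            min_area = min_area),
                          warnings = "no ridge signal above threshold"))
  }

  fg <- EBImage::fillHull(ridge)

  if (!is.null(seeds)) {
    seeds <- as.matrix(seeds)
    markers <- matrix(0L, nrow(m), ncol(m))
    for (k in seq_len(nrow(seeds))) {
      r <- round(seeds[k, 1L]); c <- round(seeds[k, 2L])
      if (r < 1L || c < 1L || r > nrow(m) || c > ncol(m)) {
        stop("seed ", k, " outside the image")
      }
      if (markers[r, c] != 0L) stop("seeds ", markers[r, c], " and ", k,
                                    " fall on the same pixel")
      markers[r, c] <- k
    }
  } else {
    interior <- fg & !ridge
    interior <- EBImage::erode(EBImage::Image(interior * 1),
                               EBImage::makeBrush(5, "disc")) > 0
    markers <- EBImage::bwlabel(EBImage::Image(interior * 1))
    markers <- matrix(as.integer(EBImage::imageData(markers)),
                      nrow(m), ncol(m))
  }

  smooth <- EBImage::gblur(img, sigma = smooth_sigma)
  lab <- EBImage::propagate(smooth, EBImage::Image(markers),
                            mask = fg > 0)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(m), ncol(m))

  # drop regions below the minimum area
  sizes <- tabulate(lab[lab > 0L])
  small <- which(sizes > 0L & sizes < min_area)
  if (length(small)) {
    lab[lab %in% small] <- 0L
    warnings <- c(warnings,
                  sprintf("%d region(s) below min_area %d merged into background",
                          length(small), as.integer(min_area)))
  }
  if (!is.null(seeds)) {
    missing <- setdiff(seq_len(nrow(seeds)), unique(lab[lab > 0L]))
    if (length(missing)) {
      warnings <- c(warnings,
                    sprintf("seed(s) %s yielded no region (undetected border?)",
                            paste(missing, collapse = ",")))
    }
  }

  lab <- relabel_contiguous(lab)
  cell_label_map(lab,
                 provenance = list(membrane_channel = membrane_channel,
                                   seeded = !is.null(seeds),
                                   min_area = min_area,
                                   smooth_sigma = smooth_sigma,
                                   tophat_size = tophat_size,
                                   ridge_threshold = as.numeric(thr) * diff(rng) + 0),
                 warnings = warnings)
}

cell_label_map <- function(labels, provenance = list(), warnings = character()) {
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, provenance = provenance,
                 warnings = warnings),
            class = "cell_label_map")
}

#' @export
print.cell_label_map <- function(x, ...) {
  k <- max(x$labels)
  cat(sprintf("cell_label_map: %d x %d px, %d cell(s)\n",
              nrow(x$labels), ncol(x$labels), k))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

# keep old -> new label ordering stable (ascending old label)
relabel_contiguous <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) return(lab)
  lut <- integer(max(ids))
  lut[ids] <- seq_along(ids)
  pos <- lab > 0L
  lab[pos] <- lut[lab[pos]]
  lab
}

odd_size <- function(x) {
  x <- as.integer(round(x))
  if (x %% 2L == 0L) x + 1L else x
}

#' Classify each cell's boundary pixels as cluster-outer or cluster-internal
#'
#' A cell's boundary pixel is a pixel of that label with at least one
#' 8-neighbor of a different value (inner-boundary convention, so boundary
#' pixels stay inside the mask area they contribute to). A boundary pixel
#' adjacent to a different nonzero label is cluster-internal; one adjacent
#' only to background is cluster-outer. Internal borders are excluded from
#' surface quantification because their signal is confounded by the
#' neighboring cell.
#'
#' @param labelmap a `cell_label_map`.
#' @return a `border_mask`: per-cell lists `outer` and `internal` of linear
#'   pixel indices (disjoint; their union is the full boundary pixel set),
#'   plus the label matrix and its dimensions.
#' @export
classify_borders <- function(labelmap) {
  stopifnot(inherits(labelmap, "cell_label_map"))
  L <- labelmap$labels
  nr <- nrow(L); nc <- ncol(L)
  ids <- sort(unique(L[L > 0L]))
  if (!length(ids)) {
    return(structure(list(outer = list(), internal = list(),
                          labels = L, dim = c(nr, nc)),
                     class = "border_mask"))
  }
  Lp <- matrix(0L, nr + 2L, nc + 2L)
  Lp[2:(nr + 1L), 2:(nc + 1L)] <- L
  any_diff <- matrix(FALSE, nr, nc)
  any_other <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    N <- Lp[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    d <- N != L
    any_diff <- any_diff | d
    any_other <- any_other | (d & N > 0L)
  }
  boundary <- L > 0L & any_diff
  internal <- boundary & any_other
  outer <- boundary & !any_other

  outer_idx <- split(which(outer), L[which(outer)])
  internal_idx <- split(which(internal), L[which(internal)])
  structure(
    list(
      outer = lapply(stats::setNames(as.character(ids), ids), function(k)
        if (k %in% names(outer_idx)) outer_idx[[k]] else integer()),
      internal = lapply(stats::setNames(as.character(ids), ids), function(k)
        if (k %in% names(internal_idx)) internal_idx[[k]] else integer()),
      labels = L,
      dim = c(nr, nc)
    ),
    class = "border_mask"
  )
}
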