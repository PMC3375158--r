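# Independent brute-force oracles used across the suite. These deliberately
# use the slowest, most literal formulation of each definition so that they
# stay independent of the implementation paths they check.

# All pixels within Chebyshev distance w of any of the given pixels,
# excluding pixels carrying another cell's label. Literal O(n_px * n_border)
# scan.
brute_chebyshev_ribbon <- function(border_lin, w, labels, cell) {
  nr <- nrow(labels); nc <- ncol(labels)
  br <- (border_lin - 1L) %% nr + 1L
  bc <- (border_lin - 1L) %/% nr + 1L
  keep <- logical(nr * nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (any(pmax(abs(br - r), abs(bc - c)) <= w)) {
      lv <- labels[r, c]
      if (lv == 0L || lv == cell) keep[(c - 1L) * nr + r] <- TRUE
    }
  }
  which(keep)
}

# Literal per-pixel boundary classification: for every pixel of a label,
# enumerate its 8 neighbors (out-of-image counts as background).
brute_border_classification <- function(L) {
  nr <- nrow(L); nc <- ncol(L)
  ids <- sort(unique(L[L > 0L]))
  out <- list()
  for (k in ids) {
    outer <- integer(); internal <- integer()
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (L[r, c] != k) next
      nb <- integer()
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        nb <- c(nb, if (rr < 1 || cc < 1 || rr > nr || cc > nc) 0L
                else L[rr, cc])
      }
      if (all(nb == k)) next
      if (any(nb != k & nb > 0L)) internal <- c(internal, (c - 1L) * nr + r)
      else outer <- c(outer, (c - 1L) * nr + r)
    }
    out[[as.character(k)]] <- list(outer = outer, internal = internal)
  }
  out
}

# Dense-rasterization distance oracle for shell classification: rasterize
# the polygon outline on a grid of the given pitch, distance-transform it,
# and look distances up at granule positions.
brute_shell_classification <- function(scene, shell_nm, grid_nm = 10) {
  poly <- scene$boundary
  pts <- scene$granules
  pad <- shell_nm + 20 * grid_nm
  x0 <- min(poly[, 1L]) - pad; x1 <- max(poly[, 1L]) + pad
  y0 <- min(poly[, 2L]) - pad; y1 <- max(poly[, 2L]) + pad
  ncg <- ceiling((x1 - x0) / grid_nm) + 1L
  nrg <- ceiling((y1 - y0) / grid_nm) + 1L
  outline <- matrix(1, nrg, ncg)
  # densely sample every edge
  m <- nrow(poly)
  for (e in seq_len(m)) {
    a <- poly[e, ]; b <- poly[if (e == m) 1L else e + 1L, ]
    len <- sqrt(sum((b - a)^2))
    tt <- seq(0, 1, length.out = max(2L, ceiling(len / (grid_nm / 2))))
    px <- a[1L] + tt * (b[1L] - a[1L])
    py <- a[2L] + tt * (b[2L] - a[2L])
    gr <- round((py - y0) / grid_nm) + 1L
    gc <- round((px - x0) / grid_nm) + 1L
    outline[cbind(gr, gc)] <- 0
  }
  dmap <- as.matrix(EBImage::imageData(EBImage::distmap(EBImage::Image(outline))))
  gr <- round((pts[, 2L] - y0) / grid_nm) + 1L
  gc <- round((pts[, 1L] - x0) / grid_nm) + 1L
  dmap[cbind(gr, gc)] * grid_nm <= shell_nm
}

# hand-built label map of touching rectangles on a blank raster
rect_labels <- function(nr, nc, rects) {
  L <- matrix(0L, nr, nc)
  for (i in seq_along(rects)) {
    r <- rects[[i]]
    L[r$rows, r$cols] <- i
  }
  L
}

make_label_map <- function(L) sgquant:::cell_label_map(L)

# minimal scene wrapper around a single SgII matrix
sgii_scene <- function(sgii, annotations = NULL) {
  multichannel_scene(list(SgII = sgii), pixel_size_nm = 100,
                     annotations = annotations)
}
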