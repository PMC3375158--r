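#' Parameters for synthetic three-channel fluorescence scenes
#'
#' Describes a widefield-like scene of adherent cells with three registered
#' channels: a membrane stain (WGA) forming a bright closed ring around each
#' cell, a DNA stain (Hoechst) showing an interphase nucleus blob or a
#' metaphase plate bar, and a surface immunostain (SgII) that is punctate
#' and restricted to a band straddling the membrane of responder cells.
#' Ground truth (stage class, responder flag, true surface signal mean,
#' outline, true label map) is returned with every scene so the downstream
#' pipeline can be validated by parameter recovery.
#'
#' @param n_cells number of cells.
#' @param cluster_layout `"scatter"` (separated cells on a jittered grid) or
#'   `"paired"` (cells placed in touching pairs that share ring segments).
#' @param cell_radius_px mean and s.d. of the cell radius, in pixels.
#' @param membrane_ring_intensity peak ring intensity (a.u.).
#' @param membrane_ring_width_px full width of the membrane ring in pixels.
#' @param responder_probability probability a cell responds to stimulation;
#'   a scalar or a named vector with entries `interphase` and `metaphase`.
#' @param responder_surface_mean mean added SgII intensity (a.u.) over the
#'   surface band of an interphase responder.
#' @param nonresponder_surface_mean mean added SgII intensity on
#'   non-responders (approximately background, default 0).
#' @param intensity_scale_by_class named multiplicative factors on
#'   `responder_surface_mean` per stage class (e.g. metaphase 0.61).
#' @param background_mean uniform SgII background (a.u.).
#' @param noise_sd s.d. of additive Gaussian read noise on every channel.
#' @param pixel_size_nm physical calibration, nm per pixel (default 100,
#'   near-Nyquist for 200-250 nm optical resolution).
#' @param stage_classes optional explicit per-cell class vector
#'   (`"interphase"`/`"metaphase"`); overrides `metaphase_fraction`.
#' @param metaphase_fraction fraction of cells annotated as metaphase when
#'   `stage_classes` is not given.
#' @param surface_band_halfwidth_px half-width of the true surface-signal
#'   band around the outline, in pixels (default 3, matching the analysis
#'   mask width).
#' @param puncta_sigma_px Gaussian radius of individual SgII puncta.
#' @param puncta_density expected puncta per band pixel.
#' @param condition experiment arm label (`"stimulated"` or `"control"`),
#'   carried into annotations.
#' @param seed integer seed; identical parameters and seed give a
#'   bit-identical scene.
#' @return an object of class `fluor_scene_params`.
#' @export
fluor_scene_params <- function(n_cells = 25L,
                               cluster_layout = c("scatter", "paired"),
                               cell_radius_px = c(mean = 30, sd = 3),
                               membrane_ring_intensity = 200,
                               membrane_ring_width_px = 3,
                               responder_probability = c(interphase = 0.81,
                                                         metaphase = 0.67),
                               responder_surface_mean = 30,
                               nonresponder_surface_mean = 0,
                               intensity_scale_by_class = c(interphase = 1,
                                                            metaphase = 0.61),
                               background_mean = 10,
                               noise_sd = 0,
                               pixel_size_nm = 100,
                               stage_classes = NULL,
                               metaphase_fraction = 0,
                               surface_band_halfwidth_px = 3,
                               puncta_sigma_px = 1.5,
                               puncta_density = 0.02,
                               condition = "stimulated",
                               seed = 1L) {
  cluster_layout <- match.arg(cluster_layout)
  rp <- responder_probability
  stopifnot(
    n_cells >= 1L,
    all(rp >= 0), all(rp <= 1),
    cell_radius_px[[1L]] > 0,
    membrane_ring_intensity >= 0, membrane_ring_width_px > 0,
    responder_surface_mean >= 0, nonresponder_surface_mean >= 0,
    background_mean >= 0, noise_sd >= 0,
    pixel_size_nm > 0,
    metaphase_fraction >= 0, metaphase_fraction <= 1
  )
  if (length(rp) == 1L && is.null(names(rp))) {
    rp <- c(interphase = unname(rp), metaphase = unname(rp))
  }
  scale <- intensity_scale_by_class
  if (is.null(names(scale))) stop("intensity_scale_by_class must be named")
  structure(
    list(
      n_cells = as.integer(n_cells),
      cluster_layout = cluster_layout,
      cell_radius_px = c(mean = unname(cell_radius_px[[1L]]),
                         sd = unname(cell_radius_px[[2L]])),
      membrane_ring_intensity = membrane_ring_intensity,
      membrane_ring_width_px = membrane_ring_width_px,
      responder_probability = rp,
      responder_surface_mean = responder_surface_mean,
      nonresponder_surface_mean = nonresponder_surface_mean,
      intensity_scale_by_class = scale,
      background_mean = background_mean,
      noise_sd = noise_sd,
      pixel_size_nm = pixel_size_nm,
      stage_classes = stage_classes,
      metaphase_fraction = metaphase_fraction,
      surface_band_halfwidth_px = surface_band_halfwidth_px,
      puncta_sigma_px = puncta_sigma_px,
      puncta_density = puncta_density,
      condition = condition,
      seed = as.integer(seed)
    ),
    class = "fluor_scene_params"
  )
}

#' Generate a synthetic three-channel fluorescence scene
#'
#' Renders WGA, Hoechst and SgII channels for a population of star-shaped
#' cells and returns the scene together with exact ground truth. Cell
#' outlines are smoothed random-radius star polygons; in the `"paired"`
#' layout touching cells are assigned pixels by smallest normalized radial
#' distance, so the shared ring segment is rendered once and belongs to
#' both cells' membranes.
#'
#' @param params a [fluor_scene_params()] object (or preset).
#' @return a list with elements `scene` (a `multichannel_scene`: named
#'   channel matrices, `pixel_size_nm`, `annotations` data frame) and
#'   `truth` (per-cell data frame `cells`, list of outline `polygons` in
#'   (x = col, y = row) pixel coordinates, and the integer `label_map`).
#' @examples
#' out <- generate_fluorescence_scene(
#'   fluor_scene_params(n_cells = 4, responder_probability = 1, seed = 3))
#' dim(out$scene$channels$WGA)
#' @export
generate_fluorescence_scene <- function(params) {
  stopifnot(inherits(params, "fluor_scene_params"))
  local_rng(params$seed, render_fluor_scene(params))
}

render_fluor_scene <- function(params) {
  n <- params$n_cells
  rmean <- params$cell_radius_px[["mean"]]
  rsd <- params$cell_radius_px[["sd"]]
  ring_hw <- params$membrane_ring_width_px / 2
  band_hw <- params$surface_band_halfwidth_px

  lay <- place_cells(params)
  dims <- lay$dims
  centers <- lay$centers        # (row, col) per cell
  radii <- pmax(0.5 * rmean, stats::rnorm(n, rmean, rsd))
  radii <- pmin(radii, lay$max_radius)

  classes <- cell_stage_classes(params)
  scale <- params$intensity_scale_by_class
  p_resp <- params$responder_probability[classes]
  responder <- stats::runif(n) < p_resp
  mu <- ifelse(responder,
               params$responder_surface_mean * unname(scale[classes]),
               params$nonresponder_surface_mean)

  wga <- matrix(0, dims[1L], dims[2L])
  hoechst <- matrix(0, dims[1L], dims[2L])
  sgii <- matrix(params$background_mean, dims[1L], dims[2L])
  labmap <- matrix(0L, dims[1L], dims[2L])
  ndist <- matrix(Inf, dims[1L], dims[2L])

  polys <- vector("list", n)
  geoms <- vector("list", n)

  for (i in seq_len(n)) {
    cr <- centers[i, 1L]; cc <- centers[i, 2L]
    poly <- star_polygon(cc, cr, radii[i], n_ctrl = sample(8:12, 1L),
                         irregularity = 0.1)
    polys[[i]] <- poly
    ext <- max(attr(poly, "r")) + ring_hw + band_hw + 2
    r0 <- floor(cr - ext); r1 <- ceiling(cr + ext)
    c0 <- floor(cc - ext); c1 <- ceiling(cc + ext)
    if (r0 < 1L || c0 < 1L || r1 > dims[1L] || c1 > dims[2L]) {
      stop("cell placement exceeded the image for seed ", params$seed,
           "; enlarge the layout or reduce cell_radius_px")
    }
    rows <- r0:r1; cols <- c0:c1
    rho <- sqrt(outer((rows - cr)^2, (cols - cc)^2, `+`))
    theta <- atan2(
      matrix(rows - cr, length(rows), length(cols)),
      matrix(cols - cc, length(rows), length(cols), byrow = TRUE)
    )
    rtheta <- matrix(star_radius_at(poly, as.vector(theta)),
                     length(rows), length(cols))
    norm_d <- rho / rtheta
    geoms[[i]] <- list(rows = rows, cols = cols, rho = rho,
                       rtheta = rtheta, norm_d = norm_d)

    # pixel ownership: smallest normalized radial distance wins
    inside <- norm_d <= 1
    sub_nd <- ndist[rows, cols]
    claim <- inside & (norm_d < sub_nd)
    sub_lab <- labmap[rows, cols]
    sub_lab[claim] <- i
    sub_nd[claim] <- norm_d[claim]
    labmap[rows, cols] <- sub_lab
    ndist[rows, cols] <- sub_nd

    # membrane ring: bright band of the stated width centred on the outline
    ringm <- abs(rho - rtheta) <= ring_hw
    sub <- wga[rows, cols]
    sub[ringm] <- pmax(sub[ringm], params$membrane_ring_intensity)
    interior <- norm_d < 1 - ring_hw / radii[i]
    sub[interior] <- pmax(sub[interior], 0.15 * params$membrane_ring_intensity)
    wga[rows, cols] <- sub

    # DNA stain: nucleus blob (interphase) or metaphase plate bar
    sub <- hoechst[rows, cols]
    if (classes[i] == "metaphase") {
      phi <- stats::runif(1L, 0, pi)
      u <- (matrix(cols - cc, length(rows), length(cols), byrow = TRUE)) * cos(phi) +
        (matrix(rows - cr, length(rows), length(cols))) * sin(phi)
      v <- -(matrix(cols - cc, length(rows), length(cols), byrow = TRUE)) * sin(phi) +
        (matrix(rows - cr, length(rows), length(cols))) * cos(phi)
      plate <- abs(v) <= 0.12 * radii[i] & abs(u) <= 0.55 * radii[i]
      sub[plate] <- pmax(sub[plate], 150)
    } else {
      blob <- 150 * exp(-rho^2 / (2 * (0.45 * radii[i])^2))
      sub <- pmax(sub, blob)
    }
    hoechst[rows, cols] <- sub
  }

  # touching cells share one membrane: paint the ridge along inter-cell
  # interfaces of the ownership map at full ring intensity and width
  if (n > 1L) {
    ib <- classify_borders(cell_label_map(labmap))
    shared <- unlist(ib$internal, use.names = FALSE)
    if (length(shared)) {
      sm <- matrix(0, dims[1L], dims[2L])
      sm[shared] <- 1
      sm <- EBImage::imageData(EBImage::dilate(
        EBImage::Image(sm),
        EBImage::makeBrush(odd_size(params$membrane_ring_width_px), "disc")))
      wga[sm > 0] <- pmax(wga[sm > 0], params$membrane_ring_intensity)
    }
  }

  # surface SgII puncta, stamped after ownership so band areas are known
  for (i in seq_len(n)) {
    if (mu[i] <= 0) next
    g <- geoms[[i]]
    bandm <- abs(g$rho - g$rtheta) <= band_hw
    band_area <- sum(bandm)
    if (band_area == 0L) next
    n_punc <- max(6L, round(band_area * params$puncta_density))
    pick <- sample.int(band_area, n_punc, replace = TRUE)
    idx <- which(bandm, arr.ind = TRUE)[pick, , drop = FALSE]
    prow <- g$rows[idx[, 1L]] + stats::runif(n_punc, -0.5, 0.5)
    pcol <- g$cols[idx[, 2L]] + stats::runif(n_punc, -0.5, 0.5)
    amp <- mu[i] * band_area /
      (n_punc * 2 * pi * params$puncta_sigma_px^2)
    sgii <- stamp_gaussians(sgii, prow, pcol, amp, params$puncta_sigma_px)
  }

  if (params$noise_sd > 0) {
    wga <- wga + stats::rnorm(length(wga), 0, params$noise_sd)
    hoechst <- hoechst + stats::rnorm(length(hoechst), 0, params$noise_sd)
    sgii <- sgii + stats::rnorm(length(sgii), 0, params$noise_sd)
  }

  annotations <- data.frame(
    cell_id = seq_len(n),
    stage_class = classes,
    seed_row = round(centers[, 1L]),
    seed_col = round(centers[, 2L]),
    condition = rep(params$condition, n),
    stringsAsFactors = FALSE
  )
  scene <- multichannel_scene(
    channels = list(WGA = wga, Hoechst = hoechst, SgII = sgii),
    pixel_size_nm = params$pixel_size_nm,
    annotations = annotations
  )
  truth_cells <- data.frame(
    cell_id = seq_len(n),
    stage_class = classes,
    responder_flag = responder,
    true_surface_mean_au = mu,
    center_row = centers[, 1L],
    center_col = centers[, 2L],
    radius_px = radii,
    stringsAsFactors = FALSE
  )
  list(scene = scene,
       truth = list(cells = truth_cells, polygons = polys,
                    label_map = labmap))
}

# Grid-based layouts. "scatter" keeps every cell separated; "paired" puts
# two touching cells per site so they share a membrane segment.
place_cells <- function(params) {
  n <- params$n_cells
  rmean <- params$cell_radius_px[["mean"]]
  rsd <- params$cell_radius_px[["sd"]]
  rmax <- rmean + 3 * rsd
  pad <- params$membrane_ring_width_px / 2 +
    params$surface_band_halfwidth_px + 6
  if (params$cluster_layout == "scatter") {
    spacing <- 2 * rmax * 1.25 + 2 * pad
    ncol_g <- ceiling(sqrt(n))
    nrow_g <- ceiling(n / ncol_g)
    margin <- spacing / 2 + pad
    rows <- margin + (seq_len(nrow_g) - 1L) * spacing
    cols <- margin + (seq_len(ncol_g) - 1L) * spacing
    grid <- expand.grid(row = rows, col = cols)[seq_len(n), ]
    jitter <- matrix(stats::runif(2L * n, -3, 3), n)
    centers <- cbind(grid$row, grid$col) + jitter
    dims <- c(ceiling(max(rows) + margin), ceiling(max(cols) + margin))
    max_radius <- spacing / 2 - pad
  } else {
    site_w <- 4.4 * rmax + 2 * pad
    site_h <- 2.6 * rmax + 2 * pad
    n_sites <- ceiling(n / 2)
    ncol_g <- ceiling(sqrt(n_sites))
    nrow_g <- ceiling(n_sites / ncol_g)
    centers <- matrix(NA_real_, n, 2L)
    for (s in seq_len(n_sites)) {
      gr <- (s - 1L) %/% ncol_g
      gc <- (s - 1L) %% ncol_g
      crow <- site_h / 2 + gr * site_h + pad
      ccol <- site_w / 2 + gc * site_w + pad
      i1 <- 2L * s - 1L; i2 <- 2L * s
      off <- 0.92 * rmean
      centers[i1, ] <- c(crow, ccol - off)
      if (i2 <= n) centers[i2, ] <- c(crow, ccol + off)
    }
    dims <- c(ceiling(nrow_g * site_h + 2 * pad),
              ceiling(ncol_g * site_w + 2 * pad))
    max_radius <- 1.1 * rmean
  }
  list(centers = centers, dims = as.integer(dims), max_radius = max_radius)
}

cell_stage_classes <- function(params) {
  n <- params$n_cells
  if (!is.null(params$stage_classes)) {
    cl <- params$stage_classes
    if (length(cl) != n) stop("stage_classes must have length n_cells")
    if (!all(cl %in% c("interphase", "metaphase"))) {
      stop("stage_classes must be 'interphase' or 'metaphase'")
    }
    return(cl)
  }
  n_meta <- round(n * params$metaphase_fraction)
  c(rep("interphase", n - n_meta), rep("metaphase", n_meta))
}

# Add Gaussian spots of a common amplitude and sd at subpixel positions.
stamp_gaussians <- function(img, rows, cols, amplitude, sigma) {
  w <- ceiling(3 * sigma)
  nr <- nrow(img); nc <- ncol(img)
  for (k in seq_along(rows)) {
    r0 <- max(1L, floor(rows[k]) - w); r1 <- min(nr, ceiling(rows[k]) + w)
    c0 <- max(1L, floor(cols[k]) - w); c1 <- min(nc, ceiling(cols[k]) + w)
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    g <- amplitude * exp(-outer((rr - rows[k])^2, (cc - cols[k])^2, `+`) /
                           (2 * sigma^2))
    img[rr, cc] <- img[rr, cc] + g
  }
  img
}
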