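#' Named parameter presets anchored to the published experiments
#'
#' The preset registry bundles generator parameters that reproduce the
#' statistical structure of the study's experimental conditions:
#'
#' * `em_interphase` / `em_metaphase`: EM-scale granule scenes with a
#'   cortical (500 nm shell) placement probability of 0.70 and 0.13, the
#'   reported mean peripheral fractions for interphase and metaphase PC12
#'   cells, at roughly 75 and 125 granules per cell.
#' * `em_interphase_fixture` / `em_metaphase_fixture`: three-cell scenes with
#'   exact total granule counts of 227 and 376 (the published totals),
#'   at fixed seeds, used for the packaged text fixtures.
#' * `fluor_stimulated`: stimulated fluorescence scenes; responder
#'   probability 0.81 for interphase and 0.67 for metaphase cells, and a
#'   metaphase surface-signal intensity factor of 0.61 relative to
#'   interphase. `fluor_control`: matched unstimulated scenes (no
#'   responders), used for background estimation.
#' * `tracks_anaphase` / `tracks_cytokinesis`: directed-track speed
#'   distributions of 0.23 +/- 0.09 and 0.34 +/- 0.09 um/s.
#'
#' Presets are immutable parameter bundles; every field can be overridden by
#' passing replacements to [sg_preset()].
#'
#' @param name preset name, one of [sg_preset_names()].
#' @param ... named overrides merged over the preset's fields.
#' @return a named list of parameters (class depends on preset family:
#'   `em_scene_params`, `fluor_scene_params` or `track_set_params`).
#' @examples
#' p <- sg_preset("em_interphase", n_cells = 5, seed = 1)
#' p$cortical_probability
#' @export
sg_preset <- function(name, ...) {
  registry <- sg_preset_registry()
  if (!name %in% names(registry)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(registry), collapse = ", "))
  }
  preset <- registry[[name]]
  ctor <- preset$constructor
  args <- preset$fields
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("preset overrides must be named")
    }
    args[names(dots)] <- dots
  }
  do.call(ctor, args)
}

#' @rdname sg_preset
#' @export
sg_preset_names <- function() names(sg_preset_registry())

sg_preset_registry <- function() {
  list(
    em_interphase = list(
      constructor = em_scene_params,
      fields = list(
        n_cells = 20L, granules_per_cell = 75L, cortical_probability = 0.70,
        shell_thickness_nm = 500, cell_radius_nm = 5000, pixel_size_nm = 10,
        stage_class = "interphase", seed = 1L
      )
    ),
    em_metaphase = list(
      constructor = em_scene_params,
      fields = list(
        n_cells = 20L, granules_per_cell = 125L, cortical_probability = 0.13,
        shell_thickness_nm = 500, cell_radius_nm = 5000, pixel_size_nm = 10,
        stage_class = "metaphase", seed = 2L
      )
    ),
    em_interphase_fixture = list(
      constructor = em_scene_params,
      fields = list(
        n_cells = 3L, total_granules = 227L, cortical_probability = 0.70,
        shell_thickness_nm = 500, cell_radius_nm = 5000, pixel_size_nm = 10,
        stage_class = "interphase", seed = 227L
      )
    ),
    em_metaphase_fixture = list(
      constructor = em_scene_params,
      fields = list(
        n_cells = 3L, total_granules = 376L, cortical_probability = 0.13,
        shell_thickness_nm = 500, cell_radius_nm = 5000, pixel_size_nm = 10,
        stage_class = "metaphase", seed = 376L
      )
    ),
    fluor_stimulated = list(
      constructor = fluor_scene_params,
      fields = list(
        n_cells = 25L,
        responder_probability = c(interphase = 0.81, metaphase = 0.67),
        intensity_scale_by_class = c(interphase = 1, metaphase = 0.61),
        responder_surface_mean = 30, nonresponder_surface_mean = 0,
        background_mean = 10, noise_sd = 0, seed = 7L
      )
    ),
    fluor_control = list(
      constructor = fluor_scene_params,
      fields = list(
        n_cells = 25L,
        responder_probability = c(interphase = 0, metaphase = 0),
        intensity_scale_by_class = c(interphase = 1, metaphase = 0.61),
        responder_surface_mean = 30, nonresponder_surface_mean = 0,
        background_mean = 10, noise_sd = 0, seed = 8L
      )
    ),
    tracks_anaphase = list(
      constructor = track_set_params,
      fields = list(
        n_tracks = 50L, speed_mean_um_s = 0.23, speed_sd_um_s = 0.09,
        frame_interval_s = 1, n_frames = 20L, localization_noise_nm = 20,
        fraction_directed = 0.7, diffusive_step_sd_nm = 50,
        on_skeleton_fraction = 0.7, pixel_size_nm = 100, seed = 11L
      )
    ),
    tracks_cytokinesis = list(
      constructor = track_set_params,
      fields = list(
        n_tracks = 50L, speed_mean_um_s = 0.34, speed_sd_um_s = 0.09,
        frame_interval_s = 1, n_frames = 20L, localization_noise_nm = 20,
        fraction_directed = 0.7, diffusive_step_sd_nm = 50,
        on_skeleton_fraction = 0.7, pixel_size_nm = 100, seed = 12L
      )
    )
  )
}
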