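#' Physical constants and detection thresholds for water-column analysis
#'
#' Returns the constants used throughout the stratification chain. Defaults
#' are the values used for Lake Zurich-type monitoring: a lake-specific
#' conductivity-to-salinity factor for waters dominated by calcium
#' carbonate, the matching haline contraction coefficient, and the
#' mixed-layer / metalimnion detection thresholds.
#'
#' @param g gravitational acceleration (m s^-2).
#' @param beta_haline haline contraction coefficient (per permille).
#' @param cond_to_salinity salinity per unit conductivity at 25 degC
#'   (permille per uS cm^-1).
#' @param mld_density_offset density exceedance over the near-surface
#'   reference that defines the mixed-layer depth (kg m^-3).
#' @param surface_reference_span depth span averaged for the near-surface
#'   reference density (m).
#' @param n2_validity_min minimum N^2 maximum for a properly established
#'   metalimnion (s^-2).
#' @param meta_thickness_max maximum metalimnion thickness for validity (m).
#'
#' @return A named list of class `physics_constants`.
#' @export
#' @examples
#' lake_constants()$beta_haline
lake_constants <- function(g = 9.81,
                           beta_haline = 0.807e-3,
                           cond_to_salinity = 0.7999e-3,
                           mld_density_offset = 0.01,
                           surface_reference_span = 2,
                           n2_validity_min = 2e-4,
                           meta_thickness_max = 20) {
  const <- list(
    g = g,
    beta_haline = beta_haline,
    cond_to_salinity = cond_to_salinity,
    mld_density_offset = mld_density_offset,
    surface_reference_span = surface_reference_span,
    n2_validity_min = n2_validity_min,
    meta_thickness_max = meta_thickness_max
  )
  bad <- names(const)[!vapply(const, function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad)) {
    stop("lake_constants: all constants must be single positive numbers; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(const, class = c("physics_constants", "list"))
}

#' Species-intrinsic irradiance thresholds
#'
#' The three PAR levels that control buoyancy of the target cyanobacterium:
#' `e_comp` (buoyancy gain / minimal heterotrophically assisted growth),
#' `e_buoy` (neutral buoyancy of more than half the population) and `e_sat`
#' (saturating light, buoyancy loss), plus the sensor floor below which the
#' underwater quantum sensor stops recording.
#'
#' @param e_comp,e_buoy,e_sat irradiance thresholds (umol photons m^-2 s^-1).
#' @param sensor_floor lowest recordable irradiance (umol photons m^-2 s^-1).
#' @return A named list of class `irradiance_thresholds`.
#' @export
irradiance_thresholds <- function(e_comp = 0.8, e_buoy = 6.5, e_sat = 25,
                                  sensor_floor = 0.05) {
  if (!(e_comp > 0 && e_buoy > 0 && e_sat > 0 && sensor_floor > 0)) {
    stop("irradiance thresholds must all be positive", call. = FALSE)
  }
  if (!(e_comp < e_buoy && e_buoy < e_sat)) {
    stop("irradiance thresholds must satisfy e_comp < e_buoy < e_sat", call. = FALSE)
  }
  structure(list(e_comp = e_comp, e_buoy = e_buoy, e_sat = e_sat,
                 sensor_floor = sensor_floor),
            class = c("irradiance_thresholds", "list"))
}

#' Full pipeline configuration
#'
#' Bundles every tunable of the analysis chain with its default. Any element
#' can be overridden; defaults equal the published monitoring values where
#' one exists and documented package choices elsewhere.
#'
#' @param constants a [lake_constants()] list.
#' @param thresholds an [irradiance_thresholds()] list.
#' @param r2_min running-fit R^2 threshold for the PAR attenuation fit range.
#' @param kd_resid_mult,kd_resid_floor prediction-band rule for extending
#'   the attenuation fit range: the next point must lie within
#'   `kd_resid_mult` residual SDs of the running fit, with the band floored
#'   at `kd_resid_floor` log units (three times a typical 2 percent sensor
#'   noise) so noise-free profiles still extend.
#' @param kd_mode `"surface-linear"` (truncated fit, stratified season) or
#'   `"full-profile"` (autumn/winter whole-profile fit).
#' @param drop_surface drop the topmost metre from the attenuation fit
#'   (wave contamination guard).
#' @param detection_limit_chla FluoroProbe detection limit (ug L^-1).
#' @param detection_limit_mass whole-lake mass floor substituted for
#'   below-detection populations so log growth stays defined (metric tons).
#' @param vernal_window_start,vernal_window_end month-day bounds ("MM-DD")
#'   of the spring search window for annual population minima.
#' @param albedo shortwave albedo of the lake surface.
#' @param emissivity_water longwave emissivity of the water surface.
#' @param longwave_a multiplicative calibration constant of atmospheric
#'   longwave absorption (fitted value 1.02 for this lake).
#' @param c_p_water specific heat of water (J kg^-1 K^-1).
#' @param latitude_deg lake latitude, used for clear-sky radiation (deg N).
#' @param transmissivity clear-sky atmospheric transmissivity.
#' @param wind_height anemometer height (m).
#' @param smk_season `"month"`: seasonal blocking used by the seasonal
#'   Mann-Kendall test.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(constants = lake_constants(),
                            thresholds = irradiance_thresholds(),
                            r2_min = 0.99,
                            kd_resid_mult = 4,
                            kd_resid_floor = 0.06,
                            kd_mode = c("surface-linear", "full-profile"),
                            drop_surface = FALSE,
                            detection_limit_chla = 0.05,
                            detection_limit_mass = 0.05,
                            vernal_window_start = "04-01",
                            vernal_window_end = "07-31",
                            albedo = 0.07,
                            emissivity_water = 0.97,
                            longwave_a = 1.02,
                            c_p_water = 4186,
                            latitude_deg = 47.286,
                            transmissivity = 0.75,
                            wind_height = 10,
                            smk_season = "month") {
  kd_mode <- match.arg(kd_mode)
  structure(list(
    constants = constants,
    thresholds = thresholds,
    r2_min = r2_min,
    kd_resid_mult = kd_resid_mult,
    kd_resid_floor = kd_resid_floor,
    kd_mode = kd_mode,
    drop_surface = drop_surface,
    detection_limit_chla = detection_limit_chla,
    detection_limit_mass = detection_limit_mass,
    vernal_window_start = vernal_window_start,
    vernal_window_end = vernal_window_end,
    albedo = albedo,
    emissivity_water = emissivity_water,
    longwave_a = longwave_a,
    c_p_water = c_p_water,
    latitude_deg = latitude_deg,
    transmissivity = transmissivity,
    wind_height = wind_height,
    smk_season = smk_season
  ), class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration file
#'
#' Configurations are stored as plain YAML key-value text. Only keys present
#' in the file override the defaults, so a config file may be sparse.
#'
#' @param path file path.
#' @param config for [write_config()], a [pipeline_config()] list.
#' @return [read_config()] returns a `pipeline_config`; [write_config()]
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  const <- do.call(lake_constants, raw$constants %||% list())
  thr <- do.call(irradiance_thresholds, raw$thresholds %||% list())
  rest <- raw[setdiff(names(raw), c("constants", "thresholds"))]
  do.call(pipeline_config, c(list(constants = const, thresholds = thr), rest))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- unclass(config)
  out$constants <- unclass(out$constants)
  out$thresholds <- unclass(out$thresholds)
  yaml::write_yaml(out, path)
  invisible(path)
}
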