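#' Salinity from conductivity at 25 degC
#'
#' Converts conductivity normalised to 25 degC into salinity with a
#' lake-specific multiplicative factor appropriate for calcium-carbonate
#' dominated waters.
#'
#' @param cond25 conductivity at 25 degC (uS cm^-1), vectorised.
#' @param constants a [lake_constants()] list.
#' @return salinity (permille).
#' @export
#' @examples
#' salinity_from_conductivity(200)
salinity_from_conductivity <- function(cond25, constants = lake_constants()) {
  if (any(cond25 < 0, na.rm = TRUE)) {
    abort("conductivity must be non-negative")
  }
  cond25 * constants$cond_to_salinity
}

# drho/dT of the pure-water polynomial, used for the adiabatic lapse rate
.drho_dT <- function(theta) {
  6.7914e-2 - 2 * 9.0894e-3 * theta + 3 * 1.0171e-4 * theta^2 -
    4 * 1.2846e-6 * theta^3 + 5 * 1.1592e-8 * theta^4 -
    6 * 5.0125e-11 * theta^5
}

#' Potential temperature of lake water
#'
#' Corrects in-situ temperature adiabatically to the lake surface (0 dbar).
#' The freshwater adiabatic lapse rate Gamma = g * alpha(T) * T_abs / c_p is
#' evaluated at the in-situ temperature, with the thermal expansion
#' coefficient alpha taken from the pure-water density polynomial; pressure
#' follows from depth as p ~ rho0 g z. Over 0-140 m the correction is below
#' 0.02 K, so the first-order (single-step) correction is exact for all
#' practical purposes.
#'
#' @param t_insitu in-situ temperature (degC), vectorised.
#' @param depth depth of the measurement (m, positive downward).
#' @return potential temperature (degC).
#' @export
potential_temperature <- function(t_insitu, depth) {
  if (any(depth < 0, na.rm = TRUE)) {
    abort("depth must be non-negative")
  }
  rho <- potential_density(t_insitu)
  alpha <- -.drho_dT(t_insitu) / rho    # 1/K; negative below ~4 degC
  gamma <- 9.81 * alpha * (t_insitu + 273.15) / 4186   # K per m
  t_insitu - gamma * depth
}

#' Potential density of pure water
#'
#' Pure-water density polynomial (Chen-Millero type) evaluated at potential
#' temperature; the density maximum sits near 4 degC.
#'
#' @param theta potential temperature (degC), must lie in (0, 35).
#' @return density (kg m^-3).
#' @export
#' @examples
#' potential_density(4)
potential_density <- function(theta) {
  if (any(theta <= 0 | theta >= 35, na.rm = TRUE)) {
    abort("temperature outside the supported range (0, 35) degC")
  }
  999.8395 + 6.7914e-2 * theta - 9.0894e-3 * theta^2 +
    1.0171e-4 * theta^3 - 1.2846e-6 * theta^4 +
    1.1592e-8 * theta^5 - 5.0125e-11 * theta^6
}

#' Water density with haline contraction
#'
#' rho = rho_theta(theta) * (1 + beta * S): the pure-water potential density
#' corrected for dissolved solids via the haline contraction coefficient.
#'
#' @param theta potential temperature (degC).
#' @param salinity salinity (permille), non-negative.
#' @param constants a [lake_constants()] list.
#' @return density (kg m^-3).
#' @export
water_density <- function(theta, salinity, constants = lake_constants()) {
  if (any(salinity < 0, na.rm = TRUE)) {
    abort("salinity must be non-negative")
  }
  potential_density(theta) * (1 + constants$beta_haline * salinity)
}

#' Buoyancy (Brunt-Vaisala) frequency squared
#'
#' N^2(z) = -(g/rho)(drho/dz) with z pointing upward; on a depth axis
#' positive downward this means stable stratification (density increasing
#' with depth) gives N^2 > 0. The vertical gradient is a centred finite
#' difference at interior points and one-sided at the profile ends; N^2 is
#' reported at the grid depths themselves.
#'
#' @param density density profile (kg m^-3), ordered by increasing depth.
#' @param depth matching depths (m); defaults to a unit grid.
#' @param g gravitational acceleration (m s^-2).
#' @return N^2 per depth (s^-2).
#' @export
buoyancy_frequency <- function(density, depth = seq_along(density) - 1,
                               g = 9.81) {
  n <- length(density)
  if (n < 2L) abort("buoyancy_frequency needs at least 2 depth points")
  if (length(depth) != n) abort("depth and density lengths differ")
  grad <- numeric(n)
  grad[1] <- (density[2] - density[1]) / (depth[2] - depth[1])
  grad[n] <- (density[n] - density[n - 1]) / (depth[n] - depth[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    grad[i] <- (density[i + 1] - density[i - 1]) / (depth[i + 1] - depth[i - 1])
  }
  g * grad / density
}

#' Mixed-layer depth from a density profile
#'
#' The shallowest depth at which density strictly exceeds the near-surface
#' reference density (the mean over the top `surface_reference_span` metres)
#' by `mld_density_offset`. A profile that never meets the criterion is
#' treated as fully mixed: the deepest grid depth is returned with
#' `full_mixing = TRUE`.
#'
#' @param density density profile (kg m^-3), ordered by increasing depth.
#' @param depth matching depths (m).
#' @param constants a [lake_constants()] list.
#' @return list with `z_mix` (m) and `full_mixing` (logical).
#' @export
mixed_layer_depth <- function(density, depth = seq_along(density) - 1,
                              constants = lake_constants()) {
  span <- constants$surface_reference_span
  top <- depth <= span & !is.na(density)
  if (!any(depth[!is.na(density)] <= 0) || sum(top) < 2L) {
    abort("profile must cover the surface reference span (0-2 m)")
  }
  rho_ref <- mean(density[top])
  exceed <- which(density > rho_ref + constants$mld_density_offset)
  if (length(exceed) == 0L) {
    list(z_mix = max(depth[!is.na(density)]), full_mixing = TRUE)
  } else {
    list(z_mix = depth[exceed[1]], full_mixing = FALSE)
  }
}

#' Detect the metalimnion from an N^2 profile
#'
#' The metalimnion centre is the depth of maximum N^2 (ties resolved toward
#' the shallower depth); the upper and lower boundaries are the first
#' half-maximum crossings walking outward from the centre, with linear
#' interpolation between grid points for sub-grid precision. The detection
#' is valid only if the N^2 maximum exceeds `n2_validity_min` and the
#' boundary-to-boundary thickness stays below `meta_thickness_max`; when a
#' boundary crossing does not exist the boundary is clipped to the profile
#' end (and thickness-based validity usually fails).
#'
#' @param n2 N^2 profile (s^-2), ordered by increasing depth.
#' @param depth matching depths (m).
#' @param constants a [lake_constants()] list.
#' @return tibble with `metalimnion_upper`, `metalimnion_center`,
#'   `metalimnion_lower`, `metalimnion_valid`, `n2_max`.
#' @export
detect_metalimnion <- function(n2, depth = seq_along(n2) - 1,
                               constants = lake_constants()) {
  ok <- !is.na(n2)
  if (!any(ok) || all(n2[ok] <= 0)) {
    return(tibble(metalimnion_upper = NA_real_, metalimnion_center = NA_real_,
                  metalimnion_lower = NA_real_, metalimnion_valid = FALSE,
                  n2_max = if (any(ok)) max(n2[ok]) else NA_real_))
  }
  imax <- which.max(n2)            # first occurrence = shallower tie-break
  n2max <- n2[imax]
  half <- n2max / 2

  cross_at <- function(i_out, i_in) {
    # linear interpolation of the half-max crossing between two grid points
    depth[i_in] + (half - n2[i_in]) / (n2[i_out] - n2[i_in]) *
      (depth[i_out] - depth[i_in])
  }

  upper <- depth[1]
  if (imax > 1L) {
    for (i in seq(imax - 1L, 1L)) {
      if (!is.na(n2[i]) && n2[i] < half) {
        upper <- cross_at(i, i + 1L)
        break
      }
    }
  }
  n <- length(n2)
  lower <- depth[n]
  if (imax < n) {
    for (i in seq(imax + 1L, n)) {
      if (!is.na(n2[i]) && n2[i] < half) {
        lower <- cross_at(i, i - 1L)
        break
      }
    }
  }
  thickness <- lower - upper
  tibble(
    metalimnion_upper = upper,
    metalimnion_center = depth[imax],
    metalimnion_lower = lower,
    metalimnion_valid = n2max > constants$n2_validity_min &&
      thickness < constants$meta_thickness_max,
    n2_max = n2max
  )
}

#' Stratification summaries for a series of gridded profiles
#'
#' Runs the full density chain (salinity, potential temperature, potential
#' density, haline correction) and the stratification diagnostics (N^2,
#' mixed-layer depth, metalimnion detection) on every profile of a long
#' gridded profile table.
#'
#' @param profiles long tibble with columns `timestamp`, `depth_m`,
#'   `temp_c`, `cond25_uScm` (other channels are carried along unharmed).
#' @param config a [pipeline_config()] list.
#' @return A tibble of class `strat_summary` with one row per profile:
#'   `timestamp`, `z_mix`, `full_mixing`, `n2_max`, metalimnion bounds and
#'   validity, plus a list column `n2_profile` holding the per-depth N^2.
#' @export
stratify_profiles <- function(profiles, config = pipeline_config()) {
  const <- config$constants
  profiles %>%
    filter(!is.na(.data$temp_c), !is.na(.data$cond25_uScm)) %>%
    group_by(.data$timestamp) %>%
    group_modify(function(p, key) {
      p <- arrange(p, .data$depth_m)
      sal <- salinity_from_conductivity(p$cond25_uScm, const)
      theta <- potential_temperature(p$temp_c, p$depth_m)
      rho <- water_density(theta, sal, const)
      n2 <- buoyancy_frequency(rho, p$depth_m, const$g)
      mld <- mixed_layer_depth(rho, p$depth_m, const)
      meta <- detect_metalimnion(n2, p$depth_m, const)
      tibble(
        z_mix = mld$z_mix,
        full_mixing = mld$full_mixing,
        n2_max = meta$n2_max,
        metalimnion_upper = meta$metalimnion_upper,
        metalimnion_center = meta$metalimnion_center,
        metalimnion_lower = meta$metalimnion_lower,
        metalimnion_valid = meta$metalimnion_valid,
        n2_profile = list(tibble(depth_m = p$depth_m, n2 = n2))
      )
    }) %>%
    ungroup() %>%
    structure(class = c("strat_summary", class(tibble())))
}
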