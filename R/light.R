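#' Fit the PAR attenuation coefficient
#'
#' K_d is minus the slope of an ordinary least-squares regression of
#' ln(E_d) on depth. In `"surface-linear"` mode (stratified season) the fit
#' range starts at the surface and is extended downward point by point
#' while (i) the next point's ln(E_d) lies within a prediction band of the
#' running fit (`kd_resid_mult` residual SDs, floored at `kd_resid_floor`
#' log units to stay meaningful on noise-free data) and (ii) the running
#' fit keeps R^2 at or above `r2_min`, with at least four points included.
#' The strictness of the band is what stops the fit above opaque layers
#' such as dense metalimnetic blooms. In `"full-profile"` mode
#' (autumn/winter) the whole ln-positive profile is used.
#'
#' @param par downwelling PAR (umol photons m^-2 s^-1), by increasing depth.
#' @param depth matching depths (m).
#' @param config a [pipeline_config()] list; uses `r2_min`, `kd_mode`,
#'   `drop_surface` and the sensor floor.
#' @return An object of class `kd_fit`: list with `k_d` (m^-1), `fit_top`,
#'   `fit_bottom` (m), `fit_r2`, `n_fit`.
#' @export
attenuation_coefficient <- function(par, depth = seq_along(par) - 1,
                                    config = pipeline_config()) {
  keep <- !is.na(par) & par > config$thresholds$sensor_floor
  if (isTRUE(config$drop_surface)) keep <- keep & depth >= 1
  z <- depth[keep]
  y <- log(par[keep])
  n <- length(z)
  if (n < 4L) abort("too few valid PAR points for an attenuation fit",
                    class = "limnobloom_no_fit")
  r2_of <- function(m) {
    r <- suppressWarnings(stats::cor(z[1:m], y[1:m]))
    if (is.na(r)) 0 else r^2
  }
  if (config$kd_mode == "full-profile") {
    m <- n
  } else {
    m <- 4L
    while (m < n) {
      f <- lm(y[1:m] ~ z[1:m])
      sigma <- sqrt(sum(f$residuals^2) / f$df.residual)
      bound <- max(config$kd_resid_mult * sigma, config$kd_resid_floor)
      resid_at <- function(i) {
        abs(y[i] - unname(coef(f)[1] + coef(f)[2] * z[i]))
      }
      if (resid_at(m + 1L) >= bound) {
        # a lone noise outlier is tolerated; persistent deviation (an
        # opaque layer or attenuation kink) stops the fit
        if (m + 2L > n || resid_at(m + 2L) >= bound) break
      }
      if (r2_of(m + 1L) < config$r2_min) break
      m <- m + 1L
    }
  }
  fit <- lm(y[1:m] ~ z[1:m])
  k_d <- -unname(coef(fit)[2])
  if (!is.finite(k_d) || k_d <= 1e-10) {
    abort("PAR profile is not attenuating (k_d <= 0)",
          class = "limnobloom_no_fit")
  }
  structure(list(k_d = k_d, fit_top = z[1], fit_bottom = z[m],
                 fit_r2 = r2_of(m), n_fit = m),
            class = "kd_fit")
}

#' Euphotic depth from the attenuation coefficient
#'
#' The depth where 1 percent of surface irradiance remains:
#' z_eu = ln(100) / K_d.
#'
#' @param k_d attenuation coefficient (m^-1), positive.
#' @return euphotic depth (m).
#' @export
#' @examples
#' euphotic_depth(0.4605)
euphotic_depth <- function(k_d) {
  if (any(!is.finite(k_d) | k_d <= 0)) abort("k_d must be positive")
  log(100) / k_d
}

#' Depth at which irradiance falls to a threshold
#'
#' Finds the shallowest depth where E_d crosses the threshold, with the
#' crossing interpolated linearly in ln(E_d) between the bracketing grid
#' points (exponential decay between samples). Returns `NA` when the
#' surface irradiance is already below the threshold; when the whole
#' recorded profile stays at or above the threshold the deepest recorded
#' depth is returned and flagged unbounded.
#'
#' @param par downwelling PAR profile, by increasing depth.
#' @param depth matching depths (m).
#' @param threshold irradiance threshold (umol photons m^-2 s^-1), > 0.
#' @return list with `depth` (m or NA) and `unbounded` (logical).
#' @export
irradiance_depth <- function(par, depth = seq_along(par) - 1, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    abort("threshold must be a single positive number")
  }
  keep <- !is.na(par) & par > 0
  e <- par[keep]
  z <- depth[keep]
  if (length(e) == 0L) return(list(depth = NA_real_, unbounded = FALSE))
  below <- which(e < threshold)
  if (length(below) == 0L) {
    return(list(depth = z[length(z)], unbounded = TRUE))
  }
  i <- below[1]
  if (i == 1L) return(list(depth = NA_real_, unbounded = FALSE))
  frac <- (log(e[i - 1]) - log(threshold)) / (log(e[i - 1]) - log(e[i]))
  list(depth = z[i - 1] + frac * (z[i] - z[i - 1]), unbounded = FALSE)
}

#' Species-intrinsic irradiance depths
#'
#' Applies [irradiance_depth()] at the three buoyancy-controlling
#' thresholds: `e_comp` (buoyancy gain), `e_buoy` (neutral buoyancy) and
#' `e_sat` (buoyancy loss). Because irradiance decreases with depth, the
#' outputs satisfy z_sat <= z_buoy <= z_comp whenever all exist.
#'
#' @inheritParams irradiance_depth
#' @param thresholds an [irradiance_thresholds()] list.
#' @return tibble with `z_comp`, `z_buoy`, `z_sat` (m, NA when the surface
#'   irradiance is below a threshold) and matching `*_unbounded` flags.
#' @export
intrinsic_depths <- function(par, depth = seq_along(par) - 1,
                             thresholds = irradiance_thresholds()) {
  comp <- irradiance_depth(par, depth, thresholds$e_comp)
  buoy <- irradiance_depth(par, depth, thresholds$e_buoy)
  sat <- irradiance_depth(par, depth, thresholds$e_sat)
  tibble(
    z_comp = comp$depth, z_buoy = buoy$depth, z_sat = sat$depth,
    z_comp_unbounded = comp$unbounded,
    z_buoy_unbounded = buoy$unbounded,
    z_sat_unbounded = sat$unbounded
  )
}

#' Light summaries for a series of gridded profiles
#'
#' Fits K_d and derives the euphotic depth and the three species-intrinsic
#' irradiance depths for every profile date. Profiles on which no
#' attenuation fit is possible (night casts, constant PAR) get `NA` fit
#' fields but still report the intrinsic depths where defined.
#'
#' @param profiles long tibble with columns `timestamp`, `depth_m`,
#'   `par_umol_m2_s`.
#' @param config a [pipeline_config()] list.
#' @return A tibble of class `light_summary` with one row per profile.
#' @export
summarize_light <- function(profiles, config = pipeline_config()) {
  profiles %>%
    group_by(.data$timestamp) %>%
    group_modify(function(p, key) {
      p <- arrange(p, .data$depth_m)
      fit <- tryCatch(
        attenuation_coefficient(p$par_umol_m2_s, p$depth_m, config),
        limnobloom_no_fit = function(e) NULL
      )
      intr <- intrinsic_depths(p$par_umol_m2_s, p$depth_m, config$thresholds)
      tibble(
        k_d = fit$k_d %||% NA_real_,
        fit_top = fit$fit_top %||% NA_real_,
        fit_bottom = fit$fit_bottom %||% NA_real_,
        fit_r2 = fit$fit_r2 %||% NA_real_,
        z_eu = if (is.null(fit)) NA_real_ else euphotic_depth(fit$k_d)
      ) %>%
        bind_cols(intr)
    }) %>%
    ungroup() %>%
    structure(class = c("light_summary", class(tibble())))
}
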