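STEFAN_BOLTZMANN <- 5.670374419e-8
VON_KARMAN <- 0.4

#' Saturation vapour pressure over water
#'
#' Magnus form, hPa.
#' @param temp_c temperature (degC).
#' @return saturation vapour pressure (hPa).
#' @export
saturation_vapor_pressure <- function(temp_c) {
  6.112 * exp(17.62 * temp_c / (243.12 + temp_c))
}

# specific humidity (kg/kg) from vapour pressure (hPa) and pressure (hPa)
.specific_humidity <- function(e_hpa, p_hpa) {
  0.622 * e_hpa / (p_hpa - 0.378 * e_hpa)
}

#' Bulk latent and sensible heat fluxes with stability adjustment
#'
#' Bulk-aerodynamic turbulent fluxes following Monin-Obukhov similarity:
#' neutral 10-m transfer coefficients are adjusted iteratively with
#' Businger-Dyer stability functions (unstable branch) or the log-linear
#' stable branch, until the coefficients change by less than 1e-4 relative
#' or 50 iterations are reached (failure falls back to neutral
#' coefficients, flagged). Fluxes are signed positive toward the lake, so
#' evaporation and surface-to-air heat transfer are negative.
#'
#' @param tair_c air temperature (degC), vectorised over days.
#' @param rh_pct relative humidity (percent).
#' @param pressure_hpa atmospheric pressure (hPa).
#' @param wind_ms wind speed at measurement height (m s^-1).
#' @param tsurf_c lake surface temperature (degC).
#' @param wind_height anemometer height (m).
#' @param c_dn,c_hn,c_en neutral drag / heat / moisture transfer
#'   coefficients at the measurement height.
#' @return tibble with `q_latent`, `q_sensible` (W m^-2) and `converged`.
#' @export
bulk_turbulent_fluxes <- function(tair_c, rh_pct, pressure_hpa, wind_ms,
                                  tsurf_c, wind_height = 10,
                                  c_dn = 1.3e-3, c_hn = 1.35e-3,
                                  c_en = 1.35e-3) {
  one_day <- function(ta, rh, p, u, ts) {
    if (any(is.na(c(ta, rh, p, u, ts)))) {
      return(c(NA_real_, NA_real_, NA))
    }
    ea <- rh / 100 * saturation_vapor_pressure(ta)
    es <- saturation_vapor_pressure(ts)
    qa <- .specific_humidity(ea, p)
    qs <- .specific_humidity(es, p)
    ta_k <- ta + 273.15
    tv <- ta_k * (1 + 0.608 * qa)
    rho <- 100 * p / (287.05 * tv)
    lv <- 2.501e6 - 2370 * ts
    cp <- 1005
    if (u <= 0) {
      return(c(0, 0, TRUE))
    }
    cd <- c_dn; ch <- c_hn; ce <- c_en
    converged <- FALSE
    for (it in seq_len(50)) {
      h <- rho * cp * ch * u * (ta - ts)
      e <- rho * lv * ce * u * (qa - qs)
      ustar <- sqrt(cd) * u
      w_thetav <- h / (rho * cp) + 0.61 * ta_k * e / (rho * lv)
      if (abs(w_thetav) < 1e-12) {
        converged <- TRUE
        break
      }
      obukhov <- -ustar^3 * tv / (VON_KARMAN * 9.81 * w_thetav)
      zeta <- max(min(wind_height / obukhov, 10), -10)
      if (zeta < 0) {
        x <- (1 - 16 * zeta)^0.25
        psi_m <- 2 * log((1 + x) / 2) + log((1 + x^2) / 2) -
          2 * atan(x) + pi / 2
        psi_h <- 2 * log((1 + x^2) / 2)
      } else {
        psi_m <- -5 * zeta
        psi_h <- -5 * zeta
      }
      denom_m <- 1 - sqrt(c_dn) / VON_KARMAN * psi_m
      denom_h <- 1 - c_hn / (VON_KARMAN * sqrt(c_dn)) * psi_h
      denom_m <- max(denom_m, 0.1)
      denom_h <- max(denom_h, 0.1)
      cd_new <- c_dn / denom_m^2
      ch_new <- c_hn / (denom_m * denom_h)
      ce_new <- c_en / (denom_m * denom_h)
      delta <- max(abs(cd_new - cd) / cd, abs(ch_new - ch) / ch)
      cd <- cd_new; ch <- ch_new; ce <- ce_new
      if (delta < 1e-4) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      cd <- c_dn; ch <- c_hn; ce <- c_en
    }
    h <- rho * cp * ch * u * (ta - ts)
    e <- rho * lv * ce * u * (qa - qs)
    c(e, h, converged)
  }
  out <- mapply(one_day, tair_c, rh_pct, pressure_hpa, wind_ms, tsurf_c)
  tibble(q_latent = out[1, ], q_sensible = out[2, ],
         converged = as.logical(out[3, ]))
}

#' Daily-mean clear-sky solar radiation
#'
#' Extraterrestrial radiation from solar geometry (declination, sunset hour
#' angle) scaled by a fixed atmospheric transmissivity; used as the
#' reference for the cloudiness proxy.
#'
#' @param date `Date` vector.
#' @param latitude_deg latitude (degrees north).
#' @param transmissivity clear-sky transmissivity.
#' @return daily-mean clear-sky shortwave irradiance (W m^-2).
#' @export
clear_sky_radiation <- function(date, latitude_deg = 47.286,
                                transmissivity = 0.75) {
  j <- as.numeric(format(as.Date(date), "%j"))
  phi <- latitude_deg * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * j / 365)
  delta <- 0.409 * sin(2 * pi * j / 365 - 1.39)
  ws <- acos(pmin(pmax(-tan(phi) * tan(delta), -1), 1))
  ra <- (1367 / pi) * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  transmissivity * pmax(ra, 0)
}

#' Effective atmospheric longwave emissivity
#'
#' Brutsaert clear-sky emissivity 1.24 (e_a / T_a)^(1/7) with a cloud
#' correction factor (1 + 0.22 C^2), capped at 1. The cloudiness proxy C is
#' one minus the ratio of observed to clear-sky solar radiation.
#'
#' @param tair_c air temperature (degC).
#' @param e_a_hpa air vapour pressure (hPa).
#' @param cloud cloudiness proxy in `[0, 1]`.
#' @return effective emissivity (dimensionless, <= 1).
#' @export
atmospheric_emissivity <- function(tair_c, e_a_hpa, cloud = 0) {
  eps_clear <- 1.24 * (e_a_hpa / (tair_c + 273.15))^(1 / 7)
  pmin(eps_clear * (1 + 0.22 * cloud^2), 1)
}

#' Radiative flux components
#'
#' q_sw_net = (1 - albedo) * SW_in; q_lw_out = eps_w sigma T_surf^4;
#' q_lw_in = a * eps_atm * sigma * T_air^4, with the effective atmospheric
#' emissivity from [atmospheric_emissivity()] and the multiplicative
#' calibration constant `a` of the longwave absorption.
#'
#' @param met tibble with `date`, `tair_c`, `rh_pct`, `swdown_wm2`,
#'   `tsurf_c`.
#' @param a longwave calibration constant (> 0).
#' @param config a [pipeline_config()] list.
#' @return tibble with `q_sw_net`, `q_lw_in`, `q_lw_out` (W m^-2).
#' @export
radiative_fluxes <- function(met, a = NULL, config = pipeline_config()) {
  a <- a %||% config$longwave_a
  if (a <= 0) abort("longwave constant a must be positive")
  sw_clear <- clear_sky_radiation(met$date, config$latitude_deg,
                                  config$transmissivity)
  cloud <- pmin(pmax(1 - met$swdown_wm2 / pmax(sw_clear, 1), 0), 1)
  e_a <- met$rh_pct / 100 * saturation_vapor_pressure(met$tair_c)
  eps_atm <- atmospheric_emissivity(met$tair_c, e_a, cloud)
  tibble(
    q_sw_net = (1 - config$albedo) * met$swdown_wm2,
    q_lw_in = a * eps_atm * STEFAN_BOLTZMANN * (met$tair_c + 273.15)^4,
    q_lw_out = config$emissivity_water * STEFAN_BOLTZMANN *
      (met$tsurf_c + 273.15)^4
  )
}

#' Daily surface heat-flux budget
#'
#' Combines the radiative and bulk turbulent components into the net
#' surface heat flux, positive toward the lake.
#'
#' @param met meteorology tibble: `date`, `tair_c`, `rh_pct`,
#'   `pressure_hpa`, `wind_ms`, `swdown_wm2`, `tsurf_c`.
#' @param a longwave calibration constant; default from `config`.
#' @param config a [pipeline_config()] list.
#' @return A tibble of class `flux_series`: one row per day with all five
#'   components, `q_net` and the stability-iteration `converged` flag.
#' @export
surface_fluxes <- function(met, a = NULL, config = pipeline_config()) {
  rad <- radiative_fluxes(met, a, config)
  turb <- bulk_turbulent_fluxes(met$tair_c, met$rh_pct, met$pressure_hpa,
                                met$wind_ms, met$tsurf_c,
                                wind_height = config$wind_height)
  bind_cols(tibble(date = as.Date(met$date)), rad, turb) %>%
    mutate(q_net = .data$q_sw_net + .data$q_lw_in - .data$q_lw_out +
             .data$q_latent + .data$q_sensible) %>%
    structure(class = c("flux_series", class(tibble())))
}

#' Whole-lake heat content of a temperature profile
#'
#' Sum over 1-m layers of rho * c_p * T * V, relative to 0 degC.
#'
#' @param temp_c temperature per 1-m cell (degC), indexed by cell top depth.
#' @param depth cell top depths (m).
#' @param hyps hypsography tibble (`layer_top_m`, `volume_m3`).
#' @param c_p specific heat of water (J kg^-1 K^-1).
#' @return heat content (J).
#' @export
heat_content <- function(temp_c, depth = seq_along(temp_c) - 1, hyps,
                         c_p = 4186) {
  idx <- match(hyps$layer_top_m, depth)
  if (anyNA(idx)) abort("profile grid does not cover the hypsography layers")
  t_layer <- temp_c[idx]
  keep <- !is.na(t_layer)
  rho <- water_density(pmax(t_layer[keep], 0.01), 0)
  sum(rho * c_p * t_layer[keep] * hyps$volume_m3[keep])
}

#' Calibrate the longwave constant against lake heat content
#'
#' The net heat flux is affine in the longwave constant a, so the a that
#' minimises the squared mismatch between cumulative q_net * area and the
#' observed heat-content change has a closed-form least-squares solution.
#'
#' @param met daily meteorology tibble (see [surface_fluxes()]).
#' @param heat_series tibble with `date` and `heat_content_j` (J), observed
#'   on a subset of the met dates.
#' @param lake_area lake surface area (m^2).
#' @param config a [pipeline_config()] list.
#' @return An object of class `lw_calibration`: list with `a`, `n_obs`,
#'   `rss` (J^2) and `rmse_j`.
#' @export
fit_longwave_constant <- function(met, heat_series, lake_area,
                                  config = pipeline_config()) {
  met <- arrange(met, .data$date)
  base <- surface_fluxes(met, a = 1, config = config)
  lw_unit <- base$q_lw_in                      # q_lw_in at a = 1
  q_base <- base$q_net - lw_unit               # everything except lw_in
  cum_base <- cumsum(q_base) * 86400 * lake_area
  cum_lw <- cumsum(lw_unit) * 86400 * lake_area
  hs <- heat_series %>%
    arrange(.data$date) %>%
    filter(.data$date %in% as.Date(met$date))
  if (nrow(hs) < 2L) abort("need at least two overlapping heat-content dates")
  idx <- match(as.Date(hs$date), as.Date(met$date))
  y <- (hs$heat_content_j - hs$heat_content_j[1]) -
    (cum_base[idx] - cum_base[idx[1]])
  x <- cum_lw[idx] - cum_lw[idx[1]]
  sxx <- sum(x^2)
  if (sxx <= 0) abort("longwave signal is degenerate; a is unidentifiable",
                      class = "limnobloom_unidentifiable")
  a_hat <- sum(x * y) / sxx
  rss <- sum((y - a_hat * x)^2)
  structure(list(a = a_hat, n_obs = nrow(hs), rss = rss,
                 rmse_j = sqrt(rss / nrow(hs))),
            class = "lw_calibration")
}

#' Seasonal climatology and anomalies of a daily series
#'
#' Seasons are DJF, MAM, JJA and SON, with December assigned to the
#' following year's winter. The anomaly of a season-year is its mean minus
#' the long-term mean of that season; seasons whose absolute anomaly
#' exceeds one long-term standard deviation are flagged.
#'
#' @param series tibble with `date` and `value`.
#' @return A tibble of class `seasonal_anomaly`: `season`, `year`,
#'   `mean_value`, `anomaly`, `flagged`.
#' @export
seasonal_climatology <- function(series) {
  s <- series %>%
    mutate(
      month = lubridate::month(.data$date),
      season = dplyr::case_when(
        month %in% c(12, 1, 2) ~ "DJF",
        month %in% 3:5 ~ "MAM",
        month %in% 6:8 ~ "JJA",
        TRUE ~ "SON"
      ),
      year = lubridate::year(.data$date) + as.integer(.data$month == 12)
    ) %>%
    group_by(.data$season, .data$year) %>%
    summarise(mean_value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  s %>%
    group_by(.data$season) %>%
    mutate(
      anomaly = .data$mean_value - mean(.data$mean_value),
      flagged = abs(.data$anomaly) > sd(.data$mean_value)
    ) %>%
    ungroup() %>%
    arrange(.data$year, match(.data$season, c("DJF", "MAM", "JJA", "SON"))) %>%
    structure(class = c("seasonal_anomaly", class(tibble())))
}
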