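#' Synthetic hypsography from a power-law basin profile
#'
#' Lake area shrinks with depth as `(1 - z / max_depth)^shape_exponent`;
#' layer volumes are exact integrals of that profile, scaled so the whole
#' basin holds `total_volume`. The default exponent is chosen so the 0-120 m
#' grid holds 98 percent of the total volume, mirroring the monitored
#' basin.
#'
#' @param total_volume whole-lake volume (m^3).
#' @param max_depth maximum lake depth (m).
#' @param shape_exponent basin shape exponent (0 = cylinder, 2 = cone);
#'   `NULL` picks the exponent for which the grid holds `grid_fraction` of
#'   the volume.
#' @param grid_max deepest analysis grid depth (m).
#' @param grid_fraction volume fraction the 0-`grid_max` grid should hold
#'   when `shape_exponent` is `NULL`.
#' @return hypsography tibble (`layer_top_m`, `layer_bottom_m`,
#'   `volume_m3`) for 1-m layers down to `grid_max`, with the basin totals
#'   in attributes `total_volume` and `grid_fraction`.
#' @export
#' @examples
#' hyps <- make_hypsography()
#' sum(hyps$volume_m3) / attr(hyps, "total_volume")
make_hypsography <- function(total_volume = 3.3e9, max_depth = 136,
                             shape_exponent = NULL, grid_max = 120,
                             grid_fraction = 0.98) {
  if (total_volume <= 0 || max_depth <= grid_max) {
    abort("total_volume must be positive and max_depth deeper than the grid")
  }
  if (is.null(shape_exponent)) {
    # (1 - grid_max/max_depth)^(q+1) = 1 - grid_fraction
    shape_exponent <- log(1 - grid_fraction) /
      log(1 - grid_max / max_depth) - 1
  }
  if (!is.finite(shape_exponent) || shape_exponent < 0) {
    abort("shape_exponent must be a non-negative number")
  }
  q1 <- shape_exponent + 1
  tops <- 0:(grid_max - 1)
  vol <- total_volume *
    ((1 - tops / max_depth)^q1 - (1 - (tops + 1) / max_depth)^q1)
  out <- tibble(layer_top_m = tops, layer_bottom_m = tops + 1,
                volume_m3 = vol)
  attr(out, "total_volume") <- total_volume
  attr(out, "grid_fraction") <- sum(vol) / total_volume
  out
}

#' Scenario configuration for the synthetic-lake generator
#'
#' Defaults emulate a 12-year biweekly monitoring campaign on a deep
#' monomictic prealpine lake: a seasonally deepening thermocline,
#' interannually variable winter mixing (holomixis in some years,
#' incomplete mixing to 47-86 m in others), an exponentially attenuated
#' light field with biomass self-shading, and a buoyancy-regulated
#' cyanobacterial layer with bimodal annual growth (metalimnetic mid-June
#' to September, epilimnetic October to December, decay during winter
#' mixing, gas-vesicle collapse below 100 m).
#'
#' @param n_years number of simulated years.
#' @param profiles_per_year sampling dates per year (biweekly = 26).
#' @param winter_mix_depths maximum winter mixing depth per year (m);
#'   recycled to `n_years`.
#' @param start_year calendar year of the first simulated year.
#' @param hypolimnion_temp deep-water temperature (degC).
#' @param surface_temp_peak summer epilimnion temperature maximum (degC).
#' @param winter_temp mixed-column winter temperature (degC).
#' @param thermocline_width e-folding width of the thermocline (m).
#' @param cond_surface epilimnetic conductivity at 25 degC (uS cm^-1).
#' @param cond_deep_excess deep-water conductivity excess (uS cm^-1).
#' @param cond_width e-folding width of the deep conductivity gradient (m).
#' @param kd_background biomass-free attenuation coefficient (m^-1).
#' @param kd_per_chla biomass-specific attenuation (m^-1 per ug L^-1).
#' @param par_surface_max,par_surface_min summer / winter midday-mean
#'   surface PAR (umol photons m^-2 s^-1).
#' @param chla_euk_summer,chla_euk_winter eukaryote chlorophyll, uniform
#'   through the lit zone (ug L^-1).
#' @param mu_meta,mu_autumn maximum net growth rates of the metalimnetic
#'   and autumn epilimnetic phases (day^-1).
#' @param mu_winter_rate winter decay rate at full-depth mixing (day^-1);
#'   scaled by the year's mixing depth / 120.
#' @param mu_spring net rate during early stratification (day^-1).
#' @param collapse_depth gas-vesicle collapse depth (m); biomass mixed
#'   below it during holomixis is removed.
#' @param b_init initial population (metric tons chlorophyll a).
#' @param b_capacity logistic ceiling of the population (tons).
#' @param layer_sigma vertical standard deviation of the stratified layer (m).
#' @param stratified_onset_doy,meta_growth_start_doy,autumn_start_doy
#'   day-of-year breakpoints of the growth schedule.
#' @param temp_sd,cond_sd additive measurement noise (degC, uS cm^-1).
#' @param chla_cv,par_cv multiplicative lognormal noise (coefficient of
#'   variation) of the chlorophyll and PAR channels.
#' @param a_true longwave calibration constant used by the heat-budget
#'   generator.
#' @param lake_area lake surface area (m^2).
#' @param total_volume,max_depth_lake basin geometry for the hypsography.
#' @return named list of class `scenario_config`.
#' @export
scenario_config <- function(n_years = 12,
                            profiles_per_year = 26,
                            winter_mix_depths = c(120, 120, 120, 120, 120,
                                                  47, 82, 61, 115, 120, 81, 86),
                            start_year = 2009,
                            hypolimnion_temp = 4.6,
                            surface_temp_peak = 18,
                            winter_temp = 4.3,
                            thermocline_width = 4,
                            cond_surface = 205,
                            cond_deep_excess = 40,
                            cond_width = 2,
                            kd_background = 0.22,
                            kd_per_chla = 0.02,
                            par_surface_max = 1400,
                            par_surface_min = 250,
                            chla_euk_summer = 3,
                            chla_euk_winter = 0.5,
                            mu_meta = 0.02,
                            mu_autumn = 0.015,
                            mu_winter_rate = 0.025,
                            mu_spring = -0.005,
                            collapse_depth = 100,
                            b_init = 10,
                            b_capacity = 25,
                            layer_sigma = 2,
                            stratified_onset_doy = 105,
                            meta_growth_start_doy = 166,
                            autumn_start_doy = 274,
                            temp_sd = 0.01,
                            cond_sd = 0.5,
                            chla_cv = 0.05,
                            par_cv = 0.02,
                            a_true = 1.02,
                            lake_area = 66.6e6,
                            total_volume = 3.3e9,
                            max_depth_lake = 136) {
  winter_mix_depths <- rep_len(winter_mix_depths, n_years)
  if (any(winter_mix_depths <= 0 | winter_mix_depths > 120)) {
    abort("winter_mix_depths must lie in (0, 120]")
  }
  if (any(winter_mix_depths < 20)) {
    abort("winter mixing shallower than the summer thermocline is inconsistent")
  }
  out <- as.list(environment())
  structure(out, class = c("scenario_config", "list"))
}

# scheduled mixed-layer depth (piecewise linear over day of year)
.zmix_schedule <- function(doy, d_winter, onset_doy = 105) {
  knots_x <- c(1, 55, 78, onset_doy, 150, 250, 300, 365)
  knots_y <- c(min(40, d_winter), d_winter, d_winter, 15, 10, 8, 20, 40)
  approx(knots_x, knots_y, xout = doy, rule = 2)$y
}

# scheduled epilimnion temperature
.tmix_schedule <- function(doy, winter_temp, peak_temp) {
  mid <- (peak_temp + 0.5 + winter_temp) / 2
  amp <- (peak_temp + 0.5 - winter_temp) / 2
  pmax(winter_temp, mid + amp * cos(2 * pi * (doy - 215) / 365))
}

# surface PAR (daytime mean at sampling time)
.par_surface <- function(doy, par_min, par_max) {
  mid <- (par_max + par_min) / 2
  amp <- (par_max - par_min) / 2
  mid + amp * cos(2 * pi * (doy - 172) / 365)
}

# PAR profile from a total-chlorophyll profile (cell-wise Beer-Lambert)
.par_profile <- function(e0, kd_bg, kd_chl, chla_total) {
  k <- kd_bg + kd_chl * chla_total
  n <- length(k)
  e0 * exp(-c(0, cumsum(k[-n])))
}

# ln-interpolated threshold crossing on a grid (generator-side twin of
# irradiance_depth, kept minimal)
.light_depth <- function(par, depth, threshold) {
  below <- which(par < threshold)
  if (length(below) == 0L) return(depth[length(depth)])
  i <- below[1]
  if (i == 1L) return(NA_real_)
  frac <- (log(par[i - 1]) - log(threshold)) / (log(par[i - 1]) - log(par[i]))
  depth[i - 1] + frac * (depth[i] - depth[i - 1])
}

#' Generate a multi-year synthetic monitoring dataset
#'
#' Produces the three data streams the analysis pipeline consumes --
#' weekly/biweekly 1-m profiles (temperature, conductivity, oxygen,
#' class-resolved chlorophyll, PAR), daily meteorology with a closed heat
#' budget, and a hypsographic table -- together with the per-date and
#' per-year ground truth the generator imposed. Deterministic given `seed`.
#'
#' The cyanobacterial layer is centred on the generator's own
#' neutral-buoyancy depth (the 6.5 umol m^-2 s^-1 isolume of its light
#' field, found by fixed-point iteration so self-shading is honoured)
#' while the water column is stratified, and is mixed uniformly through
#' the mixed layer otherwise. Ground-truth stratification quantities are
#' defined by running the water-column operators on the noise-free fields,
#' so recovery tests measure robustness to measurement noise alone.
#'
#' @param config a [scenario_config()] list.
#' @param seed integer RNG seed.
#' @return list with `profiles`, `meteo`, `hypsography`, `heat_series`,
#'   `truth` (per sampling date), `truth_year` (per-year survival from the
#'   noise-free series), and `config`.
#' @export
simulate_lake_scenario <- function(config = scenario_config(), seed = 1) {
  set.seed(seed)
  cfg <- config
  depth <- 0:120
  nz <- length(depth)
  hyps <- make_hypsography(cfg$total_volume, cfg$max_depth_lake,
                           grid_max = 120)
  vol <- hyps$volume_m3

  years <- cfg$start_year + seq_len(cfg$n_years) - 1
  sample_dates <- as.Date(unlist(lapply(years, function(y) {
    as.character(as.Date(paste0(y, "-01-07")) +
                   14 * (seq_len(cfg$profiles_per_year) - 1))
  })))
  all_days <- seq(as.Date(paste0(min(years), "-01-01")),
                  as.Date(paste0(max(years), "-12-31")), by = "day")

  d_winter_of <- setNames(rep_len(cfg$winter_mix_depths, cfg$n_years),
                          as.character(years))

  day_state <- function(dt) {
    doy <- as.numeric(format(dt, "%j"))
    yr <- as.character(lubridate::year(dt))
    d_w <- d_winter_of[[yr]]
    list(
      doy = doy,
      z_mix = .zmix_schedule(doy, d_w, cfg$stratified_onset_doy),
      t_mix = .tmix_schedule(doy, cfg$winter_temp, cfg$surface_temp_peak),
      e0 = .par_surface(doy, cfg$par_surface_min, cfg$par_surface_max),
      layered = doy > cfg$stratified_onset_doy & doy < cfg$autumn_start_doy
    )
  }

  # ---- daily biomass trajectory with winter kill and logistic ceiling ----
  frac_below_collapse <- sum(vol[hyps$layer_top_m >= cfg$collapse_depth]) /
    sum(vol)
  b <- cfg$b_init
  b_series <- numeric(length(all_days))
  killed <- FALSE
  for (i in seq_along(all_days)) {
    st <- day_state(all_days[i])
    doy <- st$doy
    if (doy == 1) killed <- FALSE
    d_w <- d_winter_of[[as.character(lubridate::year(all_days[i]))]]
    if (doy <= cfg$stratified_onset_doy && st$z_mix > 20) {
      mu <- -cfg$mu_winter_rate * d_w / 120
      if (!killed && st$z_mix >= cfg$collapse_depth) {
        b <- b * (1 - frac_below_collapse)
        killed <- TRUE
      }
    } else if (doy < cfg$meta_growth_start_doy) {
      mu <- cfg$mu_spring
    } else if (doy < cfg$autumn_start_doy) {
      mu <- cfg$mu_meta * (1 - b / cfg$b_capacity)
    } else {
      mu <- cfg$mu_autumn * (1 - b / cfg$b_capacity)
    }
    b <- b * exp(mu)
    b_series[i] <- b
  }

  # ---- per-sampling-date noise-free fields and ground truth ----
  const <- lake_constants()
  mk_profile <- function(dt) {
    st <- day_state(dt)
    d <- st$z_mix
    t_deep <- cfg$hypolimnion_temp
    temp <- ifelse(depth <= d, st$t_mix,
                   t_deep + (st$t_mix - t_deep) *
                     exp(-(depth - d) / cfg$thermocline_width))
    cond <- ifelse(depth <= d, cfg$cond_surface,
                   cfg$cond_surface + cfg$cond_deep_excess *
                     (1 - exp(-(depth - d) / cfg$cond_width)))
    season <- (1 + cos(2 * pi * (st$doy - 200) / 365)) / 2
    c_euk <- cfg$chla_euk_winter +
      (cfg$chla_euk_summer - cfg$chla_euk_winter) * season
    # eukaryotes occupy the lit zone uniformly; the emitted channel is
    # truncated at the light floor after the final light field is known
    chla_euk <- rep(c_euk, nz)

    b_today <- b_series[match(dt, all_days)]
    mass_mg <- b_today * 1e9
    in_grid <- seq_len(nrow(hyps))           # cells with a volume layer
    if (st$layered) {
      center <- .light_depth(.par_profile(st$e0, cfg$kd_background,
                                          cfg$kd_per_chla, chla_euk),
                             depth, 6.5)
      for (it in 1:8) {
        shape <- exp(-(depth - center)^2 / (2 * cfg$layer_sigma^2))
        conc <- mass_mg * shape / sum(shape[in_grid] * vol)
        par_full <- .par_profile(st$e0, cfg$kd_background, cfg$kd_per_chla,
                                 chla_euk + conc)
        new_center <- .light_depth(par_full, depth, 6.5)
        if (is.na(new_center)) break
        if (abs(new_center - center) < 0.05) {
          center <- new_center
          break
        }
        center <- new_center
      }
      shape <- exp(-(depth - center)^2 / (2 * cfg$layer_sigma^2))
      chla_p <- mass_mg * shape / sum(shape[in_grid] * vol)
      regime <- "metalimnetic"
      layer_center <- center
    } else {
      mix_to <- max(d, 12)
      shape <- as.numeric(depth <= mix_to)
      chla_p <- mass_mg * shape / sum(shape[in_grid] * vol)
      regime <- "mixed"
      layer_center <- NA_real_
    }
    par_true <- .par_profile(st$e0, cfg$kd_background, cfg$kd_per_chla,
                             chla_euk + chla_p)
    chla_euk <- ifelse(par_true >= 0.05, c_euk, 0)
    o2 <- pmax(4, 12 - 0.25 * temp - 2 * season * pmax(0, (depth - 60) / 60))

    # truth from the noise-free fields
    sal <- salinity_from_conductivity(cond, const)
    rho <- water_density(potential_temperature(temp, depth), sal, const)
    n2 <- buoyancy_frequency(rho, depth, const$g)
    mld <- mixed_layer_depth(rho, depth, const)
    meta <- detect_metalimnion(n2, depth, const)
    kd_true <- cfg$kd_background + cfg$kd_per_chla * (chla_euk[1] + chla_p[1])
    z_buoy_true <- .light_depth(par_true, depth, 6.5)

    list(
      profile = tibble(
        timestamp = dt, depth_m = depth,
        temp_c = temp + rnorm(nz, 0, cfg$temp_sd),
        cond25_uScm = cond + rnorm(nz, 0, cfg$cond_sd),
        o2_mgL = o2,
        chla_plank_ugL = chla_p * rlnorm(nz, -cfg$chla_cv^2 / 2, cfg$chla_cv),
        chla_euk_ugL = chla_euk * rlnorm(nz, -cfg$chla_cv^2 / 2, cfg$chla_cv),
        par_umol_m2_s = ifelse(
          par_true >= 0.05,
          par_true * rlnorm(nz, -cfg$par_cv^2 / 2, cfg$par_cv),
          NA_real_
        )
      ),
      truth = tibble(
        timestamp = dt,
        z_mix_true = mld$z_mix,
        z_mix_scheduled = d,
        metalimnion_upper_true = meta$metalimnion_upper,
        metalimnion_center_true = meta$metalimnion_center,
        metalimnion_lower_true = meta$metalimnion_lower,
        metalimnion_valid_true = meta$metalimnion_valid,
        k_d_true = kd_true,
        z_buoy_true = z_buoy_true,
        layer_center_true = layer_center,
        total_tons_true = b_today,
        regime_true = regime
      )
    )
  }

  made <- purrr::map(sample_dates, mk_profile)
  profiles <- purrr::list_rbind(purrr::map(made, "profile"))
  truth <- purrr::list_rbind(purrr::map(made, "truth"))

  # ---- per-year true survival/recovery from the noise-free sampled series ----
  cfg_pipe <- pipeline_config()
  truth_pop <- truth %>%
    select("timestamp") %>%
    mutate(total_tons = truth$total_tons_true, z_plankt = NA_real_,
           below_detection = FALSE)
  truth_year <- annual_extremes(truth_pop, cfg_pipe)

  budget <- simulate_heat_budget(
    n_years = cfg$n_years, start_year = cfg$start_year, a_true = cfg$a_true,
    lake_area = cfg$lake_area, seed = seed + 1L,
    tsurf = .tmix_schedule(as.numeric(format(all_days, "%j")),
                           cfg$winter_temp, cfg$surface_temp_peak)
  )

  list(profiles = profiles, meteo = budget$met, hypsography = hyps,
       heat_series = budget$heat_series, truth = truth,
       truth_year = truth_year, config = cfg)
}

#' Generate daily meteorology with a closed surface heat budget
#'
#' Draws plausible daily meteorology (seasonal air temperature, humidity,
#' pressure, wind, cloud-modulated shortwave) and then *derives* the lake
#' heat-content series by integrating the package's own flux model with
#' the imposed longwave constant `a_true`, so the budget closes exactly by
#' construction. Optional multiplicative noise on the daily heat-content
#' increments emulates observation error.
#'
#' @param n_years number of years.
#' @param start_year first calendar year.
#' @param a_true imposed longwave calibration constant.
#' @param lake_area lake surface area (m^2).
#' @param seed RNG seed.
#' @param heat_noise_cv coefficient of variation of multiplicative noise on
#'   daily heat-content increments (0 = noise-free closure).
#' @param tsurf optional daily lake-surface temperature series (degC);
#'   default is a smooth seasonal cycle.
#' @param config a [pipeline_config()] list (albedo, emissivity, geometry).
#' @return list with `met` (daily meteorology tibble), `heat_series`
#'   (`date`, `heat_content_j`), `lake_area`, `a_true`.
#' @export
simulate_heat_budget <- function(n_years = 2, start_year = 2009,
                                 a_true = 1.02, lake_area = 66.6e6,
                                 seed = 1, heat_noise_cv = 0,
                                 tsurf = NULL,
                                 config = pipeline_config()) {
  set.seed(seed)
  days <- seq(as.Date(paste0(start_year, "-01-01")),
              as.Date(paste0(start_year + n_years - 1, "-12-31")), by = "day")
  doy <- as.numeric(format(days, "%j"))
  n <- length(days)
  tair <- 9.5 + 9 * cos(2 * pi * (doy - 205) / 365) + rnorm(n, 0, 1.5)
  if (is.null(tsurf)) {
    tsurf <- pmax(4.2, 9.5 + 8.5 * cos(2 * pi * (doy - 215) / 365)) +
      rnorm(n, 0, 0.2)
  }
  cloud <- stats::plogis(stats::filter(rnorm(n, 0, 1.2), 0.7,
                                       method = "recursive"))
  sw_clear <- clear_sky_radiation(days, config$latitude_deg,
                                  config$transmissivity)
  met <- tibble(
    date = days,
    tair_c = tair,
    rh_pct = pmin(100, pmax(30, 70 + rnorm(n, 0, 8))),
    pressure_hpa = 966 + rnorm(n, 0, 5),
    wind_ms = pmax(0.3, rnorm(n, 2.8, 1.2)),
    swdown_wm2 = sw_clear * (1 - 0.72 * as.numeric(cloud)),
    tsurf_c = tsurf
  )
  flux <- surface_fluxes(met, a = a_true, config = config)
  dh <- flux$q_net * 86400 * lake_area
  if (heat_noise_cv > 0) dh <- dh * rnorm(n, 1, heat_noise_cv)
  heat_series <- tibble(date = days,
                        heat_content_j = 2e17 + cumsum(dh))
  list(met = met, heat_series = heat_series, lake_area = lake_area,
       a_true = a_true)
}
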