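#' Depth-integrate a chlorophyll profile over the lake hypsography
#'
#' Each 1-m cell concentration (ug L^-1, identically mg m^-3) is multiplied
#' by the volume of its layer and summed: tons = sum(mg) / 1e9. Layer
#' membership in the 20-m strata is half-open `[top, bottom)`. Missing cells
#' contribute zero mass and are counted.
#'
#' @param chla chlorophyll concentration per 1-m cell (ug L^-1), indexed by
#'   the cell's top depth.
#' @param depth top depths of the cells (m).
#' @param hyps hypsography tibble with `layer_top_m`, `layer_bottom_m`,
#'   `volume_m3` (1-m layers).
#' @return list with `total_tons`, `strata` (tibble: `stratum`, `mass_tons`,
#'   `fraction`), and `n_missing`.
#' @export
depth_integrated_mass <- function(chla, depth = seq_along(chla) - 1, hyps) {
  idx <- match(hyps$layer_top_m, depth)
  if (anyNA(idx)) abort("profile grid does not cover the hypsography layers")
  conc <- chla[idx]
  n_missing <- sum(is.na(conc))
  conc[is.na(conc)] <- 0
  mass_mg <- conc * hyps$volume_m3              # mg m^-3 * m^3
  stratum_top <- 20 * (hyps$layer_top_m %/% 20)
  strata <- tibble(
    stratum = sprintf("%d-%d m", stratum_top, stratum_top + 20),
    stratum_top = stratum_top,
    mass_tons = mass_mg / 1e9
  ) %>%
    group_by(.data$stratum, .data$stratum_top) %>%
    summarise(mass_tons = sum(.data$mass_tons), .groups = "drop") %>%
    arrange(.data$stratum_top)
  total <- sum(strata$mass_tons)
  strata$fraction <- if (total > 0) strata$mass_tons / total else NA_real_
  list(total_tons = total, strata = strata, n_missing = n_missing)
}

#' Net population growth rate between two sampling dates
#'
#' mu = (ln B_t1 - ln B_t0) / (t1 - t0), with the time difference in days.
#'
#' @param b0,b1 whole-lake population mass on the two dates (metric tons),
#'   strictly positive.
#' @param t0,t1 the two dates (`Date` or date-time), `t1 > t0`.
#' @return net growth rate (day^-1).
#' @export
#' @examples
#' net_growth_rate(1, 2, as.Date("2020-06-01"), as.Date("2020-06-15"))
net_growth_rate <- function(b0, b1, t0, t1) {
  if (any(b0 <= 0 | b1 <= 0, na.rm = TRUE)) {
    abort("population mass must be positive; floor below-detection values first",
          class = "limnobloom_undefined_growth")
  }
  dt <- as.numeric(difftime(t1, t0, units = "days"))
  if (any(dt <= 0)) abort("t1 must be later than t0")
  (log(b1) - log(b0)) / dt
}

#' Depth of the chlorophyll maximum
#'
#' Ties are resolved toward the shallower depth. The result carries a
#' below-detection flag when the maximum concentration falls short of the
#' instrument detection limit; an all-zero (or all-missing) profile yields
#' `NA` with the flag set.
#'
#' @param chla chlorophyll profile (ug L^-1), ordered by increasing depth.
#' @param depth matching depths (m).
#' @param detection_limit instrument detection limit (ug L^-1).
#' @return list with `z_plankt` (m or NA) and `below_detection` (logical).
#' @export
chl_max_depth <- function(chla, depth = seq_along(chla) - 1,
                          detection_limit = 0.05) {
  ok <- !is.na(chla)
  if (!any(ok) || all(chla[ok] <= 0)) {
    return(list(z_plankt = NA_real_, below_detection = TRUE))
  }
  imax <- which.max(chla)    # first maximum = shallower tie-break
  list(z_plankt = depth[imax], below_detection = chla[imax] < detection_limit)
}

#' Label the population's growth regime
#'
#' `"metalimnetic"` when a valid metalimnion exists and the population
#' maximum sits at or below its upper boundary; `"mixed"` otherwise
#' (including winter profiles without a valid metalimnion).
#'
#' @param z_plankt depth of the chlorophyll maximum (m), vectorised.
#' @param metalimnion_valid logical, metalimnion validity per date.
#' @param metalimnion_upper upper metalimnion boundary (m).
#' @return character vector, `"mixed"` / `"metalimnetic"` (`NA` input gives
#'   `NA`).
#' @export
regime_label <- function(z_plankt, metalimnion_valid, metalimnion_upper) {
  out <- ifelse(
    !is.na(metalimnion_valid) & metalimnion_valid &
      !is.na(metalimnion_upper) & z_plankt >= metalimnion_upper,
    "metalimnetic", "mixed"
  )
  out[is.na(z_plankt)] <- NA_character_
  out
}

#' Whole-lake population series from chlorophyll profiles
#'
#' Depth-integrates the cyanobacterial chlorophyll channel of every profile
#' over the hypsography and locates the population maximum.
#'
#' @param profiles long tibble with `timestamp`, `depth_m`,
#'   `chla_plank_ugL`.
#' @param hyps hypsography tibble (see [depth_integrated_mass()]).
#' @param config a [pipeline_config()] list.
#' @return A tibble of class `population_series`, one row per profile:
#'   `timestamp`, `total_tons`, `z_plankt`, `below_detection`, plus a nested
#'   `strata` list column with the 20-m layer partition.
#' @export
population_series <- function(profiles, hyps, config = pipeline_config()) {
  profiles %>%
    group_by(.data$timestamp) %>%
    group_modify(function(p, key) {
      p <- arrange(p, .data$depth_m)
      m <- depth_integrated_mass(p$chla_plank_ugL, p$depth_m, hyps)
      mx <- chl_max_depth(p$chla_plank_ugL, p$depth_m,
                          config$detection_limit_chla)
      tibble(
        total_tons = m$total_tons,
        z_plankt = mx$z_plankt,
        below_detection = mx$below_detection,
        n_missing_cells = m$n_missing,
        strata = list(m$strata)
      )
    }) %>%
    ungroup() %>%
    structure(class = c("population_series", class(tibble())))
}

#' Net growth rates with regime labels for a population series
#'
#' Computes mu between consecutive sampling dates. Below-detection masses
#' are floored at the configured whole-lake detection mass so the log rate
#' stays defined; floored intervals are flagged. Each interval is labelled
#' by the regime at its start date.
#'
#' @param population a [population_series()] tibble.
#' @param stratification a [stratify_profiles()] tibble on the same dates.
#' @param config a [pipeline_config()] list.
#' @return tibble with `t0`, `t1`, `mu` (day^-1), `regime`, `floored`.
#' @export
growth_series <- function(population, stratification,
                          config = pipeline_config()) {
  floor_mass <- config$detection_limit_mass
  pop <- population %>%
    arrange(.data$timestamp) %>%
    left_join(
      stratification %>%
        select("timestamp", "metalimnion_valid", "metalimnion_upper"),
      by = "timestamp"
    ) %>%
    mutate(
      regime = regime_label(.data$z_plankt, .data$metalimnion_valid,
                            .data$metalimnion_upper),
      mass_floored = pmax(.data$total_tons, floor_mass)
    )
  n <- nrow(pop)
  if (n < 2L) return(tibble(t0 = pop$timestamp[0], t1 = pop$timestamp[0],
                            mu = numeric(0), regime = character(0),
                            floored = logical(0)))
  tibble(
    t0 = pop$timestamp[-n],
    t1 = pop$timestamp[-1],
    mu = net_growth_rate(pop$mass_floored[-n], pop$mass_floored[-1],
                         pop$timestamp[-n], pop$timestamp[-1]),
    regime = pop$regime[-n],
    floored = pop$total_tons[-n] < floor_mass | pop$total_tons[-1] < floor_mass
  )
}

#' Annual population extremes, survival and recovery ratios
#'
#' For each bloom year (labelled by the year of vernal deep mixing) the
#' vernal minimum is the lowest whole-lake mass inside the spring search
#' window; the following maximum is the highest mass between this minimum
#' and the next year's minimum. The survival ratio divides the vernal
#' minimum by the *preceding* year's maximum (fraction of the population
#' that survived winter mixing); the recovery ratio divides it by the
#' *following* maximum. Minima below the whole-lake detection floor are
#' floored and flagged.
#'
#' @param population a [population_series()] tibble.
#' @param config a [pipeline_config()] list (spring window, detection floor).
#' @return tibble with one row per bloom year: `bloom_year`, `vernal_min`,
#'   `min_date`, `following_max`, `survival_ratio`, `recovery_ratio`,
#'   `min_below_detection`.
#' @export
annual_extremes <- function(population, config = pipeline_config()) {
  pop <- arrange(population, .data$timestamp)
  dts <- as.Date(pop$timestamp)
  years <- sort(unique(lubridate::year(dts)))
  floor_mass <- config$detection_limit_mass

  mins <- purrr::map(years, function(y) {
    w0 <- as.Date(paste0(y, "-", config$vernal_window_start))
    w1 <- as.Date(paste0(y, "-", config$vernal_window_end))
    in_win <- dts >= w0 & dts <= w1
    if (!any(in_win)) return(NULL)
    i <- which(in_win)[which.min(pop$total_tons[in_win])]
    tibble(bloom_year = y, vernal_min = pop$total_tons[i], min_date = dts[i])
  }) %>% purrr::list_rbind()
  if (is.null(mins) || nrow(mins) < 2L) {
    return(tibble(bloom_year = integer(0), vernal_min = numeric(0),
                  min_date = as.Date(character(0)), following_max = numeric(0),
                  survival_ratio = numeric(0), recovery_ratio = numeric(0),
                  min_below_detection = logical(0)))
  }
  k <- nrow(mins)
  mins$following_max <- vapply(seq_len(k), function(j) {
    from <- mins$min_date[j]
    to <- if (j < k) mins$min_date[j + 1] else max(dts)
    max(pop$total_tons[dts >= from & dts <= to])
  }, numeric(1))
  mins %>%
    mutate(
      min_below_detection = .data$vernal_min < floor_mass,
      min_eff = pmax(.data$vernal_min, floor_mass),
      survival_ratio = .data$min_eff / lag(.data$following_max),
      recovery_ratio = .data$min_eff / .data$following_max
    ) %>%
    select(-"min_eff")
}

#' Congruence of the population depth with candidate physical depths
#'
#' Per-date deviation = comparison depth minus the depth of the
#' chlorophyll maximum; positive values mean the population maximum sits
#' shallower than the comparison depth. Missing inputs propagate as `NA`.
#'
#' @param population a [population_series()] tibble.
#' @param light a [summarize_light()] tibble.
#' @param stratification a [stratify_profiles()] tibble.
#' @return tibble with `timestamp`, `dev_z_buoy`, `dev_meta_lower`,
#'   `dev_z_eu` (m).
#' @export
congruence_series <- function(population, light, stratification) {
  population %>%
    select("timestamp", "z_plankt") %>%
    left_join(select(light, "timestamp", "z_buoy", "z_eu"), by = "timestamp") %>%
    left_join(select(stratification, "timestamp", "metalimnion_lower",
                     "metalimnion_valid"), by = "timestamp") %>%
    mutate(
      dev_z_buoy = .data$z_buoy - .data$z_plankt,
      dev_meta_lower = ifelse(.data$metalimnion_valid,
                              .data$metalimnion_lower - .data$z_plankt,
                              NA_real_),
      dev_z_eu = .data$z_eu - .data$z_plankt
    ) %>%
    select("timestamp", "dev_z_buoy", "dev_meta_lower", "dev_z_eu")
}
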