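.parse_timestamp <- function(x) {
  if (inherits(x, "Date") || inherits(x, "POSIXct")) return(x)
  out <- suppressWarnings(lubridate::ymd_hms(x, quiet = TRUE))
  if (all(is.na(out))) out <- suppressWarnings(lubridate::ymd(x, quiet = TRUE))
  if (all(is.na(out))) abort("timestamps are not ISO-8601")
  out
}

#' Read long-format profile, hypsography and meteorology CSV files
#'
#' The CSV dialect is fixed: comma separator, dot decimal, UTF-8, ISO-8601
#' timestamps, `#`-prefixed comment/header lines. Profile columns:
#' `timestamp, depth_m, temp_c, cond25_uScm, o2_mgL, chla_plank_ugL,
#' chla_euk_ugL, par_umol_m2_s`; hypsography: `layer_top_m, layer_bottom_m,
#' volume_m3`; meteorology: `date, tair_c, rh_pct, pressure_hpa, wind_ms,
#' swdown_wm2, tsurf_c`.
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_profiles <- function(path) {
  out <- as_tibble(utils::read.csv(path, comment.char = "#",
                                   fileEncoding = "UTF-8"))
  out$timestamp <- .parse_timestamp(out$timestamp)
  out
}

#' @rdname read_profiles
#' @export
read_hypsography <- function(path) {
  as_tibble(utils::read.csv(path, comment.char = "#", fileEncoding = "UTF-8"))
}

#' @rdname read_profiles
#' @export
read_meteo <- function(path) {
  out <- as_tibble(utils::read.csv(path, comment.char = "#",
                                   fileEncoding = "UTF-8"))
  out$date <- as.Date(out$date)
  out
}

#' Write a tibble as CSV with a provenance header block
#'
#' Prepends `#`-prefixed comment lines carrying the package version and,
#' when given, a configuration hash, so every output file records how it
#' was produced. Files written this way round-trip through the readers.
#'
#' @param x tibble to write.
#' @param path destination path.
#' @param config_hash optional configuration hash string.
#' @return `path`, invisibly.
#' @export
write_output_csv <- function(x, path, config_hash = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# limnobloom %s",
                     as.character(utils::packageVersion("limnobloom"))), con)
  if (!is.null(config_hash)) {
    writeLines(sprintf("# config_hash: %s", config_hash), con)
  }
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (inherits(x[[j]], "Date")) x[[j]] <- format(x[[j]], "%Y-%m-%d")
  }
  utils::write.csv(x, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Interpolate a raw downcast onto the 1-m analysis grid
#'
#' Duplicate depths are averaged per channel, then every channel is
#' linearly interpolated onto integer depths. No extrapolation: grid cells
#' above the shallowest or below the deepest measurement stay `NA`.
#' Channels with fewer than two valid samples are returned all-`NA`.
#'
#' @param raw long tibble with `timestamp`, `depth_m` and any numeric
#'   channels (irregular depths).
#' @param grid target depths (m).
#' @return tibble with one row per `timestamp` x grid depth.
#' @export
#' @examples
#' raw <- tibble::tibble(timestamp = as.Date("2020-06-01"),
#'                       depth_m = c(0, 10), temp_c = c(4, 14))
#' grid_profile(raw, grid = 0:10)
grid_profile <- function(raw, grid = 0:120) {
  channels <- setdiff(names(raw), c("timestamp", "depth_m"))
  raw %>%
    group_by(.data$timestamp) %>%
    group_modify(function(p, key) {
      out <- tibble(depth_m = grid)
      for (ch in channels) {
        d <- p %>%
          filter(!is.na(.data[[ch]])) %>%
          group_by(.data$depth_m) %>%
          summarise(v = mean(.data[[ch]]), .groups = "drop") %>%
          arrange(.data$depth_m)
        out[[ch]] <- if (nrow(d) < 2L) {
          NA_real_
        } else {
          approx(d$depth_m, d$v, xout = grid, rule = 1)$y
        }
      }
      out
    }) %>%
    ungroup()
}

#' Priority-merge two daily meteorology tables
#'
#' Rows and fields from the primary station win; dates absent from it, and
#' `NA` fields within shared dates, are filled from the fallback station.
#'
#' @param primary,fallback meteorology tibbles (see [read_profiles()]).
#' @return merged tibble sorted by date.
#' @export
merge_meteo <- function(primary, fallback) {
  all_dates <- sort(unique(c(primary$date, fallback$date)))
  out <- tibble(date = all_dates) %>%
    left_join(primary, by = "date") %>%
    left_join(fallback, by = "date", suffix = c("", ".fb"))
  for (v in setdiff(names(primary), "date")) {
    fb <- paste0(v, ".fb")
    if (fb %in% names(out)) {
      out[[v]] <- dplyr::coalesce(out[[v]], out[[fb]])
      out[[fb]] <- NULL
    }
  }
  out
}

#' Run the full analysis pipeline
#'
#' Gridding, stratification physics, light structure, population metrics,
#' growth and extremes, depth-congruence correlations, and (when
#' meteorology is supplied) the surface heat-flux budget with seasonal
#' anomalies and the population trend test. Profiles on which a step fails
#' are skipped and listed in the run summary rather than aborting the run.
#'
#' @param profiles long profile tibble (raw or already on the 1-m grid).
#' @param hyps hypsography tibble.
#' @param meteo optional daily meteorology tibble.
#' @param config a [pipeline_config()] list.
#' @param regrid interpolate onto the 1-m grid first (default `TRUE`).
#' @return A list of class `limnobloom_run`: `stratification`, `light`,
#'   `population`, `growth`, `extremes`, `congruence`, `correlations`,
#'   `fluxes`, `seasonal_anomalies`, `population_trend`, plus
#'   `config_hash` and `skipped` (dates dropped per step).
#' @export
run_pipeline <- function(profiles, hyps, meteo = NULL,
                         config = pipeline_config(), regrid = TRUE) {
  if (regrid) profiles <- grid_profile(profiles)
  dates_in <- unique(profiles$timestamp)

  strat <- stratify_profiles(profiles, config)
  light <- summarize_light(profiles, config)
  pop <- population_series(profiles, hyps, config)
  growth <- growth_series(pop, strat, config)
  extremes <- annual_extremes(pop, config)
  congr <- congruence_series(pop, light, strat)
  corr <- depth_correlations(pop, light, strat)

  fluxes <- NULL
  seasonal <- NULL
  if (!is.null(meteo)) {
    fluxes <- surface_fluxes(meteo, config = config)
    seasonal <- seasonal_climatology(
      tibble(date = fluxes$date, value = fluxes$q_net)
    )
  }
  pop_trend <- tryCatch(
    seasonal_mann_kendall(tibble(date = as.Date(pop$timestamp),
                                 value = pop$total_tons)),
    error = function(e) NULL
  )
  skipped <- list(
    stratification = setdiff(as.character(dates_in),
                             as.character(strat$timestamp)),
    light = as.character(light$timestamp[is.na(light$k_d)])
  )
  structure(list(
    stratification = strat, light = light, population = pop,
    growth = growth, extremes = extremes, congruence = congr,
    correlations = corr, fluxes = fluxes, seasonal_anomalies = seasonal,
    population_trend = pop_trend,
    config_hash = rlang::hash(config), skipped = skipped
  ), class = "limnobloom_run")
}

#' Write every table of a pipeline run to CSV
#'
#' @param run a [run_pipeline()] result.
#' @param outdir output directory (created if missing).
#' @return named character vector of the files written, invisibly.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  drop_lists <- function(x) x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  tabs <- list(
    stratification = drop_lists(run$stratification),
    light = run$light,
    population = drop_lists(run$population),
    growth = run$growth,
    extremes = run$extremes,
    congruence = run$congruence,
    correlations = run$correlations
  )
  if (!is.null(run$fluxes)) tabs$fluxes <- run$fluxes
  if (!is.null(run$seasonal_anomalies)) {
    tabs$seasonal_anomalies <- run$seasonal_anomalies
  }
  paths <- vapply(names(tabs), function(nm) {
    write_output_csv(tabs[[nm]], file.path(outdir, paste0(nm, ".csv")),
                     config_hash = run$config_hash)
  }, character(1))
  invisible(paths)
}
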