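#' Spearman rank correlation between two aligned series
#'
#' Thin wrapper over [stats::cor.test()] with `method = "spearman"`
#' (average ranks for ties, large-sample t approximation for the p value).
#' Incomplete pairs are dropped.
#'
#' @param x,y paired observations; pairs with `NA` are removed.
#' @param pair_label optional label for the variable pair.
#' @return tibble with `variable_pair`, `rho`, `p_value`, `n`.
#' @export
trend_spearman <- function(x, y, pair_label = NULL) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for constant input")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(
    variable_pair = pair_label %||% "x~y",
    rho = unname(ct$estimate),
    p_value = ct$p.value,
    n = length(x)
  )
}

# Kendall S and tie-corrected variance for one season's yearly values
.kendall_s <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < 2L) return(list(s = 0, var = 0, pairs = 0))
  s <- 0
  for (i in seq_len(n - 1L)) {
    s <- s + sum(sign(v[(i + 1L):n] - v[i]))
  }
  ties <- table(v)
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  list(s = s, var = var_s, pairs = n * (n - 1) / 2)
}

#' Seasonal Mann-Kendall trend test
#'
#' Computes the Mann-Kendall S statistic on the yearly values within each
#' seasonal block (default blocking: calendar month; multiple observations
#' within a season-year are averaged), sums S and its tie-corrected
#' variance across seasons, and reports tau = sum(S) / total pair count
#' with a two-sided p value from the continuity-corrected normal
#' approximation.
#'
#' @param series tibble with `date` and `value`.
#' @param season_of function mapping dates to a season label; default
#'   calendar month.
#' @return An object of class `smk_trend`: list with `tau`, `s`, `var_s`,
#'   `p_value`, `n_seasons`, `n_years`, `method = "smk"`.
#' @export
seasonal_mann_kendall <- function(series,
                                  season_of = function(d) lubridate::month(d)) {
  dat <- series %>%
    filter(!is.na(.data$value)) %>%
    mutate(season = season_of(.data$date),
           year = lubridate::year(.data$date)) %>%
    group_by(.data$season, .data$year) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  if (length(unique(dat$year)) < 2L) abort("need at least 2 years of data")
  per_season <- dat %>%
    group_by(.data$season) %>%
    group_map(function(g, key) .kendall_s(g$value[order(g$year)]))
  s_tot <- sum(vapply(per_season, `[[`, numeric(1), "s"))
  var_tot <- sum(vapply(per_season, `[[`, numeric(1), "var"))
  pairs_tot <- sum(vapply(per_season, `[[`, numeric(1), "pairs"))
  tau <- if (pairs_tot > 0) s_tot / pairs_tot else 0
  if (var_tot <= 0) {
    p <- 1
  } else {
    z <- (s_tot - sign(s_tot)) / sqrt(var_tot)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(tau = tau, s = s_tot, var_s = var_tot, p_value = p,
                 n_seasons = length(per_season),
                 n_years = length(unique(dat$year)), method = "smk"),
            class = "smk_trend")
}

#' Linear trend of annual values
#'
#' Ordinary least squares of value on year; slope, r-squared and the
#' two-sided p value of the slope.
#'
#' @param year numeric years (>= 3 distinct values).
#' @param value yearly values.
#' @return tibble with `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n_years`, `method = "ols"`.
#' @export
linear_trend <- function(year, value) {
  keep <- complete.cases(year, value)
  year <- year[keep]; value <- value[keep]
  if (length(year) < 3L) abort("need at least 3 years")
  if (sd(year) == 0) abort("year values are constant")
  fit <- lm(value ~ year)
  sm <- suppressWarnings(summary(fit))
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    n_years = length(year),
    method = "ols"
  )
}

#' Depth-congruence correlation table
#'
#' Spearman correlations of the population maximum depth against each
#' candidate physical depth (intrinsic irradiance depths, metalimnion
#' boundaries, euphotic depth, depth of maximal stratification), the
#' analysis behind the light-versus-stability question. Reported without
#' multiplicity adjustment; set `adjust = "holm"` to add adjusted p values.
#'
#' @param population a [population_series()] tibble.
#' @param light a [summarize_light()] tibble.
#' @param stratification a [stratify_profiles()] tibble.
#' @param adjust `"none"` (default) or a [stats::p.adjust()] method.
#' @return tibble of [trend_spearman()] rows, one per candidate depth.
#' @export
depth_correlations <- function(population, light, stratification,
                               adjust = "none") {
  strat <- stratification %>%
    mutate(
      z_n2max = .data$metalimnion_center,
      meta_upper = ifelse(.data$metalimnion_valid, .data$metalimnion_upper, NA_real_),
      meta_lower = ifelse(.data$metalimnion_valid, .data$metalimnion_lower, NA_real_)
    )
  joined <- population %>%
    select("timestamp", "z_plankt") %>%
    left_join(select(light, "timestamp", "z_comp", "z_buoy", "z_sat", "z_eu"),
              by = "timestamp") %>%
    left_join(select(strat, "timestamp", "meta_upper", "meta_lower", "z_n2max"),
              by = "timestamp")
  vars <- c("z_comp", "z_buoy", "z_sat", "z_eu", "meta_upper", "meta_lower",
            "z_n2max")
  out <- purrr::map(vars, function(v) {
    keep <- complete.cases(joined$z_plankt, joined[[v]])
    if (sum(keep) < 3L) return(NULL)
    trend_spearman(joined$z_plankt[keep], joined[[v]][keep],
                   pair_label = paste0("z_plankt~", v))
  }) %>% purrr::list_rbind()
  if (adjust != "none" && nrow(out) > 0) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  }
  out
}
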