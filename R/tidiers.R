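#' Tidy / glance methods for fitted objects
#'
#' `kd_fit` (PAR attenuation fit), `smk_trend` (seasonal Mann-Kendall) and
#' `lw_calibration` (longwave constant fit) follow the broom convention:
#' `tidy()` returns one row per estimated quantity, `glance()` a one-row
#' model summary.
#'
#' @param x a fitted object.
#' @param ... unused.
#' @return a tibble.
#' @name limnobloom-tidiers
NULL

#' @rdname limnobloom-tidiers
#' @exportS3Method generics::tidy
tidy.kd_fit <- function(x, ...) {
  tibble(term = c("k_d", "z_eu"),
         estimate = c(x$k_d, euphotic_depth(x$k_d)))
}

#' @rdname limnobloom-tidiers
#' @exportS3Method generics::glance
glance.kd_fit <- function(x, ...) {
  tibble(r.squared = x$fit_r2, fit_top = x$fit_top,
         fit_bottom = x$fit_bottom, nobs = x$n_fit)
}

#' @rdname limnobloom-tidiers
#' @exportS3Method generics::tidy
tidy.smk_trend <- function(x, ...) {
  tibble(term = "tau", estimate = x$tau, statistic = x$s,
         p.value = x$p_value)
}

#' @rdname limnobloom-tidiers
#' @exportS3Method generics::glance
glance.smk_trend <- function(x, ...) {
  tibble(tau = x$tau, s = x$s, var_s = x$var_s, p.value = x$p_value,
         n_seasons = x$n_seasons, n_years = x$n_years, method = x$method)
}

#' @rdname limnobloom-tidiers
#' @exportS3Method generics::tidy
tidy.lw_calibration <- function(x, ...) {
  tibble(term = "a", estimate = x$a)
}

#' @rdname limnobloom-tidiers
#' @exportS3Method generics::glance
glance.lw_calibration <- function(x, ...) {
  tibble(a = x$a, nobs = x$n_obs, rmse_j = x$rmse_j)
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("PAR attenuation fit: k_d = %.4f m^-1 (R^2 = %.4f, %g-%g m, n = %d)\n",
              x$k_d, x$fit_r2, x$fit_top, x$fit_bottom, x$n_fit))
  invisible(x)
}

#' @export
print.smk_trend <- function(x, ...) {
  cat(sprintf("Seasonal Mann-Kendall: tau = %.3f (S = %g, p = %.4g, %d seasons x %d years)\n",
              x$tau, x$s, x$p_value, x$n_seasons, x$n_years))
  invisible(x)
}

#' @export
print.lw_calibration <- function(x, ...) {
  cat(sprintf("Longwave calibration: a = %.4f (n = %d, RMSE = %.3g J)\n",
              x$a, x$n_obs, x$rmse_j))
  invisible(x)
}
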