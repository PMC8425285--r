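# fixtures built in code, shared across test files

# exponential PAR profile on a 1-m grid
exp_par <- function(e0 = 600, k = 0.4605, zmax = 20) {
  e0 * exp(-k * (0:zmax))
}

# cylinder hypsography: equal 1-m layer volumes summing to total
cylinder_hyps <- function(total = 1.2e9, zmax = 120) {
  tibble::tibble(
    layer_top_m = 0:(zmax - 1),
    layer_bottom_m = 1:zmax,
    volume_m3 = total / zmax
  )
}

# small synthetic scenario reused by several test files (2 years is enough
# for structural checks; the full 12-year run lives in the acceptance tests)
scenario_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_lake_scenario(scenario_config(n_years = 2), seed = 11)
    }
    cache
  }
})
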