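Package: limnobloom
Title: Metalimnetic Cyanobacterial Bloom Dynamics from Lake Monitoring Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive the seasonal dynamics of deep-dwelling
    cyanobacteria (Planktothrix rubescens and similar metalimnetic taxa)
    from multiparameter lake profiles. Converts temperature/conductivity
    casts into potential density, buoyancy frequency, mixed-layer depth
    and a detected metalimnion; fits the attenuation coefficient of
    downwelling PAR and locates the species-intrinsic irradiance depths
    (compensation, neutral-buoyancy and saturation); integrates
    class-resolved chlorophyll profiles over the lake hypsography into
    whole-lake population mass, net growth rates, overwinter survival and
    recovery ratios; computes a calibrated bulk surface heat-flux budget
    with seasonal anomalies; and tests monotonic trends with a seasonal
    Mann-Kendall statistic. A synthetic-lake generator with known ground
    truth exercises the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
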