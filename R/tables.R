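#' Morphometrics of the 14 study species
#'
#' Body mass, wingspan and wing area for the 14 bird species carrying
#' back-mounted biologgers, as compiled from direct measurements and the
#' literature. Wing loading and residual wing loading (the species' residual
#' from the log-log regression of wing loading on body mass) are computed on
#' the fly.
#'
#' @return Data frame: `species`, `n_individuals`, `mass_g`, `wingspan_m`,
#'   `wing_area_m2`, `wing_loading` (g per m^2 as tabulated; the residual is
#'   unit-invariant), `residual_wing_loading`.
#' @export
morphometrics_table <- function() {
  d <- data.frame(
    species = c("Brunnich's guillemot", "common guillemot", "northern fulmar",
                "pigeon", "red-tailed tropicbird", "great frigatebird",
                "black-legged kittiwake", "imperial cormorant",
                "western barn owl", "grey-headed albatross",
                "wandering albatross", "streaked shearwater", "dunlin",
                "northern gannet"),
    n_individuals = c(13L, 6L, 3L, 9L, 10L, 3L, 3L, 5L, 10L, 5L, 6L, 5L, 1L, 10L),
    mass_g = c(949, 1050, 778, 456, 820, 1113, 387, 2400, 296, 3290, 8500,
               503, 55, 2856),
    wingspan_m = c(0.727, 0.73, 1.12, 0.647, 1.115, 2.084, 0.965, 1.13,
                   0.936, 2.186, 3.01, 1.119, 0.334, 1.85),
    wing_area_m2 = c(0.069, 0.056, 0.106, 0.064, 0.117, 0.365, 0.101, 0.183,
                     0.134, 0.348, 0.583, 0.126, 0.014, 0.262)
  )
  d$mass <- d$mass_g
  d$wing_area <- d$wing_area_m2
  d <- residual_wing_loading(d)
  d$mass <- NULL
  d$wing_area <- NULL
  d
}

#' Species-level wingbeat kinematics summaries
#'
#' Per-species summaries of the amplitude-frequency analysis for the 14
#' species flying in the wild and the two wind-tunnel datasets: mean and
#' standard deviation of heave (signal) amplitude and wingbeat frequency, the
#' OLS slope/intercept/p/R-squared of amplitude on frequency, and the total
#' number of wingbeats analysed. The printed p-values "<0.001" are stored as
#' 0.001 upper bounds.
#'
#' @return Data frame with columns `species`, `setting` ("wild" or
#'   "wind_tunnel"), `amp_mean_g`, `amp_sd_g`, `freq_mean_hz`, `freq_sd_hz`,
#'   `slope`, `intercept`, `p_value`, `r_squared`, `total_wingbeats`,
#'   `cv_frequency`.
#' @export
kinematics_summary_table <- function() {
  d <- data.frame(
    species = c("dunlin", "pigeon", "pigeon", "western barn owl",
                "common guillemot", "Brunnich's guillemot",
                "imperial cormorant", "red-tailed tropicbird",
                "black-legged kittiwake", "great frigatebird",
                "streaked shearwater", "northern fulmar",
                "grey-headed albatross", "wandering albatross",
                "northern gannet"),
    setting = c("wind_tunnel", "wind_tunnel", "wild", "wild", "wild", "wild",
                "wild", "wild", "wild", "wild", "wild", "wild", "wild",
                "wild", "wild"),
    amp_mean_g = c(3.2, 6.0, 3.7, 2.4, 2.5, 1.3, 1.1, 1.8, 2.0, 1.7, 1.4,
                   1.3, 1.4, 1.1, 2.5),
    amp_sd_g = c(0.3, 0.7, 0.4, 0.4, 0.3, 0.2, 0.2, 0.3, 0.4, 0.3, 0.1, 0.1,
                 0.1, 0.1, 0.6),
    freq_mean_hz = c(13.2, 6.7, 5.2, 4.4, 9.7, 7.7, 5.7, 4.0, 4.0, 2.6, 4.1,
                     4.7, 3.1, 2.8, 3.9),
    freq_sd_hz = c(0.9, 0.4, 0.5, 0.4, 0.6, 0.5, 0.2, 0.3, 0.2, 0.2, 0.3,
                   0.3, 0.2, 0.2, 0.3),
    slope = c(0.110, 0.893, 0.189, 0.518, 0.206, 0.180, 0.190, 0.527, 0.998,
              0.757, 0.018, -0.003, 0.016, 0.043, 0.489),
    intercept = c(1.833, 1.337, 2.713, 0.531, 0.541, -0.076, 0.044, -0.341,
                  -1.915, -0.213, 1.315, 1.354, 1.325, 0.952, 0.632),
    p_value = c(0.001, 0.001, 0.001, 0.001, 0.001, 0.001, 0.001, 0.001,
                0.001, 0.001, 0.001, 0.437, 0.500, 0.207, 0.001),
    r_squared = c(0.11, 0.309, 0.048, 0.162, 0.170, 0.195, 0.062, 0.151,
                  0.383, 0.256, 0.001, 0.000, -0.001, 0.001, 0.051),
    total_wingbeats = c(273L, 147L, 4858L, 134919L, 31349L, 122598L, 11068L,
                        174190L, 21767L, 2805L, 18036L, 8505L, 590L, 533L,
                        15410L)
  )
  d$cv_frequency <- d$freq_sd_hz / d$freq_mean_hz
  d
}

#' Correlation of wingbeat-frequency CV with morphology across species
#'
#' Reconstructs the species-level analysis from the bundled summary tables:
#' per-species coefficients of variation of wingbeat frequency (sd/mean from
#' [kinematics_summary_table()]) are correlated (Pearson) with a predictor
#' from [morphometrics_table()]. Wild datasets are used, plus the wind-tunnel
#' dunlin (its only dataset); for the pigeon, which has both, `pigeon`
#' selects which dataset supplies the CV ("wild" by default, matching how the
#' original analysis was described).
#'
#' Note the published correlation was computed from the underlying per-bird
#' data; reconstructing CVs from summary columns rounded to one decimal
#' perturbs the coefficient appreciably (the pigeon row alone moves it by
#' ~0.15), so this function reproduces the analysis, not its third decimal.
#'
#' @param predictor Morphological predictor: `"residual_wing_loading"`
#'   (default), `"mass_g"` or `"wingspan_m"`.
#' @param pigeon Which pigeon dataset supplies the pigeon CV: `"wild"` or
#'   `"wind_tunnel"`.
#' @return A `wb_cor` object (see [correlate_cv_morphology()]).
#' @examples
#' cv_wing_loading_correlation()
#' @export
cv_wing_loading_correlation <- function(predictor = "residual_wing_loading",
                                        pigeon = c("wild", "wind_tunnel")) {
  pigeon <- match.arg(pigeon)
  k <- kinematics_summary_table()
  keep <- k$setting == "wild" |
    (k$species == "dunlin" & k$setting == "wind_tunnel")
  if (pigeon == "wind_tunnel") {
    keep <- (k$setting == "wild" & k$species != "pigeon") |
      (k$setting == "wind_tunnel" & k$species %in% c("dunlin", "pigeon"))
  }
  k <- k[keep, , drop = FALSE]
  correlate_cv_morphology(k[, c("species", "cv_frequency")],
                          morphometrics_table(), predictor = predictor)
}
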