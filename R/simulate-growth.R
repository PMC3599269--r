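#' Simulate a microbial growth curve
#'
#' Three-phase model sampled every `dt_min` minutes for `t_max_min`
#' minutes: a flat baseline until `lag_min`, exponential growth of the
#' baseline-subtracted signal with the given doubling time, and saturation
#' at `baseline_od + efficiency_od`.  The signal is
#' `S(t) = f * (exp(mu * (t - lag)) - 1)` with `f = floor_frac *
#' efficiency_od` and `mu = log(2) / doubling_min`, capped at
#' `efficiency_od`, so that `log(S + f)` is exactly linear with slope `mu`
#' during the exponential phase (the convention [extract_growth()]
#' inverts).  Gaussian noise of standard deviation `noise_sd` is added to
#' every reading.
#'
#' @param lag_min Lag (adaptation) time in minutes.
#' @param doubling_min Doubling time of the signal in minutes.
#' @param efficiency_od Total density change (max OD minus baseline).
#' @param noise_sd Gaussian noise standard deviation (OD units).
#' @param rng_seed Integer seed.
#' @param baseline_od Optical density before growth.
#' @param floor_frac Effective inoculum signal as a fraction of
#'   `efficiency_od`; the default 0.1 matches high-density yeast
#'   phenotyping (initial OD near 0.1 against a density change near 1).
#' @param t_max_min Total cultivation time (default 72 h).
#' @param dt_min Sampling interval (default 20 min).
#' @return A data.frame with columns `time_min` and `od`.
#' @export
#' @examples
#' gc <- simulate_growth_curve(120, 90, 1.0, noise_sd = 0)
#' range(gc$od)
simulate_growth_curve <- function(lag_min, doubling_min, efficiency_od,
                                  noise_sd = 0, rng_seed = 1L,
                                  baseline_od = 0.1, floor_frac = 0.1,
                                  t_max_min = 4320, dt_min = 20) {
  stopifnot(lag_min >= 0, doubling_min > 0, efficiency_od > 0)
  set.seed(rng_seed)
  t <- seq(0, t_max_min, by = dt_min)
  mu <- log(2) / doubling_min
  f <- floor_frac * efficiency_od
  s <- ifelse(t <= lag_min, 0,
              pmin(f * (exp(mu * (t - lag_min)) - 1), efficiency_od))
  od <- baseline_od + s
  if (noise_sd > 0) od <- od + rnorm(length(t), 0, noise_sd)
  data.frame(time_min = t, od = od)
}
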