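#' Default saliva sampling clocks (minutes from arrival)
#'
#' Protocol-shaped sampling times. The OMC group has a longer S0-S1 interval
#' (changing + 20-30 min marker application + questionnaire) than controls,
#' who proceed directly to walking; S4 = S3 + 15 min, S5 = S4 + 10 min for
#' both groups.
#'
#' @param group `"OMC"` or `"control"`.
#' @return Named numeric vector of six times, minutes.
#' @export
default_sample_clock <- function(group = c("OMC", "control")) {
  group <- match.arg(group)
  if (group == "OMC") c(S0 = 0, S1 = 40, S2 = 47, S3 = 54, S4 = 69, S5 = 79)
  else c(S0 = 0, S1 = 12, S2 = 19, S3 = 26, S4 = 41, S5 = 51)
}

# Gamma-shaped unit pulse: 0 before onset, peaks at exactly 1 at
# `peak_delay` minutes after onset, exponential-like tail with time constant
# ~`decay` minutes.
cortisol_pulse <- function(t_min, onset, peak_delay, decay) {
  s <- peak_delay / decay
  u <- pmax(t_min - onset, 0) / peak_delay
  ifelse(u > 0, u^s * exp(s * (1 - u)), 0)
}

#' Simulate a salivary cortisol series
#'
#' Response curve: baseline plus a gamma-shaped pulse that starts at `onset`,
#' peaks (at height `amplitude`) `peak_delay` minutes later -- matching the
#' delayed HPA-axis response of roughly 15-20 min -- and decays with time
#' constant `decay`. The curve is evaluated at the six protocol sample times;
#' optional lognormal measurement noise multiplies each sample. Negative
#' values (impossible here unless noise is misused) would be clipped at 0.
#'
#' @param baseline Baseline concentration, nmol/L (> 0).
#' @param amplitude Peak increase over baseline, nmol/L (>= 0).
#' @param onset Stress onset, minutes from arrival.
#' @param peak_delay Minutes from onset to peak (default 17, in 15--20).
#' @param decay Tail time constant, minutes (default 25).
#' @param sample_clock Named vector of six sample times
#'   (default [default_sample_clock()] for `group`).
#' @param noise_cv Lognormal measurement noise coefficient of variation
#'   (default 0 = noiseless).
#' @param group,participant_id Metadata labels.
#' @return A list: `series` ([cortisol_series]), `truth` (generating
#'   parameters plus the continuous-curve maximum increase and the responder
#'   flag implied by the sampled values at threshold 1.5 nmol/L).
#' @export
simulate_cortisol <- function(baseline, amplitude, onset = 10, peak_delay = 17,
                              decay = 25, sample_clock = NULL, noise_cv = 0,
                              group = "OMC", participant_id = "P00") {
  stopifnot(baseline > 0, amplitude >= 0)
  if (is.null(sample_clock)) sample_clock <- default_sample_clock(group)
  conc <- baseline + amplitude * cortisol_pulse(sample_clock, onset, peak_delay, decay)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    conc <- conc * stats::rlnorm(length(conc), -sdlog^2 / 2, sdlog)
  }
  if (any(conc < 0)) { warning("negative concentration clipped at 0"); conc <- pmax(conc, 0) }
  ser <- cortisol_series(stats::setNames(conc, names(sample_clock)), sample_clock,
                         group = group, participant_id = participant_id)
  truth <- list(baseline = baseline, amplitude = amplitude, onset = onset,
                peak_delay = peak_delay, decay = decay,
                sampled_max_increase = max(conc[-1] - conc[[1]]),
                responder = max(conc[-1] - conc[[1]]) > 1.5)
  list(series = ser, truth = truth)
}

#' Simulate Likert questionnaire responses
#'
#' Item responses are drawn around a latent subscale mean: response =
#' `round(mean + N(0, item_sd))` clipped to 1..5.
#'
#' @param instrument `"PANAS"` or `"SSSQ"`.
#' @param subscale_means Named numeric vector of latent means on the 1--5
#'   scale, one per subscale of the instrument's key.
#' @param item_sd Latent item noise SD (default 0.7).
#' @param key Scoring key (defaults to the instrument's shipped key).
#' @param timepoint,group,participant_id Metadata labels.
#' @return A [questionnaire_response].
#' @export
simulate_questionnaire <- function(instrument, subscale_means, item_sd = 0.7,
                                   key = NULL, timepoint = "Q-pre",
                                   group = "OMC", participant_id = "P00") {
  if (is.null(key)) key <- if (instrument == "PANAS") panas_key() else sssq_key()
  mu <- subscale_means[key$subscale]
  if (anyNA(mu)) stop("subscale_means must name every subscale in the key",
                      call. = FALSE)
  r <- round(mu + stats::rnorm(nrow(key), 0, item_sd))
  r <- pmin(pmax(r, 1), 5)
  items <- integer(nrow(key)); items[key$index] <- ifelse(key$reverse, 6L - r, r)
  questionnaire_response(items, instrument = instrument, timepoint = timepoint,
                         group = group, participant_id = participant_id)
}
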