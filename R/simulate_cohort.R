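#' Default cohort effect specification
#'
#' Generating parameters for [simulate_cohort()], chosen to emulate the study
#' conditions: two groups walking two 4-minute treadmill bouts (slow/fast),
#' six saliva samples, questionnaires at Q-pre/Q-post (plus Q-marker for the
#' OMC group only). Cortisol pulses are larger and more variable in the OMC
#' group; stride-to-stride waveform jitter is slightly larger for controls
#' (looser clothing); marker application raises negative and lowers positive
#' affect at Q-marker. All values are overridable.
#'
#' @return A nested list of generating parameters.
#' @export
default_cohort_effects <- function() {
  list(
    stride_time_mean = c(slow = 1.25, fast = 1.10),
    stride_time_sd = 0.06,
    stride_jitter_sd = c(OMC = 0.025, control = 0.035),
    clothing_bias = list(OMC = list(), control = list()),
    cortisol = list(
      baseline_meanlog = log(3), baseline_sdlog = 0.35,
      amplitude_mean = c(OMC = 1.6, control = 0.7),
      amplitude_sd = c(OMC = 1.8, control = 0.8),
      onset = c(OMC = 10, control = 8), noise_cv = 0.08),
    panas_means = list(  # positive, negative latent means per timepoint
      `Q-pre` = c(positive = 3.1, negative = 1.4),
      `Q-marker` = c(positive = 2.5, negative = 2.1),
      `Q-post` = c(positive = 3.0, negative = 1.2)),
    sssq_means = list(
      `Q-pre` = c(distress = 1.8, worry = 2.2, confidence = 3.5,
                  negative_affect = 1.6, motivation = 3.3, self_evaluation = 3.4),
      `Q-marker` = c(distress = 1.9, worry = 2.0, confidence = 3.4,
                     negative_affect = 1.8, motivation = 3.2, self_evaluation = 3.2),
      `Q-post` = c(distress = 1.6, worry = 1.9, confidence = 3.5,
                   negative_affect = 1.5, motivation = 3.3, self_evaluation = 3.0)),
    item_sd = 0.7)
}

#' Simulate a full study cohort
#'
#' Generates, per participant: two walker runs (slow and fast bout), one
#' cortisol series, and questionnaire responses at Q-pre and Q-post (plus
#' Q-marker for the OMC group, as in the protocol). All generating quantities
#' are recorded in `truth`.
#'
#' @param n_per_group Named vector `c(OMC=, control=)` or a single number for
#'   both groups (default `c(OMC = 19, control = 20)`).
#' @param duration Bout duration in seconds (default 240).
#' @param noise_sd Keypoint noise SD in pixels (default 2).
#' @param effects Generating parameters; defaults from
#'   [default_cohort_effects()], partially overridable (top-level names).
#' @param seed RNG seed (all randomness derives from it).
#' @return A list of class `cohort`: `participants` (each with `id`, `group`,
#'   `bouts` (slow/fast walker outputs), `cortisol`, `questionnaires`),
#'   `truth` (per-participant generating values), `effects`, `seed`.
#' @export
simulate_cohort <- function(n_per_group = c(OMC = 19, control = 20),
                            duration = 240, noise_sd = 2, effects = list(),
                            seed = 1) {
  if (length(n_per_group) == 1 && is.null(names(n_per_group)))
    n_per_group <- c(OMC = n_per_group, control = n_per_group)
  stopifnot(all(n_per_group >= 2))
  eff <- utils::modifyList(default_cohort_effects(), effects)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  groups <- rep(names(n_per_group), n_per_group)
  ids <- sprintf("P%02d", seq_along(groups))
  participants <- vector("list", length(ids))
  truth <- vector("list", length(ids))

  for (i in seq_along(ids)) {
    g <- groups[i]
    st <- stats::rnorm(2, eff$stride_time_mean, eff$stride_time_sd)
    st <- pmin(pmax(st, 0.8), 1.8)
    wseeds <- sample.int(2^30, 2)
    bouts <- list()
    for (b in 1:2) {
      bn <- c("slow", "fast")[b]
      wp <- walker_params(stride_time = st[b], duration = duration,
                          noise_sd = noise_sd,
                          stride_jitter_sd = unname(eff$stride_jitter_sd[g]),
                          clothing_bias = eff$clothing_bias[[g]],
                          seed = wseeds[b])
      bouts[[bn]] <- simulate_walker(wp, participant_id = ids[i], bout = bn)
    }
    co <- eff$cortisol
    amp <- max(0, stats::rnorm(1, co$amplitude_mean[[g]], co$amplitude_sd[[g]]))
    base <- stats::rlnorm(1, co$baseline_meanlog, co$baseline_sdlog)
    cort <- simulate_cortisol(base, amp, onset = co$onset[[g]],
                              noise_cv = co$noise_cv, group = g,
                              participant_id = ids[i])
    tps <- if (g == "OMC") c("Q-pre", "Q-marker", "Q-post") else c("Q-pre", "Q-post")
    qs <- list()
    for (tp in tps) {
      qs[[paste0("PANAS.", tp)]] <- simulate_questionnaire(
        "PANAS", eff$panas_means[[tp]], item_sd = eff$item_sd,
        timepoint = tp, group = g, participant_id = ids[i])
      qs[[paste0("SSSQ.", tp)]] <- simulate_questionnaire(
        "SSSQ", eff$sssq_means[[tp]], item_sd = eff$item_sd,
        timepoint = tp, group = g, participant_id = ids[i])
    }
    participants[[i]] <- list(id = ids[i], group = g, bouts = bouts,
                              cortisol = cort$series, questionnaires = qs)
    truth[[i]] <- list(id = ids[i], group = g, stride_times = st,
                       walker_truth = lapply(bouts, `[[`, "truth"),
                       cortisol = cort$truth)
  }
  names(participants) <- names(truth) <- ids
  structure(list(participants = participants, truth = truth, effects = eff,
                 seed = seed, n_per_group = n_per_group),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %s participants (%s), seed %d\n",
              length(x$participants),
              paste(names(x$n_per_group), x$n_per_group, collapse = ", ", sep = "="),
              x$seed))
  invisible(x)
}
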