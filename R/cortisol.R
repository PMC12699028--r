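#' Salivary cortisol sample series
#'
#' Six timed saliva samples per participant: S0 at arrival (baseline), S1-S3
#' around the walking bouts, S4 and S5 during recovery.
#'
#' @param concentrations Named numeric vector of six concentrations in nmol/L,
#'   names `S0`..`S5` (canonical order enforced).
#' @param clock_min Minutes from arrival for each sample, strictly increasing.
#' @param group Group label, `"OMC"` or `"control"`.
#' @param participant_id Participant label.
#' @return An object of class `cortisol_series`.
#' @export
cortisol_series <- function(concentrations, clock_min, group = c("OMC", "control"),
                            participant_id = "P00") {
  group <- match.arg(group)
  ids <- paste0("S", 0:5)
  if (is.null(names(concentrations)) || !setequal(names(concentrations), ids))
    stop("exactly six samples S0-S5 required", call. = FALSE)
  concentrations <- concentrations[ids]
  if (length(clock_min) != 6 || any(diff(clock_min) <= 0))
    stop("clock_min must be six strictly increasing times", call. = FALSE)
  if (any(concentrations < 0) || any(!is.finite(concentrations)))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  structure(list(concentrations = concentrations, clock_min = clock_min,
                 group = group, participant_id = participant_id),
            class = "cortisol_series")
}

#' @export
print.cortisol_series <- function(x, ...) {
  cat(sprintf("<cortisol_series> %s (%s): S0=%.2f nmol/L, max increase %.2f\n",
              x$participant_id, x$group, x$concentrations[["S0"]],
              max(x$concentrations[-1] - x$concentrations[["S0"]])))
  invisible(x)
}

#' Cortisol response features and responder classification
#'
#' Baseline-adjusts samples S1-S5 by subtracting S0, computes the maximum
#' increase over baseline (absolute and as a percentage of S0), and classifies
#' the participant as a cortisol responder when the maximum increase strictly
#' exceeds `responder_threshold` (default 1.5 nmol/L).
#'
#' @param series A [cortisol_series].
#' @param responder_threshold Responder cut-off in nmol/L (default 1.5).
#' @return A list of class `cortisol_features`: `adjusted` (named S1-S5,
#'   nmol/L), `max_increase`, `max_increase_pct` (NA when S0 = 0),
#'   `responder`, plus group/participant metadata.
#' @export
cortisol_features <- function(series, responder_threshold = 1.5) {
  conc <- series$concentrations
  s0 <- conc[["S0"]]
  adjusted <- conc[paste0("S", 1:5)] - s0
  max_inc <- max(adjusted)
  structure(list(
    participant_id = series$participant_id, group = series$group,
    adjusted = adjusted, max_increase = max_inc,
    max_increase_pct = if (s0 > 0) 100 * max_inc / s0 else NA_real_,
    responder = max_inc > responder_threshold,
    responder_threshold = responder_threshold),
    class = "cortisol_features")
}

#' @export
print.cortisol_features <- function(x, ...) {
  cat(sprintf("<cortisol_features> %s (%s): max increase %.2f nmol/L (%s%%), %s\n",
              x$participant_id, x$group, x$max_increase,
              if (is.na(x$max_increase_pct)) "NA" else sprintf("%.0f", x$max_increase_pct),
              if (x$responder) "responder" else "non-responder"))
  invisible(x)
}

#' Read a cortisol CSV
#'
#' Columns: `participant,group,sample_id,clock_min,nmol_per_l`.
#'
#' @param path File path.
#' @return A list of [cortisol_series], one per participant.
#' @export
read_cortisol <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "group", "sample_id", "clock_min", "nmol_per_l")
  if (!all(need %in% names(d)))
    stop("cortisol CSV parse error: need columns ", paste(need, collapse = ","),
         call. = FALSE)
  lapply(split(d, d$participant), function(sub) {
    sub <- sub[order(sub$clock_min), ]
    cortisol_series(stats::setNames(sub$nmol_per_l, sub$sample_id),
                    sub$clock_min, group = sub$group[1],
                    participant_id = sub$participant[1])
  })
}

#' Write a cortisol CSV for a list of series
#' @param series_list List of [cortisol_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cortisol <- function(series_list, path) {
  rows <- lapply(series_list, function(s) data.frame(
    participant = s$participant_id, group = s$group,
    sample_id = names(s$concentrations), clock_min = s$clock_min,
    nmol_per_l = unname(s$concentrations), stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
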