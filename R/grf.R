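#' Vertical ground-reaction-force series
#'
#' Treadmill force traces for the left and right belt, sampled at `sample_rate`
#' Hz (study condition: 1000 Hz). Used only as an independent oracle for heel
#' strikes; belt crossover artifacts are flagged, not corrected.
#'
#' @param f_left,f_right Numeric vectors of vertical force in newtons.
#' @param sample_rate Samples per second (default 1000).
#' @param participant_id,bout Metadata labels.
#' @return An object of class `grf_series`.
#' @export
grf_series <- function(f_left, f_right, sample_rate = 1000,
                       participant_id = "P00", bout = "slow") {
  if (length(f_left) != length(f_right))
    stop("belt traces must have equal length", call. = FALSE)
  if (!isTRUE(sample_rate > 0)) stop("sample_rate must be positive", call. = FALSE)
  if (any(!is.finite(f_left)) || any(!is.finite(f_right)))
    stop("non-finite force values", call. = FALSE)
  structure(list(f_left = f_left, f_right = f_right, sample_rate = sample_rate,
                 participant_id = participant_id, bout = bout),
            class = "grf_series")
}

#' @export
print.grf_series <- function(x, ...) {
  cat(sprintf("<grf_series> %s/%s: %d samples @ %g Hz (%.1f s)\n",
              x$participant_id, x$bout, length(x$f_left), x$sample_rate,
              length(x$f_left) / x$sample_rate))
  invisible(x)
}

#' Read a GRF CSV (columns time_s, f_left_n, f_right_n)
#' @param path File path.
#' @param participant_id,bout Metadata labels.
#' @return A [grf_series]; the sample rate is inferred from the time column.
#' @export
read_grf <- function(path, participant_id = "P00", bout = "slow") {
  d <- utils::read.csv(path)
  need <- c("time_s", "f_left_n", "f_right_n")
  if (!all(need %in% names(d)))
    stop("GRF CSV parse error: need columns ", paste(need, collapse = ","), call. = FALSE)
  dt <- stats::median(diff(d$time_s))
  grf_series(d$f_left_n, d$f_right_n, sample_rate = 1 / dt,
             participant_id = participant_id, bout = bout)
}

#' Write a GRF CSV
#' @param grf A [grf_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grf <- function(grf, path) {
  n <- length(grf$f_left)
  d <- data.frame(time_s = (seq_len(n) - 1) / grf$sample_rate,
                  f_left_n = grf$f_left, f_right_n = grf$f_right)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
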