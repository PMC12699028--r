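#' Questionnaire response container
#'
#' Ordered 5-point Likert item responses for one participant at one timepoint.
#' PANAS has 20 items (10 positive affect, 10 negative affect); the SSSQ has
#' 24 items over six dimensions.
#'
#' @param items Integer vector of responses in 1..5 (length 20 for PANAS,
#'   24 for SSSQ).
#' @param instrument `"PANAS"` or `"SSSQ"`.
#' @param timepoint `"Q-pre"`, `"Q-marker"` or `"Q-post"`.
#' @param group,participant_id Metadata labels.
#' @return An object of class `questionnaire_response`.
#' @export
questionnaire_response <- function(items, instrument = c("PANAS", "SSSQ"),
                                   timepoint = c("Q-pre", "Q-marker", "Q-post"),
                                   group = c("OMC", "control"),
                                   participant_id = "P00") {
  instrument <- match.arg(instrument)
  timepoint <- match.arg(timepoint)
  group <- match.arg(group)
  n_expect <- if (instrument == "PANAS") 20L else 24L
  if (length(items) != n_expect)
    stop(instrument, " requires ", n_expect, " items, got ", length(items),
         call. = FALSE)
  if (any(items != round(items)) || any(items < 1) || any(items > 5))
    stop("validation error: item responses must be integers in 1..5", call. = FALSE)
  structure(list(items = as.integer(items), instrument = instrument,
                 timepoint = timepoint, group = group,
                 participant_id = participant_id),
            class = "questionnaire_response")
}

#' Default PANAS scoring key
#'
#' Item-to-subscale assignment following the standard published ordering:
#' positive-affect items at positions 1, 3, 5, 9, 10, 12, 14, 16, 17, 19, the
#' remaining ten items negative affect. No reverse-keyed items. Editable keys
#' can be loaded with [read_scoring_key()].
#'
#' @return A data.frame with columns `index`, `subscale`, `reverse`.
#' @export
panas_key <- function() {
  pos <- c(1, 3, 5, 9, 10, 12, 14, 16, 17, 19)
  data.frame(index = 1:20,
             subscale = ifelse(1:20 %in% pos, "positive", "negative"),
             reverse = FALSE, stringsAsFactors = FALSE)
}

#' Default SSSQ scoring key
#'
#' Assigns the 24 items to the six dimensions (distress, worry, confidence,
#' negative_affect, motivation, self_evaluation) in consecutive blocks of
#' four. The published German key is not reproduced here; supply a custom key
#' via [read_scoring_key()] to match a specific translation.
#'
#' @return A data.frame with columns `index`, `subscale`, `reverse`.
#' @export
sssq_key <- function() {
  dims <- c("distress", "worry", "confidence", "negative_affect",
            "motivation", "self_evaluation")
  data.frame(index = 1:24, subscale = rep(dims, each = 4), reverse = FALSE,
             stringsAsFactors = FALSE)
}

#' Read a scoring key from YAML
#'
#' Expected layout: `instrument:` name and `items:` a list of
#' `{index, subscale, reverse}` entries.
#'
#' @param path YAML file path.
#' @return A data.frame with columns `index`, `subscale`, `reverse`.
#' @export
read_scoring_key <- function(path) {
  k <- yaml::read_yaml(path)
  items <- do.call(rbind, lapply(k$items, function(it) data.frame(
    index = as.integer(it$index), subscale = it$subscale,
    reverse = isTRUE(it$reverse), stringsAsFactors = FALSE)))
  items[order(items$index), ]
}

apply_key <- function(resp, key) {
  if (!setequal(key$index, seq_along(resp$items)))
    stop("key error: key must cover every item exactly once", call. = FALSE)
  v <- resp$items[key$index]
  ifelse(key$reverse, 6L - v, v)
}

#' Score the PANAS
#'
#' Subscale scores are item means on the 1--5 scale (matching the instrument's
#' reporting range); item sums (10--50) are attached as the `"sums"`
#' attribute.
#'
#' @param resp A [questionnaire_response] with `instrument = "PANAS"`.
#' @param key Scoring key data.frame (default [panas_key()]).
#' @return Named numeric vector `c(positive=, negative=)` in `[1, 5]`.
#' @export
score_panas <- function(resp, key = panas_key()) {
  stopifnot(resp$instrument == "PANAS")
  if (any(table(key$subscale) != 10))
    stop("key error: PANAS key needs 10 items per subscale", call. = FALSE)
  v <- apply_key(resp, key)
  means <- tapply(v, key$subscale, mean)
  out <- c(positive = unname(means[["positive"]]),
           negative = unname(means[["negative"]]))
  attr(out, "sums") <- out * 10
  out
}

#' Score the SSSQ
#'
#' Dimension scores are item means (1--5); the total score is the mean over
#' all 24 items.
#'
#' @param resp A [questionnaire_response] with `instrument = "SSSQ"`.
#' @param key Scoring key data.frame (default [sssq_key()]).
#' @return Named numeric vector of the six dimension scores plus `total`,
#'   each in `[1, 5]`.
#' @export
score_sssq <- function(resp, key = sssq_key()) {
  stopifnot(resp$instrument == "SSSQ")
  v <- apply_key(resp, key)
  means <- tapply(v, key$subscale, mean)
  out <- stats::setNames(as.numeric(means), names(means))
  c(out, total = mean(v))
}

#' Read a questionnaire CSV
#'
#' Columns: `participant,group,timepoint,instrument,item_index,response`.
#'
#' @param path File path.
#' @return A list of [questionnaire_response] objects.
#' @export
read_questionnaires <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "group", "timepoint", "instrument", "item_index", "response")
  if (!all(need %in% names(d)))
    stop("questionnaire CSV parse error: need columns ",
         paste(need, collapse = ","), call. = FALSE)
  key <- interaction(d$participant, d$timepoint, d$instrument, drop = TRUE)
  lapply(split(d, key), function(sub) {
    sub <- sub[order(sub$item_index), ]
    questionnaire_response(sub$response, instrument = sub$instrument[1],
                           timepoint = sub$timepoint[1], group = sub$group[1],
                           participant_id = sub$participant[1])
  })
}

#' Write questionnaire responses to CSV
#' @param responses List of [questionnaire_response] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_questionnaires <- function(responses, path) {
  rows <- lapply(responses, function(r) data.frame(
    participant = r$participant_id, group = r$group, timepoint = r$timepoint,
    instrument = r$instrument, item_index = seq_along(r$items),
    response = r$items, stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Score a list of questionnaire responses into a table
#'
#' @param responses List of [questionnaire_response] objects.
#' @param panas_key,sssq_key Scoring keys.
#' @return A data.frame with one row per participant x timepoint x instrument
#'   score column set: `participant`, `group`, `timepoint`, then
#'   `PANAS_positive`, `PANAS_negative` or the SSSQ dimension/total columns.
#' @export
score_table <- function(responses, panas_key = gaitstress::panas_key(),
                        sssq_key = gaitstress::sssq_key()) {
  rows <- lapply(responses, function(r) {
    base <- data.frame(participant = r$participant_id, group = r$group,
                       timepoint = r$timepoint, stringsAsFactors = FALSE)
    if (r$instrument == "PANAS") {
      s <- score_panas(r, panas_key)
      base$PANAS_positive <- s[["positive"]]; base$PANAS_negative <- s[["negative"]]
    } else {
      s <- score_sssq(r, sssq_key)
      for (nm in names(s)) base[[paste0("SSSQ_", nm)]] <- s[[nm]]
    }
    base
  })
  pan <- do.call(rbind, Filter(function(x) "PANAS_positive" %in% names(x), rows))
  sss <- do.call(rbind, Filter(function(x) "SSSQ_total" %in% names(x), rows))
  if (is.null(pan)) return(sss)
  if (is.null(sss)) return(pan)
  merge(pan, sss, by = c("participant", "group", "timepoint"), all = TRUE)
}
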