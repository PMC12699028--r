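#' Run the end-to-end analysis pipeline
#'
#' Orchestrates a complete run: obtain inputs (simulated cohort or files on
#' disk), extract gait features and stride waveforms, compute cortisol and
#' questionnaire markers, and run the group statistics (mixed ANOVA on
#' baseline-adjusted cortisol, pairwise test on the maximum increase, mixed
#' ANOVAs on questionnaire scores over Q-pre/Q-post, repeated-measures ANOVAs
#' within the OMC group over all three timepoints, Bonferroni-gated pairwise
#' tests on the discrete gait features, and SPM\{t\} on the hip and knee
#' waveforms per bout). Deterministic for a fixed config.
#'
#' @param config A nested list (or path to a YAML file with the same layout):
#'   \describe{
#'   \item{simulate}{arguments for [simulate_cohort()] (used when no `inputs`)}
#'   \item{inputs}{alternatively: `keypoints` (data.frame path/participant/
#'     group/bout), `cortisol_csv`, `questionnaire_csv`}
#'   \item{gait}{stage parameters passed to [extract_gait_features()]}
#'   \item{stats}{`alpha`, `permutations`, `responder_threshold`,
#'     `m_gait_comparisons`}
#'   \item{out_dir}{optional output directory for CSV/JSON artifacts}
#'   \item{seed}{seed for all stochastic steps (default 1)}
#'   }
#' @return A list of class `pipeline_result`: `features`, `cortisol`,
#'   `scores`, `stats`, `log`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1
  gaitp <- utils::modifyList(
    list(cutoff_hz = 10, trim_seconds = 30, offset_frames = 1L,
         elbow_threshold_deg = 80, forward = "-x"), config$gait %||% list())
  statp <- utils::modifyList(
    list(alpha = 0.05, permutations = 2000, responder_threshold = 1.5),
    config$stats %||% list())

  log <- list(seed = seed, params = list(gait = gaitp, stats = statp))

  # ---- inputs ----
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    kp_tab <- inp$keypoints
    trials <- lapply(seq_len(nrow(kp_tab)), function(i)
      list(series = read_keypoints(kp_tab$path[i], fps = kp_tab$fps[i] %||% 50,
                                   participant_id = kp_tab$participant[i],
                                   bout = kp_tab$bout[i]),
           group = kp_tab$group[i]))
    cortisol_list <- if (!is.null(inp$cortisol_csv)) read_cortisol(inp$cortisol_csv)
    responses <- if (!is.null(inp$questionnaire_csv)) read_questionnaires(inp$questionnaire_csv)
    group_of <- stats::setNames(kp_tab$group, kp_tab$participant)
  } else {
    sim <- do.call(simulate_cohort,
                   utils::modifyList(list(seed = seed), config$simulate %||% list()))
    trials <- unlist(lapply(sim$participants, function(p)
      lapply(p$bouts, function(b) list(series = b$keypoints, group = p$group))),
      recursive = FALSE)
    cortisol_list <- lapply(sim$participants, `[[`, "cortisol")
    responses <- unlist(lapply(sim$participants, `[[`, "questionnaires"),
                        recursive = FALSE)
    group_of <- vapply(sim$participants, `[[`, "", "group")
    log$simulated <- TRUE
  }

  # ---- gait extraction ----
  extractions <- lapply(trials, function(tr)
    c(do.call(extract_gait_features, c(list(tr$series), gaitp)),
      list(group = tr$group)))
  bout_features <- do.call(rbind, lapply(extractions, function(e) e$features))
  features <- build_feature_table(bout_features)
  features$group <- unname(group_of[features$participant])
  log$stride_counts <- Reduce(`+`, lapply(extractions, `[[`, "counts"))

  # ---- stress markers ----
  cortisol <- NULL; scores <- NULL
  if (!is.null(cortisol_list)) {
    cf <- lapply(cortisol_list, cortisol_features,
                 responder_threshold = statp$responder_threshold)
    cortisol <- do.call(rbind, lapply(cf, function(x) data.frame(
      participant = x$participant_id, group = x$group,
      t(x$adjusted), max_increase = x$max_increase,
      max_increase_pct = x$max_increase_pct, responder = x$responder,
      stringsAsFactors = FALSE)))
  }
  if (!is.null(responses)) scores <- score_table(responses)

  # ---- statistics ----
  stats_out <- list()
  if (!is.null(cortisol)) {
    long <- stats::reshape(
      cortisol[, c("participant", "group", paste0("S", 1:5))],
      direction = "long", varying = paste0("S", 1:5), v.names = "adjusted",
      timevar = "sample", times = paste0("S", 1:5), idvar = "participant")
    stats_out$cortisol_anova <- mixed_anova(long, "adjusted", "participant",
                                            "sample", "group")
    mi_a <- cortisol$max_increase[cortisol$group == "OMC"]
    mi_b <- cortisol$max_increase[cortisol$group == "control"]
    stats_out$max_increase <- if (length(mi_a) >= 3 && length(mi_b) >= 3)
      gated_pairwise(mi_a, mi_b, m_comparisons = 1,
                     label = "max cortisol increase: OMC vs control")
    stats_out$responders <- table(cortisol$group, cortisol$responder)
  }
  if (!is.null(scores)) {
    score_cols <- intersect(c("PANAS_positive", "PANAS_negative", "SSSQ_distress",
                              "SSSQ_self_evaluation", "SSSQ_total"), names(scores))
    prepost <- scores[scores$timepoint %in% c("Q-pre", "Q-post"), ]
    stats_out$questionnaire_anova <- lapply(stats::setNames(score_cols, score_cols),
      function(sc) mixed_anova(prepost, sc, "participant", "timepoint", "group"))
    omc <- scores[scores$group == "OMC", ]
    stats_out$omc_rm_anova <- lapply(stats::setNames(score_cols, score_cols),
      function(sc) rm_anova(omc, sc, "participant", "timepoint"))
  }
  gait_feats <- setdiff(names(features), c("participant", "group"))
  m <- statp$m_gait_comparisons %||% length(gait_feats)
  stats_out$gait_pairwise <- lapply(stats::setNames(gait_feats, gait_feats),
    function(v) {
      a <- features[[v]][features$group == "OMC"]
      b <- features[[v]][features$group == "control"]
      if (sum(is.finite(a)) < 3 || sum(is.finite(b)) < 3) return(NULL)
      gated_pairwise(a, b, m_comparisons = m,
                     label = paste0(v, ": OMC vs control"))
    })

  # SPM on lower-limb waveforms, per bout
  spm_in <- list(); spm_grp <- list()
  for (e in extractions) {
    b <- e$features$bout
    for (sig in c("hip_flexion", "knee_flexion")) {
      key <- paste(sig, b, sep = ".")
      spm_in[[key]] <- rbind(spm_in[[key]], mean_waveform(e$strides[[sig]]))
      spm_grp[[key]] <- c(spm_grp[[key]], e$group)
    }
  }
  stats_out$spm <- lapply(stats::setNames(names(spm_in), names(spm_in)), function(k) {
    g <- spm_grp[[k]]; m_ <- spm_in[[k]]
    if (length(unique(g)) < 2 || sum(g == "OMC") < 2 || sum(g == "control") < 2)
      return(NULL)
    spm_ttest2(m_[g == "OMC", , drop = FALSE], m_[g == "control", , drop = FALSE],
               alpha = statp$alpha, permutations = statp$permutations, seed = seed)
  })

  res <- structure(list(features = features, cortisol = cortisol,
                        scores = scores, stats = stats_out, log = log,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(res, config$out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write pipeline artifacts to a directory
#'
#' Emits the feature table, cortisol features, questionnaire scores, a stats
#' report (CSV + JSON), per-signal SPM node tables, the fully-resolved config
#' and a run log.
#'
#' @param res A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$features, file.path(dir, "gait_features.csv"), row.names = FALSE)
  if (!is.null(res$cortisol))
    utils::write.csv(res$cortisol, file.path(dir, "cortisol_features.csv"),
                     row.names = FALSE)
  if (!is.null(res$scores))
    utils::write.csv(res$scores, file.path(dir, "questionnaire_scores.csv"),
                     row.names = FALSE)
  pw <- Filter(Negate(is.null), res$stats$gait_pairwise)
  if (length(pw)) {
    tab <- do.call(rbind, lapply(pw, function(x) data.frame(
      comparison = x$label, test = x$test, statistic = x$statistic,
      p_raw = x$p_raw, p_bonferroni = x$p_bonferroni, hedges_g = x$hedges_g)))
    utils::write.csv(tab, file.path(dir, "gait_pairwise.csv"), row.names = FALSE)
  }
  for (nm in names(res$stats$spm)) {
    s <- res$stats$spm[[nm]]
    if (is.null(s)) next
    in_cluster <- rep(FALSE, 101)
    if (nrow(s$clusters))
      for (i in seq_len(nrow(s$clusters)))
        in_cluster[(s$clusters$start_node[i]:s$clusters$end_node[i]) + 1] <- TRUE
    utils::write.csv(data.frame(node = 0:100, t = s$t_field,
                                threshold = s$critical_threshold,
                                in_cluster = in_cluster),
                     file.path(dir, paste0("spm_", gsub("\\.", "_", nm), ".csv")),
                     row.names = FALSE)
  }
  yaml::write_yaml(res$config, file.path(dir, "config.yaml"))
  jsonlite::write_json(res$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  participants: %d, gait features: %d columns\n",
              nrow(x$features), ncol(x$features) - 2))
  if (!is.null(x$stats$cortisol_anova)) {
    cat("  cortisol mixed ANOVA:\n")
    print(x$stats$cortisol_anova)
  }
  ncl <- sum(vapply(x$stats$spm, function(s)
    if (is.null(s)) 0L else nrow(s$clusters), integer(1)))
  cat(sprintf("  SPM: %d suprathreshold cluster(s) across %d waveform tests\n",
              ncl, length(x$stats$spm)))
  invisible(x)
}
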