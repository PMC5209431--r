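# Orchestration: batch measurement, group comparison and repeatability
# tables shaped like the study's report, figures, and report output.

#' Measure every frame of a series
#'
#' @param frames list of [glottal_frame()] objects (see
#'   [frames_with_landmarks()]), or a path to a series file, in which case
#'   `landmarks` (a table or CSV path) is required.
#' @param landmarks landmark table or CSV path (file input only).
#' @param subject,study,reader identifiers stored in the output rows.
#' @param policy a [measure_policy()].
#' @return measurement data.frame, one row per frame.
#' @export
run_measure <- function(frames, landmarks = NULL, subject = "S1", study = 1,
                        reader = 1, policy = measure_policy()) {
  if (is.character(frames)) {
    series <- read_series(frames)
    if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)
    if (is.null(landmarks)) stop("file input requires a landmark table")
    frames <- frames_with_landmarks(series, landmarks, subject, study)
  }
  if (length(frames) == 0) stop("empty series: nothing to measure")
  rows <- lapply(seq_along(frames), function(k) {
    fr <- frames[[k]]
    m <- measure_frame(fr, policy)
    data.frame(subject = subject, study = study, reader = reader,
               task = fr$task, frame = k, t = fr$t,
               left_area = m$left_area, right_area = m$right_area,
               left_angle = m$left_angle, right_angle = m$right_angle,
               valid_left_area = unname(m$valid["left_area"]),
               valid_right_area = unname(m$valid["right_area"]),
               valid_left_angle = unname(m$valid["left_angle"]),
               valid_right_angle = unname(m$valid["right_angle"]))
  })
  do.call(rbind, rows)
}

#' Group comparison table (study-1 style)
#'
#' Unpaired t-test per metric between the two cohorts, plus "mean (SD)"
#' strings at 2 decimals. Metrics with fewer than 2 defined values in
#' either group are skipped with a message.
#'
#' @param metrics metrics table from [metrics_from_measurements()].
#' @param subjects data.frame mapping `subject` to `cohort`
#'   (`"healthy"` / `"uvfp"`).
#' @param study,reader which slice of the metrics table to compare.
#' @param variant t-test variant, `"pooled"` (default) or `"welch"`.
#' @return data.frame: metric, per-group mean/SD/n, t, df, p.
#' @export
compare_groups <- function(metrics, subjects = NULL, study = 1, reader = 1,
                           variant = "pooled") {
  m <- metrics[metrics$study == study & metrics$reader == reader, ]
  if (!"cohort" %in% names(m)) {
    if (is.null(subjects)) stop("metrics lack a cohort column; supply `subjects`")
    m <- merge(m, subjects[, c("subject", "cohort")], by = "subject")
  }
  rows <- lapply(metric_names(), function(met) {
    h <- m[[met]][m$cohort == "healthy"]
    u <- m[[met]][m$cohort == "uvfp"]
    h <- h[is.finite(h)]; u <- u[is.finite(u)]
    base <- data.frame(metric = met,
                       healthy = fmt_mean_sd(h), uvfp = fmt_mean_sd(u),
                       n_healthy = length(h), n_uvfp = length(u),
                       mean_healthy = if (length(h)) mean(h) else NA_real_,
                       sd_healthy = if (length(h) > 1) sd(h) else NA_real_,
                       mean_uvfp = if (length(u)) mean(u) else NA_real_,
                       sd_uvfp = if (length(u) > 1) sd(u) else NA_real_)
    if (length(h) < 2 || length(u) < 2) {
      message(sprintf("compare_groups: skipped %s (<2 defined values per group)", met))
      return(cbind(base, t = NA_real_, df = NA_real_, p = NA_real_))
    }
    tt <- t_test_raw(h, u, variant)
    cbind(base, t = tt$t, df = tt$df, p = tt$p)
  })
  do.call(rbind, rows)
}

#' Repeatability (ICC) table
#'
#' Builds the three repeatability designs of the emulated protocol and
#' computes a single-measure ICC per metric for each:
#' \itemize{
#'   \item intra-session — reader 1, study 1 vs study 2;
#'   \item inter-session — reader 1, study 1 vs study 3 (subjects with a
#'     second session);
#'   \item inter-reader — study 1, reader 1 vs reader 2.
#' }
#'
#' @param metrics metrics table from [metrics_from_measurements()].
#' @param form ICC form, see [icc()].
#' @return data.frame: metric, comparison, estimate, CI bounds, band, n.
#' @export
repeatability_icc <- function(metrics, form = "ICC2") {
  designs <- list(
    intra_session = list(a = c(study = 1, reader = 1), b = c(study = 2, reader = 1)),
    inter_session = list(a = c(study = 1, reader = 1), b = c(study = 3, reader = 1)),
    inter_reader = list(a = c(study = 1, reader = 1), b = c(study = 1, reader = 2)))
  slice <- function(sel, met) {
    s <- metrics[metrics$study == sel["study"] & metrics$reader == sel["reader"],
                 c("subject", met)]
    setNames(s[[met]], s$subject)
  }
  rows <- list()
  for (cmp in names(designs)) {
    for (met in metric_names()) {
      va <- slice(designs[[cmp]]$a, met)
      vb <- slice(designs[[cmp]]$b, met)
      common <- intersect(names(va), names(vb))
      mat <- cbind(va[common], vb[common])
      mat <- mat[complete.cases(mat), , drop = FALSE]
      res <- if (nrow(mat) >= 3) icc(mat, form = form) else NULL
      rows[[length(rows) + 1]] <- data.frame(
        metric = met, comparison = cmp,
        icc = if (is.null(res)) NA_real_ else res$estimate,
        ci_low = if (is.null(res)) NA_real_ else res$ci_low,
        ci_high = if (is.null(res)) NA_real_ else res$ci_high,
        band = if (is.null(res)) NA_character_ else res$band,
        n = nrow(mat))
    }
  }
  do.call(rbind, rows)
}

#' Run configuration for [run_experiment()]
#'
#' Exactly one input source: a simulation config, or file inputs
#' (`measurements_csv` + `subjects_csv`).
#'
#' @param sim a [cohort_config()], or `NULL` for file input.
#' @param measurements_csv,subjects_csv file inputs (frame measurements
#'   and subject-to-cohort mapping).
#' @param seed master seed for simulation.
#' @param t_variant t-test variant.
#' @param icc_form ICC form.
#' @param out_dir output directory (`NULL` = return only).
#' @export
run_config <- function(sim = cohort_config(), measurements_csv = NULL,
                       subjects_csv = NULL, seed = 1, t_variant = "pooled",
                       icc_form = "ICC2", out_dir = NULL) {
  file_input <- !is.null(measurements_csv)
  if (file_input && !is.null(sim))
    stop("config must name exactly one input source (files or simulation)")
  if (!file_input && is.null(sim))
    stop("config needs either a simulation config or measurement files")
  if (file_input) {
    for (p in c(measurements_csv, subjects_csv))
      if (!file.exists(p)) stop("input path not resolvable: ", p)
  }
  list(sim = sim, measurements_csv = measurements_csv,
       subjects_csv = subjects_csv, seed = seed, t_variant = t_variant,
       icc_form = icc_form, out_dir = out_dir)
}

#' Run the full experiment
#'
#' simulate (or load) -> measure -> metrics -> statistics. Produces a
#' study-style report: per-study group "mean (SD)" summaries with t-test
#' p-values for study 1, and intra-session / inter-session / inter-reader
#' ICCs for all six metrics. Deterministic given config and seed.
#'
#' @param config a [run_config()].
#' @return report list with `measurements`, `metrics`, `comparison`,
#'   `by_study` (mean-SD strings per study), `icc`, `config_echo`. Written
#'   to `out_dir` when configured (CSV tables, JSON + markdown report,
#'   metric distribution figure).
#' @export
run_experiment <- function(config = run_config()) {
  if (!is.null(config$sim)) {
    dataset <- simulate_cohort(config$sim, config$seed)
    measurements <- dataset$measurements
    subjects <- dataset$subjects
  } else {
    measurements <- read_measurements(config$measurements_csv)
    subjects <- read.csv(config$subjects_csv)
    check_columns(subjects, c("subject", "cohort"), "subjects")
  }
  metrics <- metrics_from_measurements(measurements)
  metrics <- merge(metrics, subjects[, c("subject", "cohort")], by = "subject")
  comparison <- compare_groups(metrics, subjects, study = 1, reader = 1,
                               variant = config$t_variant)
  by_study <- summarize_by_study(metrics)
  icc_tab <- repeatability_icc(metrics, form = config$icc_form)
  report <- list(measurements = measurements, metrics = metrics,
                 comparison = comparison, by_study = by_study, icc = icc_tab,
                 config_echo = list(seed = config$seed,
                                    t_variant = config$t_variant,
                                    icc_form = config$icc_form))
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# "mean (SD)" per metric x study x reader x cohort.
summarize_by_study <- function(metrics) {
  rows <- list()
  for (met in metric_names())
    for (st in sort(unique(metrics$study)))
      for (rd in sort(unique(metrics$reader[metrics$study == st]))) {
        sel <- metrics$study == st & metrics$reader == rd
        rows[[length(rows) + 1]] <- data.frame(
          metric = met, study = st, reader = rd,
          healthy = fmt_mean_sd(metrics[[met]][sel & metrics$cohort == "healthy"]),
          uvfp = fmt_mean_sd(metrics[[met]][sel & metrics$cohort == "uvfp"]))
      }
  do.call(rbind, rows)
}

#' Write a report to disk
#'
#' Emits `measurements.csv`, `metrics.csv`, `comparison.json/.md`,
#' `icc.json/.md` and a metric-distribution figure. All floats are
#' serialized at full precision (17 significant digits).
#'
#' @param report output of [run_experiment()].
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(report$measurements, file.path(dir, "measurements.csv"))
  write_table_csv(report$metrics, file.path(dir, "metrics.csv"))
  jsonlite::write_json(
    list(comparison = report$comparison, by_study = report$by_study,
         config = report$config_echo),
    file.path(dir, "comparison.json"), digits = NA, auto_unbox = TRUE,
    dataframe = "rows", na = "null")
  jsonlite::write_json(report$icc, file.path(dir, "icc.json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "rows", na = "null")
  writeLines(md_table(report$comparison[, c("metric", "healthy", "uvfp", "p")]),
             file.path(dir, "comparison.md"))
  icc_md <- report$icc
  icc_md$icc_ci <- sprintf("%.2f (%.2f, %.2f)", icc_md$icc, icc_md$ci_low,
                           icc_md$ci_high)
  writeLines(md_table(icc_md[, c("metric", "comparison", "icc_ci", "band")]),
             file.path(dir, "icc.md"))
  fig <- plot_metric_distributions(report$metrics)
  ggplot2::ggsave(file.path(dir, "metric_distributions.png"), fig,
                  width = 8, height = 5, dpi = 150)
  invisible(dir)
}

md_table <- function(df) {
  fmt <- function(x) if (is.numeric(x)) sprintf("%.4g", x) else as.character(x)
  cells <- vapply(df, fmt, character(nrow(df)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1)
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

#' Strip plot of metric distributions by cohort
#'
#' @param metrics metrics table with a `cohort` column (study 1, reader 1
#'   is selected).
#' @return a ggplot object.
#' @export
plot_metric_distributions <- function(metrics) {
  m <- metrics[metrics$study == 1 & metrics$reader == 1, ]
  long <- do.call(rbind, lapply(metric_names(), function(met)
    data.frame(metric = met, cohort = m$cohort, value = m[[met]])))
  long <- long[is.finite(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cohort, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1.5, alpha = 0.7) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Mobility metrics by cohort (study 1, reader 1)") +
    ggplot2::theme_bw()
}
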