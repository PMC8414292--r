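# Figures and the end-to-end pipeline.
#
# Every figure writes a machine-readable CSV sidecar with the exact
# numbers plotted, so rendering is testable without image comparison.

METRIC_LABELS <- c(cu_pct = "Capacity utilization (%)",
                   turnover_pct = "Patient turnover (%)",
                   mean_pccl = "Mean patient clinical complexity level")

#' Reporting configuration
#'
#' @param smoothing_span LOESS span as a fraction of the window used for
#'   the annual smoothed curves; in (0, 1].
#' @param format Image format, `"png"` or `"svg"`.
#' @param dpi Raster resolution.
#' @param metrics Which panel metrics to plot.
#' @return An object of class `report_config`.
#' @export
report_config <- function(smoothing_span = 0.25, format = c("png", "svg"),
                          dpi = 150, metrics = PANEL_METRICS) {
  stopifnot(smoothing_span > 0, smoothing_span <= 1, dpi > 0)
  format <- match.arg(format)
  metrics <- match.arg(metrics, PANEL_METRICS, several.ok = TRUE)
  structure(list(smoothing_span = smoothing_span, format = format,
                 dpi = dpi, metrics = metrics), class = "report_config")
}

# Centered local-regression smoother with pointwise 95% CI band.
smooth_series <- function(x, y, span) {
  ok <- !is.na(y)
  fit <- stats::loess(y[ok] ~ x[ok], span = span, degree = 2,
                      family = "gaussian")
  pred <- stats::predict(fit, newdata = data.frame(x = x[ok]), se = TRUE)
  out <- data.frame(x = x, smooth = NA_real_, lo = NA_real_, hi = NA_real_)
  out$smooth[ok] <- pred$fit
  out$lo[ok] <- pred$fit - 1.96 * pred$se.fit
  out$hi[ok] <- pred$fit + 1.96 * pred$se.fit
  out
}

save_figure <- function(plot, path, config, width = 9, height = 5.5) {
  ggplot2::ggsave(path, plot = plot, width = width, height = height,
                  dpi = config$dpi)
  invisible(path)
}

sidecar_path <- function(fig_path) {
  sub("\\.(png|svg)$", ".csv", fig_path)
}

#' Annual raw and smoothed daily curves per hospital type
#'
#' For each selected metric, plots (a) the raw daily per-type mean as a
#' line chart and (b) a LOESS-smoothed curve with a pointwise 95% CI band,
#' one image per chart, plus one CSV sidecar per metric holding the
#' plotted numbers (`date`, `hospital_type`, `mean_raw`, `smooth`, `lo`,
#' `hi`).
#'
#' @param panel A demand panel.
#' @param hospitals Hospital roster (id to type mapping).
#' @param out_dir Output directory (created if needed).
#' @param config A [report_config()].
#' @return Invisibly, the paths of all files written.
#' @export
plot_annual_curves <- function(panel, hospitals, out_dir,
                               config = report_config()) {
  check_panel(panel)
  if (nrow(panel) == 0) stop("empty panel", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- join_types(panel, hospitals)
  paths <- character()
  for (metric in intersect(config$metrics, names(panel))) {
    daily <- dplyr::summarise(
      dplyr::group_by(panel, .data$hospital_type, .data$date),
      mean_raw = mean(.data[[metric]], na.rm = TRUE), .groups = "drop"
    )
    daily$mean_raw[is.nan(daily$mean_raw)] <- NA_real_
    smoothed <- dplyr::group_modify(
      dplyr::group_by(daily, .data$hospital_type),
      function(df, key) {
        sm <- smooth_series(as.numeric(df$date), df$mean_raw,
                            config$smoothing_span)
        df$smooth <- sm$smooth
        df$lo <- sm$lo
        df$hi <- sm$hi
        df
      }
    )
    smoothed <- dplyr::ungroup(smoothed)

    p_raw <- ggplot2::ggplot(
      smoothed, ggplot2::aes(x = .data$date, y = .data$mean_raw,
                             colour = .data$hospital_type)) +
      ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
      ggplot2::labs(x = NULL, y = METRIC_LABELS[[metric]],
                    colour = "Hospital type") +
      ggplot2::theme_minimal()
    f_raw <- file.path(out_dir, sprintf("%s_daily_lines.%s", metric,
                                        config$format))
    save_figure(p_raw, f_raw, config)

    p_sm <- ggplot2::ggplot(
      smoothed, ggplot2::aes(x = .data$date, colour = .data$hospital_type,
                             fill = .data$hospital_type)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           alpha = 0.2, colour = NA, na.rm = TRUE) +
      ggplot2::geom_line(ggplot2::aes(y = .data$smooth), na.rm = TRUE) +
      ggplot2::labs(x = NULL, y = METRIC_LABELS[[metric]],
                    colour = "Hospital type", fill = "Hospital type") +
      ggplot2::theme_minimal()
    f_sm <- file.path(out_dir, sprintf("%s_annual_smooth.%s", metric,
                                       config$format))
    save_figure(p_sm, f_sm, config)

    f_csv <- file.path(out_dir, sprintf("%s_annual_curves.csv", metric))
    readr::write_csv(smoothed, f_csv, na = "")
    paths <- c(paths, f_raw, f_sm, f_csv)
  }
  invisible(paths)
}

#' Day-of-week profile figure
#'
#' Mean with 95% CI error bars for each metric by weekday (Monday-first),
#' one panel per metric, coloured by hospital type, plus a CSV sidecar of
#' the plotted summary rows.
#'
#' @param dow A summary from [dow_profile()].
#' @param out_dir Output directory.
#' @param config A [report_config()].
#' @return Invisibly, the paths written.
#' @export
plot_dow_profile <- function(dow, out_dir, config = report_config()) {
  if (nrow(dow) == 0) stop("empty day-of-week summary", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dow$weekday <- factor(dow$weekday, levels = DAY_NAMES)
  p <- ggplot2::ggplot(
    dow, ggplot2::aes(x = .data$weekday, y = .data$mean,
                      colour = .data$hospital_type,
                      group = .data$hospital_type)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci95_lo,
                                          ymax = .data$ci95_hi),
                             size = 0.25) +
    ggplot2::facet_wrap(~metric, scales = "free_y",
                        labeller = ggplot2::labeller(
                          metric = METRIC_LABELS)) +
    ggplot2::labs(x = NULL, y = "Mean (95% CI)",
                  colour = "Hospital type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  f <- file.path(out_dir, sprintf("dow_profile.%s", config$format))
  save_figure(p, f, config, width = 11, height = 4.5)
  f_csv <- sidecar_path(f)
  readr::write_csv(dow, f_csv, na = "")
  invisible(c(f, f_csv))
}

#' Weekly weekday-vs-weekend dot figure
#'
#' One dot per week per weekday/weekend stratum per hospital type and
#' metric; weeks whose stratum has no observations produce no dot. A CSV
#' sidecar holds the plotted rows.
#'
#' @param weekly A summary from [weekly_series()].
#' @param out_dir Output directory.
#' @param config A [report_config()].
#' @return Invisibly, the paths written.
#' @export
plot_weekly_dots <- function(weekly, out_dir, config = report_config()) {
  if (nrow(weekly) == 0) stop("empty weekly series", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- ggplot2::ggplot(
    weekly, ggplot2::aes(x = .data$week, y = .data$mean,
                         colour = .data$day_class)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(metric ~ hospital_type, scales = "free_y",
                        labeller = ggplot2::labeller(
                          metric = METRIC_LABELS)) +
    ggplot2::labs(x = "Week of study year", y = "Weekly mean",
                  colour = NULL) +
    ggplot2::theme_minimal()
  f <- file.path(out_dir, sprintf("weekly_dots.%s", config$format))
  save_figure(p, f, config, width = 12, height = 7)
  f_csv <- sidecar_path(f)
  readr::write_csv(weekly, f_csv, na = "")
  invisible(c(f, f_csv))
}

#' Run the full pipeline: simulate (or ingest), compute, summarize, report
#'
#' Executes the end-to-end analysis and writes all artifacts to a
#' directory: the stay table (simulated with `config` unless `stays_path`
#' is given), the hospital-day demand panel, every stratified summary
#' (type, weekday/weekend, day of week, week, season, PCCL distribution,
#' LOS), the figures with their CSV sidecars, a line-oriented log and a
#' JSON manifest (seed, versions, row counts, file list). Outputs are a
#' pure function of (configuration, seed, input files).
#'
#' @param config A [sim_config()]; supplies the window and, when no
#'   `stays_path` is given, the synthetic population.
#' @param out_dir Output directory (created if needed).
#' @param report A [report_config()].
#' @param stays_path Optional path to an existing stay CSV to analyse
#'   instead of simulating.
#' @return Invisibly, a named list of the paths written.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         report = report_config(), stays_path = NULL) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  window <- config$window

  if (is.null(stays_path)) {
    say("simulate: seed=%d hospitals=%d", config$seed,
        sum(config$hospitals_per_type))
    stays <- simulate_population(config)
    roster <- attr(stays, "hospitals")
    stays_file <- file.path(out_dir, "stays.csv")
    write_stays(stays, stays_file)
  } else {
    say("ingest: %s", stays_path)
    stays <- read_stays(stays_path, window)
    roster <- hospital_table(stays)
    stays_file <- stays_path
  }
  say("stays: %d cases, %d censored", nrow(stays), sum(stays$censored))

  report_issues <- validate_stays(stays)
  n_err <- sum(report_issues$severity == "error")
  say("validate: %d errors, %d warnings", n_err,
      sum(report_issues$severity == "warning"))
  if (n_err > 0) {
    stop("stay table failed validation; see validate_stays()",
         call. = FALSE)
  }

  panel <- compute_demand_panel(stays, window, hospitals = roster)
  panel_file <- file.path(out_dir, "panel.csv")
  panel_out <- panel
  panel_out$date <- format(panel_out$date, "%Y-%m-%d")
  readr::write_csv(panel_out, panel_file, na = "")
  say("panel: %d hospital-days", nrow(panel))

  hospital_map <- roster[, c("hospital_id", "hospital_type")]
  summaries <- list(
    by_type = summarize_by_type(panel, hospital_map),
    weekday_weekend = weekday_weekend_summary(panel, hospital_map, window),
    dow = dow_profile(panel, hospital_map, window),
    weekly = weekly_series(panel, hospital_map, window),
    season = season_summary(panel, hospital_map, window),
    pccl_distribution = pccl_case_distribution(stays),
    los = los_summary(stays, window),
    population = describe_population(stays, window)
  )
  summary_files <- vapply(names(summaries), function(nm) {
    f <- file.path(out_dir, sprintf("summary_%s.csv", nm))
    readr::write_csv(summaries[[nm]], f, na = "")
    f
  }, character(1))
  say("summaries: %d tables", length(summary_files))

  fig_dir <- file.path(out_dir, "figures")
  figs <- c(
    plot_annual_curves(panel, hospital_map, fig_dir, report),
    plot_dow_profile(summaries$dow, fig_dir, report),
    plot_weekly_dots(summaries$weekly, fig_dir, report)
  )
  say("figures: %d files", length(figs))

  manifest <- list(
    package = "carecensus",
    package_version = as.character(utils::packageVersion("carecensus")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    window = list(start = format(window$start), end = format(window$end)),
    n_cases = nrow(stays),
    n_censored = sum(stays$censored),
    n_hospital_days = nrow(panel),
    stays = basename(stays_file),
    summaries = basename(unname(summary_files)),
    figures = basename(figs)
  )
  manifest_file <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       pretty = TRUE)
  writeLines(log_lines, log_path)
  invisible(list(stays = stays_file, panel = panel_file,
                 summaries = summary_files, figures = figs,
                 manifest = manifest_file, log = log_path))
}
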