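# Stratified summaries of hospital-day panels, plus the case-level PCCL
# distribution and length-of-stay tables.
#
# All summaries pool hospital-day observations within a stratum (n = the
# number of hospital-days carrying the metric); absent values are
# excluded, never zero-imputed. The 95% CI is the normal approximation
# mean +/- 1.96 * SD / sqrt(n) with the sample SD.

PANEL_METRICS <- c("cu_pct", "turnover_pct", "mean_pccl")

# Long-format metric summary over arbitrary grouping columns. Internal.
summarize_metrics <- function(panel, group_cols,
                              metrics = PANEL_METRICS) {
  metrics <- intersect(metrics, names(panel))
  long <- tidyr::pivot_longer(
    panel[, c(group_cols, metrics)],
    cols = dplyr::all_of(metrics),
    names_to = "metric", values_to = "value"
  )
  long <- long[!is.na(long$value), ]
  out <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(
      c(group_cols, "metric")))),
    mean = mean(.data$value),
    sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
    min = min(.data$value),
    max = max(.data$value),
    n = dplyr::n(),
    .groups = "drop"
  )
  out$ci95_lo <- out$mean - 1.96 * out$sd / sqrt(out$n)
  out$ci95_hi <- out$mean + 1.96 * out$sd / sqrt(out$n)
  out[, c(group_cols, "metric", "mean", "sd", "ci95_lo", "ci95_hi",
          "min", "max", "n")]
}

# Attach hospital_type to a panel, failing on unmapped hospitals.
join_types <- function(panel, hospitals) {
  if (is.data.frame(hospitals)) {
    map <- hospitals[, c("hospital_id", "hospital_type")]
  } else {
    stop("`hospitals` must be a tibble with hospital_id and hospital_type",
         call. = FALSE)
  }
  unmapped <- setdiff(unique(panel$hospital_id), map$hospital_id)
  if (length(unmapped) > 0) {
    stop("hospitals without a type mapping: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::left_join(panel, map, by = "hospital_id")
  out$hospital_type <- factor(out$hospital_type, levels = hospital_types())
  out
}

panel_window <- function(panel, window) {
  window <- window %||% attr(panel, "window")
  stopifnot(inherits(window, "calendar_window"))
  window
}

#' Summarize demand metrics by hospital type
#'
#' For each hospital type and metric (capacity utilization, patient
#' turnover, daily mean PCCL): mean, sample SD, 95% CI, minimum, maximum
#' and the number of hospital-day observations carrying the metric.
#'
#' @param panel A demand panel (see [compute_demand_panel()]).
#' @param hospitals Hospital roster mapping `hospital_id` to
#'   `hospital_type` (e.g. from [hospital_table()]).
#' @return A tibble of summary rows, one per type x metric.
#' @export
summarize_by_type <- function(panel, hospitals) {
  check_panel(panel)
  panel <- join_types(panel, hospitals)
  summarize_metrics(panel, "hospital_type")
}

#' Summarize demand metrics by weekday vs weekend, per hospital type
#'
#' Splits window days into weekday and weekend strata (per the window's
#' weekend definition) and computes the same statistics as
#' [summarize_by_type()] within each type x stratum. A message flags any
#' empty stratum (e.g. a window containing no weekday).
#'
#' @inheritParams summarize_by_type
#' @param window A [calendar_window()]; defaults to the panel's window.
#' @return A tibble with columns `hospital_type`, `day_class` and the
#'   summary statistics.
#' @export
weekday_weekend_summary <- function(panel, hospitals, window = NULL) {
  check_panel(panel)
  window <- panel_window(panel, window)
  panel <- join_types(panel, hospitals)
  panel$day_class <- factor(
    ifelse(is_weekend(panel$date, window), "weekend", "weekday"),
    levels = c("weekday", "weekend")
  )
  missing_strata <- setdiff(levels(panel$day_class),
                            as.character(unique(panel$day_class)))
  if (length(missing_strata) > 0) {
    message("no days in stratum: ",
            paste(missing_strata, collapse = ", "))
  }
  summarize_metrics(panel, c("hospital_type", "day_class"))
}

#' Day-of-week profile of demand metrics
#'
#' Mean and 95% CI of each metric grouped by weekday name (Monday-first)
#' and hospital type.
#'
#' @inheritParams weekday_weekend_summary
#' @return A tibble with columns `hospital_type`, `weekday` and the
#'   summary statistics.
#' @export
dow_profile <- function(panel, hospitals, window = NULL) {
  check_panel(panel)
  panel <- join_types(panel, hospitals)
  panel$weekday <- day_of_week(panel$date)
  summarize_metrics(panel, c("hospital_type", "weekday"))
}

#' Weekly weekday/weekend series of demand metrics
#'
#' Assigns each window day a week index (1-based blocks of 7 days from the
#' window start) and computes per type x week x weekday/weekend stratum
#' means. Strata with no observations yield no row — so a window starting
#' inside a weekend can have a week with only a weekend row, which is how
#' a missing first-week weekday point arises in weekly dot plots.
#'
#' @inheritParams weekday_weekend_summary
#' @return A tibble with columns `hospital_type`, `week`, `day_class` and
#'   the summary statistics.
#' @export
weekly_series <- function(panel, hospitals, window = NULL) {
  check_panel(panel)
  window <- panel_window(panel, window)
  panel <- join_types(panel, hospitals)
  panel$week <- week_index(panel$date, window)
  panel$day_class <- factor(
    ifelse(is_weekend(panel$date, window), "weekend", "weekday"),
    levels = c("weekday", "weekend")
  )
  summarize_metrics(panel, c("hospital_type", "week", "day_class"))
}

#' Seasonal summary of demand metrics
#'
#' Meteorological seasons by month (Dec-Feb winter, Mar-May spring,
#' Jun-Aug summer, Sep-Nov autumn), summarized per hospital type.
#'
#' @inheritParams weekday_weekend_summary
#' @return A tibble with columns `hospital_type`, `season` and the
#'   summary statistics.
#' @export
season_summary <- function(panel, hospitals, window = NULL) {
  check_panel(panel)
  panel <- join_types(panel, hospitals)
  panel$season <- season_of(panel$date)
  summarize_metrics(panel, c("hospital_type", "season"))
}

#' Case-level PCCL distribution by hospital type
#'
#' Counts and percentages of cases at each PCCL level 0-4, per hospital
#' type and overall (`"all"` rows). Only cases carrying a PCCL — i.e.
#' discharged within the window — are counted. Percentages are row
#' percentages (within type, or of the grand total for the overall rows),
#' rounded to 2 decimals for presentation.
#'
#' @param records A stay tibble.
#' @return A tibble with columns `hospital_type`, `pccl`, `n`, `pct`.
#' @export
pccl_case_distribution <- function(records) {
  records <- as_stays(records)
  graded <- records[!is.na(records$pccl), ]
  grid <- tidyr::expand_grid(
    hospital_type = factor(hospital_types(), levels = hospital_types()),
    pccl = 0:4
  )
  counts <- dplyr::count(graded, .data$hospital_type, .data$pccl)
  counts$hospital_type <- factor(counts$hospital_type,
                                 levels = hospital_types())
  out <- dplyr::left_join(grid, counts,
                          by = c("hospital_type", "pccl"))
  out$n[is.na(out$n)] <- 0L
  out <- dplyr::group_by(out, .data$hospital_type)
  out <- dplyr::mutate(out, pct = if (sum(.data$n) > 0)
    round(100 * .data$n / sum(.data$n), 2) else NA_real_)
  out <- dplyr::ungroup(out)
  out <- out[out$hospital_type %in% unique(graded$hospital_type), ]
  overall <- dplyr::summarise(dplyr::group_by(out, .data$pccl),
                              n = sum(.data$n), .groups = "drop")
  overall <- tibble::tibble(
    hospital_type = "all", pccl = overall$pccl, n = overall$n,
    pct = round(100 * overall$n / sum(overall$n), 2)
  )
  out$hospital_type <- as.character(out$hospital_type)
  dplyr::bind_rows(out, overall)
}

#' Length-of-stay summary by hospital type
#'
#' LOS = discharge date minus admission date in whole days, over cases
#' discharged within the window; summarized per type and overall as mean
#' with normal-approximation 95% CI, median and quartiles.
#'
#' @param records A stay tibble.
#' @param window A [calendar_window()].
#' @return A tibble with one row per hospital type plus an `"all"` row.
#' @export
los_summary <- function(records, window) {
  records <- as_stays(records)
  stopifnot(inherits(window, "calendar_window"))
  discharged <- records[!is.na(records$discharge_date) &
                          records$discharge_date >= window$start &
                          records$discharge_date <= window$end, ]
  discharged$los <- as.integer(discharged$discharge_date -
                                 discharged$admit_date)
  one_group <- function(los, label) {
    n <- length(los)
    if (n == 0) {
      return(tibble::tibble(group = label, n = 0L, mean = NA_real_,
                            ci95_lo = NA_real_, ci95_hi = NA_real_,
                            median = NA_real_, q1 = NA_real_,
                            q3 = NA_real_))
    }
    m <- mean(los)
    se <- if (n > 1) stats::sd(los) / sqrt(n) else 0
    tibble::tibble(group = label, n = n, mean = m,
                   ci95_lo = m - 1.96 * se, ci95_hi = m + 1.96 * se,
                   median = stats::median(los),
                   q1 = unname(stats::quantile(los, 0.25)),
                   q3 = unname(stats::quantile(los, 0.75)))
  }
  types <- intersect(hospital_types(), unique(discharged$hospital_type))
  per_type <- lapply(types, function(ty) {
    one_group(discharged$los[discharged$hospital_type == ty], ty)
  })
  dplyr::bind_rows(c(per_type, list(one_group(discharged$los, "all"))))
}
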