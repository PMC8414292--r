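# Synthetic inpatient-population generator.
#
# Admissions are drawn hospital-by-hospital, day-by-day from a Poisson
# intensity = type rate x hospital size factor x day-of-week multiplier x
# seasonal factor. Each case then receives a PCCL from its hospital type's
# case mix, a whole-day length of stay from a lognormal model inflated
# multiplicatively by its PCCL, a discharge date nudged (within +/- 2
# days) toward attractive discharge weekdays, and a death flag. A warm-up
# period before the window start seeds the census so the window opens in
# steady state; cases still in hospital at the window end are censored and
# lose their PCCL.

# Multiplicative seasonal admission factor: a flat dip over the summer
# week range and a linear ramp-down over the last `yearend_days` days of
# every calendar year (so the warm-up period preceding a Jan 1 window
# start also sees the previous year's holiday trough).
seasonal_factor <- function(dates, config) {
  f <- rep(1, length(dates))
  wk <- week_index(dates, config$window)
  in_summer <- wk >= config$summer_weeks[1] & wk <= config$summer_weeks[2]
  f[in_summer] <- f[in_summer] * (1 - config$summer_dip)
  year_end <- as.Date(paste0(format(dates, "%Y"), "-12-31"))
  days_left <- as.integer(year_end - dates)
  ramp <- days_left < config$yearend_days
  f[ramp] <- f[ramp] *
    (1 - config$yearend_dip * (1 - days_left[ramp] / config$yearend_days))
  f
}

# Hospital roster implied by a configuration: ids, types, and lognormal
# size factors (median 1 within type).
hospital_roster <- function(config) {
  types <- hospital_types()
  code <- c(university = "UNI", tertiary = "TER", large_basic = "LBH",
            medium_basic = "MBH", small_basic = "SBH")
  roster <- lapply(types, function(ty) {
    n <- config$hospitals_per_type[[ty]]
    if (n == 0) return(NULL)
    tibble::tibble(
      hospital_id = sprintf("%s%02d", code[[ty]], seq_len(n)),
      hospital_type = ty,
      size_factor = exp(stats::rnorm(n, 0, config$hospital_size_sdlog))
    )
  })
  dplyr::bind_rows(roster)
}

#' Simulate a synthetic inpatient population
#'
#' Generates one stay record per inpatient case for the configured window,
#' including cases admitted during a warm-up period before the window
#' start that are still in hospital when it opens. Cases undischarged at
#' the window end are censored: their discharge date and PCCL are absent
#' and their death flag is off, exactly as in a real extraction where
#' complexity is only graded at discharge.
#'
#' The warm-up length is `max(60, P99 of the modelled length of stay)`
#' days, so the opening census is in steady state rather than empty.
#' Output is deterministic given the configuration (including its seed)
#' and is sorted by hospital and admission date.
#'
#' @param config A [sim_config()].
#' @return A stay tibble (see [read_stays()] for the schema) with the
#'   `censored` flag, plus a `"hospitals"` attribute carrying the hospital
#'   roster (id, type, size factor).
#' @examples
#' cfg <- sim_config(hospitals_per_type = c(university = 0L, tertiary = 1L,
#'                                          large_basic = 0L,
#'                                          medium_basic = 0L,
#'                                          small_basic = 1L),
#'                   window = calendar_window("2017-01-01", "2017-03-31"),
#'                   seed = 42L)
#' stays <- simulate_population(cfg)
#' dplyr::count(stays, hospital_type)
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(config) {
  window <- config$window
  hospitals <- hospital_roster(config)
  if (is.null(hospitals) || nrow(hospitals) == 0) {
    stop("configuration defines no hospitals", call. = FALSE)
  }

  # Admission rate per hospital via Little's law: median census targets /
  # expected occupied days per case.
  occ_days <- expected_occupied_days(config)
  names(occ_days) <- hospital_types()
  base_rate <- config$occupancy_scale / occ_days[names(config$occupancy_scale)]
  hospitals$rate <- base_rate[hospitals$hospital_type] *
    hospitals$size_factor * config$admission_rate_scale

  # Warm-up long enough that virtually no pre-window admission can still
  # be in hospital at the window start without being generated.
  p99 <- max(config$pccl_los_link) *
    stats::qlnorm(0.99, config$los_meanlog, config$los_sdlog)
  warmup <- max(60L, as.integer(ceiling(p99)))
  days <- seq(window$start - warmup, window$end, by = "day")
  dow_mult <- unname(config$dow_multipliers[
    as.integer(format(days, "%u"))])
  season_mult <- seasonal_factor(days, config)

  # Poisson admissions per hospital-day.
  grid_n <- stats::rpois(
    nrow(hospitals) * length(days),
    rep(hospitals$rate, each = length(days)) *
      rep(dow_mult * season_mult, times = nrow(hospitals))
  )
  cases <- tibble::tibble(
    hospital_id = rep(rep(hospitals$hospital_id, each = length(days)),
                      times = grid_n),
    hospital_type = rep(rep(hospitals$hospital_type, each = length(days)),
                        times = grid_n),
    admit_date = rep(rep(days, times = nrow(hospitals)), times = grid_n)
  )
  n <- nrow(cases)
  if (n == 0) {
    stop("configuration generated no admissions; increase occupancy_scale",
         call. = FALSE)
  }

  # PCCL from the per-type case mix.
  cases$pccl <- NA_integer_
  for (ty in hospital_types()) {
    idx <- which(cases$hospital_type == ty)
    if (length(idx) > 0) {
      cases$pccl[idx] <- sample.int(5L, length(idx), replace = TRUE,
                                    prob = config$pccl_probs[ty, ]) - 1L
    }
  }

  # Whole-day LOS: same-day point mass, otherwise rounded PCCL-inflated
  # lognormal, at least 1 day.
  same_day <- stats::runif(n) < config$same_day_prob
  los <- integer(n)
  k <- sum(!same_day)
  los[!same_day] <- pmax(1, round(
    stats::rlnorm(k, config$los_meanlog, config$los_sdlog) *
      config$pccl_los_link[cases$pccl[!same_day] + 1L]
  ))
  discharge0 <- cases$admit_date + los

  # Nudge multi-day discharges within +/- 2 days toward attractive
  # discharge weekdays (never before the admission day).
  off <- -2:2
  shift <- integer(n)
  multi <- which(!same_day)
  if (length(multi) > 0) {
    cand <- outer(as.integer(discharge0[multi]), off, "+")
    wt <- matrix(unname(config$discharge_dow_multipliers[
      (cand + 3L) %% 7L + 1L]), nrow = length(multi))
    wt[cand < as.integer(cases$admit_date[multi])] <- 0
    cs <- wt
    for (j in 2:5) cs[, j] <- cs[, j - 1] + wt[, j]
    u <- stats::runif(length(multi)) * cs[, 5]
    pick <- rowSums(cs < u) + 1L
    shift[multi] <- off[pick]
  }
  cases$discharge_date <- discharge0 + shift

  cases$died <- stats::runif(n) < config$death_prob
  cases$sex <- ifelse(stats::runif(n) < config$female_prob,
                      "female", "male")
  cases$age <- as.integer(pmin(105, pmax(
    0, round(stats::rnorm(n, config$age_mean, config$age_sd)))))

  # Keep only stays overlapping the window; censor past the window end.
  cases <- cases[cases$discharge_date >= window$start &
                   cases$admit_date <= window$end, ]
  beyond <- cases$discharge_date > window$end
  cases$discharge_date[beyond] <- as.Date(NA)
  cases$died[beyond] <- FALSE
  cases$pccl[beyond] <- NA_integer_
  cases$censored <- beyond

  cases <- dplyr::arrange(cases, .data$hospital_id, .data$admit_date)
  cases$case_id <- sprintf("C%08d", seq_len(nrow(cases)))
  cases <- cases[, c(STAY_COLUMNS, "censored")]
  attr(cases, "hospitals") <-
    hospitals[, c("hospital_id", "hospital_type", "size_factor")]
  cases
}

#' Descriptive overview of a stay population
#'
#' Per hospital type and overall: numbers of hospitals, cases, in-window
#' admissions and discharges, the sex split, and length-of-stay summaries
#' (mean with normal-approximation 95% CI, median, quartiles) over cases
#' discharged within the window. LOS is discharge date minus admission
#' date in whole days.
#'
#' @param records A stay tibble.
#' @param window A [calendar_window()].
#' @return A tibble with one row per hospital type plus an `"all"` row.
#' @export
describe_population <- function(records, window) {
  records <- as_stays(records)
  stopifnot(inherits(window, "calendar_window"))
  describe_group <- function(df, label) {
    discharged <- df[!is.na(df$discharge_date) &
                       df$discharge_date >= window$start &
                       df$discharge_date <= window$end, ]
    los <- as.integer(discharged$discharge_date - discharged$admit_date)
    n_los <- length(los)
    mean_los <- if (n_los > 0) mean(los) else NA_real_
    se <- if (n_los > 1) stats::sd(los) / sqrt(n_los) else 0
    tibble::tibble(
      group = label,
      n_hospitals = dplyr::n_distinct(df$hospital_id),
      n_cases = nrow(df),
      n_admissions = sum(df$admit_date >= window$start &
                           df$admit_date <= window$end),
      n_discharges = n_los,
      n_female = sum(df$sex == "female"),
      pct_female = 100 * mean(df$sex == "female"),
      los_mean = mean_los,
      los_ci_lo = mean_los - 1.96 * se,
      los_ci_hi = mean_los + 1.96 * se,
      los_median = if (n_los > 0) stats::median(los) else NA_real_,
      los_q1 = if (n_los > 0) unname(stats::quantile(los, 0.25)) else NA_real_,
      los_q3 = if (n_los > 0) unname(stats::quantile(los, 0.75)) else NA_real_
    )
  }
  per_type <- lapply(intersect(hospital_types(),
                               unique(records$hospital_type)),
                     function(ty) {
                       describe_group(records[records$hospital_type == ty, ],
                                      ty)
                     })
  dplyr::bind_rows(c(per_type, list(describe_group(records, "all"))))
}
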