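# Daily census panels and the three care-demand measures.
#
# A patient occupies every calendar day from admission through discharge
# inclusive (through the window end when censored); a same-day stay
# occupies exactly one day. The census is computed as an interval sweep:
# +1 at each stay's first in-window day, -1 after its last, cumulated per
# hospital. That joint convention is what makes the turnover ceiling
# exactly 200% (each present patient contributes at most an admission and
# a departure).

# Clip stays to the window; returns day indices (1-based) plus event
# flags. Internal.
clip_stays <- function(records, window) {
  start_idx <- as.integer(pmax(records$admit_date, window$start) -
                            window$start) + 1L
  end_date <- records$discharge_date
  end_date[is.na(end_date)] <- window$end
  end_idx <- as.integer(pmin(end_date, window$end) - window$start) + 1L
  tibble::tibble(
    hospital_id = records$hospital_id,
    start_idx = start_idx,
    end_idx = end_idx,
    admit_in = records$admit_date >= window$start &
      records$admit_date <= window$end,
    admit_idx = as.integer(records$admit_date - window$start) + 1L,
    discharge_in = !is.na(records$discharge_date) &
      records$discharge_date >= window$start &
      records$discharge_date <= window$end,
    discharge_idx = end_idx,
    died = records$died
  )
}

# Empty zero-filled panel skeleton: one row per hospital x window day.
panel_grid <- function(hospital_ids, window) {
  days <- window_days(window)
  grid <- tidyr::expand_grid(
    hospital_id = sort(unique(hospital_ids)),
    date = days
  )
  grid$census <- 0L
  grid$admissions <- 0L
  grid$discharges_alive <- 0L
  grid$deaths <- 0L
  grid
}

# Join per-(hospital, day-index) counts of `flag` onto the grid column.
add_event_counts <- function(grid, clips, flag, idx_col, col, window) {
  sub <- clips[clips[[flag]], c("hospital_id", idx_col)]
  if (nrow(sub) == 0) return(grid)
  counts <- dplyr::count(sub, .data$hospital_id, .data[[idx_col]])
  pos <- match(
    paste(counts$hospital_id, counts[[idx_col]]),
    paste(grid$hospital_id, as.integer(grid$date - window$start) + 1L)
  )
  grid[[col]][pos] <- counts$n
  grid
}

#' Build the daily hospital census panel
#'
#' Converts stay intervals into one row per hospital per window day, with
#' the daily census and event counts (admissions, live discharges,
#' deaths). Presence is counted inclusively from admission through
#' discharge day; cases admitted before the window contribute presence
#' from the window start; censored cases contribute presence through the
#' window end. Events are only counted on days inside the window.
#'
#' The census is computed by an interval sweep (a difference array
#' cumulated per hospital), not by per-day membership scans; see
#' [census_bruteforce()] for the equivalent explicit oracle used in tests.
#'
#' @param records A stay tibble (validated; see [read_stays()]).
#' @param window A [calendar_window()].
#' @param hospitals Optional character vector or roster tibble of hospital
#'   ids to include even if they have no stays (their rows are zero
#'   census). Defaults to the hospitals appearing in `records`.
#' @return A panel tibble with columns `hospital_id`, `date`, `census`,
#'   `admissions`, `discharges_alive`, `deaths`, carrying the window as
#'   attribute `"window"`.
#' @export
daily_census <- function(records, window, hospitals = NULL) {
  records <- as_stays(records)
  stopifnot(inherits(window, "calendar_window"))
  ids <- hospital_id_set(records, hospitals)
  grid <- panel_grid(ids, window)
  if (nrow(records) > 0) {
    clips <- clip_stays(records, window)
    keep <- clips$start_idx <= clips$end_idx
    clips <- clips[keep, ]
    n_days <- n_window_days(window)

    # Difference array: +1 at start, -1 after end, cumulated per hospital.
    deltas <- dplyr::bind_rows(
      tibble::tibble(hospital_id = clips$hospital_id,
                     idx = clips$start_idx, d = 1L),
      tibble::tibble(hospital_id = clips$hospital_id,
                     idx = clips$end_idx + 1L, d = -1L)
    )
    deltas <- deltas[deltas$idx <= n_days, ]
    deltas <- dplyr::summarise(
      dplyr::group_by(deltas, .data$hospital_id, .data$idx),
      d = sum(.data$d), .groups = "drop"
    )
    pos <- match(
      paste(deltas$hospital_id, deltas$idx),
      paste(grid$hospital_id, as.integer(grid$date - window$start) + 1L)
    )
    diff_col <- integer(nrow(grid))
    diff_col[pos] <- deltas$d
    grid$census <- as.integer(stats::ave(
      diff_col, grid$hospital_id, FUN = cumsum))

    grid <- add_event_counts(grid, clips, "admit_in", "admit_idx",
                             "admissions", window)
    alive <- clips
    alive$discharge_in <- alive$discharge_in & !alive$died
    grid <- add_event_counts(grid, alive, "discharge_in", "discharge_idx",
                             "discharges_alive", window)
    dead <- clips
    dead$discharge_in <- dead$discharge_in & dead$died
    grid <- add_event_counts(grid, dead, "discharge_in", "discharge_idx",
                             "deaths", window)
  }
  attr(grid, "window") <- window
  grid
}

hospital_id_set <- function(records, hospitals) {
  ids <- unique(records$hospital_id)
  if (!is.null(hospitals)) {
    if (is.data.frame(hospitals)) hospitals <- hospitals$hospital_id
    ids <- union(ids, hospitals)
  }
  if (length(ids) == 0) {
    stop("no hospitals: records are empty and `hospitals` was not given",
         call. = FALSE)
  }
  ids
}

#' Brute-force census oracle
#'
#' Same contract as [daily_census()], computed by explicitly enumerating
#' every occupied day of every stay and counting memberships. Quadratic in
#' stay length and intended as an independent oracle in tests, not for
#' production panels.
#'
#' @inheritParams daily_census
#' @return A panel tibble identical in shape to [daily_census()].
#' @export
census_bruteforce <- function(records, window, hospitals = NULL) {
  records <- as_stays(records)
  stopifnot(inherits(window, "calendar_window"))
  ids <- hospital_id_set(records, hospitals)
  grid <- panel_grid(ids, window)
  days <- window_days(window)
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    d_end <- if (is.na(rec$discharge_date)) window$end else rec$discharge_date
    occupied <- days[days >= rec$admit_date & days <= d_end]
    sel <- grid$hospital_id == rec$hospital_id & grid$date %in% occupied
    grid$census[sel] <- grid$census[sel] + 1L
    day_match <- function(d) grid$hospital_id == rec$hospital_id &
      grid$date == d
    if (rec$admit_date >= window$start && rec$admit_date <= window$end) {
      sel <- day_match(rec$admit_date)
      grid$admissions[sel] <- grid$admissions[sel] + 1L
    }
    if (!is.na(rec$discharge_date) && rec$discharge_date >= window$start &&
        rec$discharge_date <= window$end) {
      sel <- day_match(rec$discharge_date)
      col <- if (rec$died) "deaths" else "discharges_alive"
      grid[[col]][sel] <- grid[[col]][sel] + 1L
    }
  }
  attr(grid, "window") <- window
  grid
}

#' Capacity utilization: percent of each hospital's annual maximum census
#'
#' Fills `cu_pct(h, d) = 100 * census(h, d) / max_d census(h, d)`, the
#' daily census as a percentage of that hospital's highest daily census
#' over the window. The maximum observed occupancy — not a licensed-bed
#' count — is the denominator, so every active hospital attains 100% on at
#' least one day. Hospitals with an all-zero census get an absent `cu_pct`
#' and a warning.
#'
#' @param panel A census panel from [daily_census()].
#' @return The panel with a `cu_pct` column added.
#' @export
capacity_utilization <- function(panel) {
  check_panel(panel)
  window <- attr(panel, "window")
  panel <- dplyr::group_by(panel, .data$hospital_id)
  panel <- dplyr::mutate(panel, .max_census = max(.data$census))
  panel <- dplyr::ungroup(panel)
  zero <- unique(panel$hospital_id[panel$.max_census == 0])
  if (length(zero) > 0) {
    warning("hospitals with all-zero census get no cu_pct: ",
            paste(zero, collapse = ", "), call. = FALSE)
  }
  panel$cu_pct <- ifelse(panel$.max_census > 0,
                         100 * panel$census / panel$.max_census, NA_real_)
  panel$.max_census <- NULL
  attr(panel, "window") <- window
  panel
}

#' Daily patient turnover percentage
#'
#' Fills `turnover_pct(h, d) = 100 * (admissions + discharges_alive +
#' deaths) / census`: the share of the day's patients accounted for by
#' that day's admissions, live discharges and deaths. Under inclusive
#' occupancy counting each present patient contributes at most two events
#' (an admission and a departure), so turnover is bounded by 200%, which a
#' lone same-day patient attains. Days with census 0 (necessarily
#' event-free) get an absent value rather than 0/0.
#'
#' @param panel A census panel from [daily_census()].
#' @return The panel with a `turnover_pct` column added.
#' @export
patient_turnover <- function(panel) {
  check_panel(panel)
  events <- panel$admissions + panel$discharges_alive + panel$deaths
  panel$turnover_pct <- ifelse(panel$census > 0,
                               100 * events / panel$census, NA_real_)
  panel
}

#' Daily mean patient clinical complexity level
#'
#' Propagates each case's PCCL to every day of its stay and fills, per
#' hospital-day, the arithmetic mean PCCL over the PCCL-bearing patients
#' present (`mean_pccl`) and their count (`n_pccl`). Censored
#' (undischarged) cases contribute to the census but never to the PCCL
#' mean — their complexity is ungraded — which is what depresses the
#' year-end daily PCCL in annual windows. Days with no PCCL-bearing
#' patient get an absent mean.
#'
#' @param records The stay tibble the panel was built from.
#' @param panel A census panel from [daily_census()].
#' @param window A [calendar_window()]; defaults to the panel's window.
#' @return The panel with `mean_pccl` and `n_pccl` columns added.
#' @export
daily_mean_pccl <- function(records, panel, window = NULL) {
  check_panel(panel)
  records <- as_stays(records)
  window <- window %||% attr(panel, "window")
  stopifnot(inherits(window, "calendar_window"))
  bearing <- records[!is.na(records$pccl) & !records$censored &
                       !is.na(records$discharge_date), ]
  n_days <- n_window_days(window)
  key <- paste(panel$hospital_id, as.integer(panel$date - window$start) + 1L)

  sweep_sum <- function(values) {
    clips <- clip_stays(bearing, window)
    keep <- clips$start_idx <= clips$end_idx
    deltas <- dplyr::bind_rows(
      tibble::tibble(hospital_id = clips$hospital_id[keep],
                     idx = clips$start_idx[keep], d = values[keep]),
      tibble::tibble(hospital_id = clips$hospital_id[keep],
                     idx = clips$end_idx[keep] + 1L, d = -values[keep])
    )
    deltas <- deltas[deltas$idx <= n_days, ]
    deltas <- dplyr::summarise(
      dplyr::group_by(deltas, .data$hospital_id, .data$idx),
      d = sum(.data$d), .groups = "drop"
    )
    col <- numeric(nrow(panel))
    pos <- match(paste(deltas$hospital_id, deltas$idx), key)
    col[pos] <- deltas$d
    stats::ave(col, panel$hospital_id, FUN = cumsum)
  }

  if (nrow(bearing) > 0) {
    pccl_sum <- sweep_sum(as.numeric(bearing$pccl))
    pccl_n <- round(sweep_sum(rep(1, nrow(bearing))))
  } else {
    pccl_sum <- numeric(nrow(panel))
    pccl_n <- numeric(nrow(panel))
  }
  panel$n_pccl <- as.integer(pccl_n)
  panel$mean_pccl <- ifelse(pccl_n > 0, pccl_sum / pccl_n, NA_real_)
  attr(panel, "window") <- window
  panel
}

#' Compute the full demand panel in one call
#'
#' Runs [daily_census()], [capacity_utilization()], [patient_turnover()]
#' and [daily_mean_pccl()] in sequence.
#'
#' @inheritParams daily_census
#' @return The complete hospital-day panel.
#' @export
compute_demand_panel <- function(records, window, hospitals = NULL) {
  panel <- daily_census(records, window, hospitals = hospitals)
  panel <- capacity_utilization(panel)
  panel <- patient_turnover(panel)
  daily_mean_pccl(records, panel, window)
}

check_panel <- function(panel) {
  needed <- c("hospital_id", "date", "census", "admissions",
              "discharges_alive", "deaths")
  missing_cols <- setdiff(needed, names(panel))
  if (length(missing_cols) > 0) {
    stop("not a census panel; missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  invisible(panel)
}
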