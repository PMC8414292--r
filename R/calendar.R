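# Calendar window: the study period plus the weekend / week / season
# conventions every downstream stratification uses.

DAY_NAMES <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
               "Saturday", "Sunday")

SEASON_NAMES <- c("winter", "spring", "summer", "autumn")

#' Define a study calendar window
#'
#' A calendar window fixes the inclusive study period and the calendar
#' conventions shared by all stratified summaries: which weekdays count as
#' the weekend, how days are grouped into week indices, and how months map
#' to seasons.
#'
#' Week indices count blocks of 7 days from the window start (days 1-7 are
#' week 1, days 8-14 week 2, ...), so a 365-day window has 53 week indices
#' with a partial final week. This day-count convention (rather than ISO
#' weeks) keeps week 1 anchored to the window start whatever weekday that
#' is. Seasons follow the meteorological rule: Dec-Feb winter, Mar-May
#' spring, Jun-Aug summer, Sep-Nov autumn.
#'
#' @param start,end First and last day of the window (inclusive), as `Date`
#'   or anything `as.Date()` accepts.
#' @param weekend_days Character vector of English weekday names treated as
#'   the weekend. Default Saturday and Sunday.
#' @return An object of class `calendar_window`.
#' @examples
#' w <- calendar_window("2017-01-01", "2017-12-31")
#' length(window_days(w))
#' @export
calendar_window <- function(start, end,
                            weekend_days = c("Saturday", "Sunday")) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end)) {
    stop("`start` and `end` must be interpretable as dates", call. = FALSE)
  }
  if (end < start) {
    stop("`end` must be on or after `start`", call. = FALSE)
  }
  weekend_days <- match.arg(weekend_days, DAY_NAMES, several.ok = TRUE)
  structure(
    list(start = start, end = end, weekend_days = weekend_days),
    class = "calendar_window"
  )
}

#' @export
print.calendar_window <- function(x, ...) {
  cat(sprintf("<calendar_window> %s .. %s (%d days; weekend: %s)\n",
              format(x$start), format(x$end),
              as.integer(x$end - x$start) + 1L,
              paste(x$weekend_days, collapse = ", ")))
  invisible(x)
}

#' Days, weekdays, weeks and seasons of a window
#'
#' Small calendar helpers used throughout the package. `window_days()`
#' enumerates every day of the window; `day_of_week()` returns a
#' Monday-first ordered factor of weekday names; `is_weekend()` flags days
#' belonging to the window's weekend set; `week_index()` assigns the
#' day-count week number (1-based blocks of 7 days from the window start);
#' `season_of()` returns the meteorological season as an ordered factor.
#'
#' Weekday names are derived from the ISO weekday number, so they do not
#' depend on the locale.
#'
#' @param window A [calendar_window()].
#' @param dates A `Date` vector.
#' @return See each description above.
#' @export
window_days <- function(window) {
  stopifnot(inherits(window, "calendar_window"))
  seq(window$start, window$end, by = "day")
}

#' @rdname window_days
#' @export
day_of_week <- function(dates) {
  factor(DAY_NAMES[as.integer(format(dates, "%u"))], levels = DAY_NAMES)
}

#' @rdname window_days
#' @export
is_weekend <- function(dates, window) {
  stopifnot(inherits(window, "calendar_window"))
  as.character(day_of_week(dates)) %in% window$weekend_days
}

#' @rdname window_days
#' @export
week_index <- function(dates, window) {
  stopifnot(inherits(window, "calendar_window"))
  as.integer(dates - window$start) %/% 7L + 1L
}

#' @rdname window_days
#' @export
season_of <- function(dates) {
  m <- as.integer(format(dates, "%m"))
  factor(SEASON_NAMES[(m %% 12L) %/% 3L + 1L], levels = SEASON_NAMES)
}

# Number of days in the window.
n_window_days <- function(window) {
  as.integer(window$end - window$start) + 1L
}
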