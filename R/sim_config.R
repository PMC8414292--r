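# Generator configuration.
#
# Defaults emulate a one-year national general-hospital inpatient
# population: 102 hospitals in 5 size classes, right-skewed lengths of
# stay (mean ~6.4 d, median ~4 d), per-type PCCL case mix, weekday-heavy
# admission and discharge rhythms, a summer dip and a pronounced year-end
# dip in admissions, ~2% in-hospital mortality and ~1.35% of cases
# carrying over the year boundary.

# Per-type PCCL case-mix (levels 0..4), national general-hospital pattern:
# university hospitals carry the most complex mix, medium basic the least.
default_pccl_probs <- function() {
  m <- rbind(
    university   = c(122567, 3281, 28812, 41159, 36308),
    tertiary     = c(433514, 11003, 83374, 110756, 77162),
    large_basic  = c(73800, 1397, 10801, 14590, 8984),
    medium_basic = c(90284, 1679, 11237, 12865, 7465),
    small_basic  = c(10728, 219, 2229, 2759, 1523)
  )
  colnames(m) <- as.character(0:4)
  sweep(m, 1, rowSums(m), "/")
}

#' Synthetic-population generator configuration
#'
#' Builds the full parameter set for [simulate_population()]. The defaults
#' describe a one-year national inpatient population across 102 general
#' hospitals; every argument can be overridden for smaller or differently
#' shaped experiments.
#'
#' @param window Study [calendar_window()]. The default year starts on a
#'   Sunday, which exercises the partial-first-week edge case in weekly
#'   summaries.
#' @param hospitals_per_type Named integer vector: number of hospitals per
#'   type (totals 102 under the defaults).
#' @param occupancy_scale Named numeric vector: target median daily census
#'   per hospital of each type.
#' @param hospital_size_sdlog Log-scale spread of hospital sizes within a
#'   type (each hospital's admission intensity is scaled by a lognormal
#'   factor with median 1).
#' @param admission_rate_scale Global multiplier on admission intensity;
#'   1 targets the occupancy scales above.
#' @param dow_multipliers Named length-7 vector (Monday..Sunday),
#'   mean-normalized internally: relative admission intensity by weekday.
#' @param discharge_dow_multipliers Named length-7 vector: relative
#'   attractiveness of each weekday as a discharge day; realized by
#'   shifting each case's provisional discharge date within +/- 2 days.
#' @param summer_dip Relative admission reduction during `summer_weeks`.
#' @param summer_weeks Integer range (first, last) of window week indices
#'   forming the summer trough.
#' @param yearend_dip Relative admission reduction reached on the last
#'   window day; ramps up linearly over the final `yearend_days` days.
#' @param yearend_days Length of the year-end admission ramp-down, days.
#' @param los_meanlog,los_sdlog Lognormal parameters of the baseline
#'   (PCCL-0) length-of-stay distribution, in days, before rounding to
#'   whole days.
#' @param same_day_prob Probability that a case is admitted and discharged
#'   on the same calendar day (length of stay 0).
#' @param pccl_probs 5 x 5 matrix (type x level 0..4) of PCCL case-mix
#'   probabilities; rows must sum to 1.
#' @param pccl_los_link Length-5 multiplicative length-of-stay inflation by
#'   PCCL level; the positive complexity-LOS link drives the weekend
#'   elevation of the daily mean PCCL.
#' @param death_prob Probability that a discharged case ends in death.
#' @param female_prob Probability that a case is female.
#' @param age_mean,age_sd Normal parameters for patient age (truncated to
#'   0..105 and rounded).
#' @param carryover_target Documented target fraction of cases still in
#'   hospital at the window end (an emergent property of the rhythms and
#'   the LOS model, recorded here for reference, not enforced).
#' @param seed Integer RNG seed; the same configuration and seed give a
#'   byte-identical population.
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(
    window = calendar_window("2017-01-01", "2017-12-31"),
    hospitals_per_type = c(university = 5L, tertiary = 39L,
                           large_basic = 19L, medium_basic = 20L,
                           small_basic = 19L),
    occupancy_scale = c(university = 988, tertiary = 298,
                        large_basic = 120, medium_basic = 71,
                        small_basic = 19),
    hospital_size_sdlog = 0.35,
    admission_rate_scale = 1,
    dow_multipliers = c(Monday = 1.30, Tuesday = 1.15, Wednesday = 1.10,
                        Thursday = 1.05, Friday = 1.00, Saturday = 0.70,
                        Sunday = 0.70),
    discharge_dow_multipliers = c(Monday = 1.35, Tuesday = 1.05,
                                  Wednesday = 1.00, Thursday = 1.05,
                                  Friday = 1.35, Saturday = 0.65,
                                  Sunday = 0.55),
    summer_dip = 0.08,
    summer_weeks = c(20L, 35L),
    yearend_dip = 0.55,
    yearend_days = 14L,
    los_meanlog = 1.17,
    los_sdlog = 0.80,
    same_day_prob = 0.10,
    pccl_probs = default_pccl_probs(),
    pccl_los_link = c(1.00, 1.30, 1.80, 2.60, 3.50),
    death_prob = 0.02,
    female_prob = 0.534,
    age_mean = 55,
    age_sd = 22,
    carryover_target = 0.0135,
    seed = 1L) {
  types <- hospital_types()
  stopifnot(inherits(window, "calendar_window"))
  hospitals_per_type <- hospitals_per_type[types]
  occupancy_scale <- occupancy_scale[types]
  if (anyNA(hospitals_per_type) || anyNA(occupancy_scale)) {
    stop("hospitals_per_type and occupancy_scale must name all 5 types",
         call. = FALSE)
  }
  if (any(hospitals_per_type > 0 & occupancy_scale <= 0)) {
    stop("occupancy_scale must be positive for every type with hospitals",
         call. = FALSE)
  }
  if (length(dow_multipliers) != 7 || any(dow_multipliers < 0) ||
      length(discharge_dow_multipliers) != 7 ||
      any(discharge_dow_multipliers < 0)) {
    stop("day-of-week multipliers must be 7 non-negative values",
         call. = FALSE)
  }
  pccl_probs <- as.matrix(pccl_probs)[types, , drop = FALSE]
  if (any(abs(rowSums(pccl_probs) - 1) > 1e-9) || any(pccl_probs < 0)) {
    stop("each row of pccl_probs must be a probability vector",
         call. = FALSE)
  }
  stopifnot(
    same_day_prob >= 0, same_day_prob < 1,
    death_prob >= 0, death_prob <= 1,
    female_prob >= 0, female_prob <= 1,
    summer_dip >= 0, summer_dip < 1, yearend_dip >= 0, yearend_dip < 1,
    length(pccl_los_link) == 5, all(pccl_los_link > 0),
    admission_rate_scale > 0
  )
  structure(list(
    window = window,
    hospitals_per_type = hospitals_per_type,
    occupancy_scale = occupancy_scale,
    hospital_size_sdlog = hospital_size_sdlog,
    admission_rate_scale = admission_rate_scale,
    dow_multipliers = dow_multipliers / mean(dow_multipliers),
    discharge_dow_multipliers = discharge_dow_multipliers,
    summer_dip = summer_dip,
    summer_weeks = as.integer(summer_weeks),
    yearend_dip = yearend_dip,
    yearend_days = as.integer(yearend_days),
    los_meanlog = los_meanlog,
    los_sdlog = los_sdlog,
    same_day_prob = same_day_prob,
    pccl_probs = pccl_probs,
    pccl_los_link = pccl_los_link,
    death_prob = death_prob,
    female_prob = female_prob,
    age_mean = age_mean,
    age_sd = age_sd,
    carryover_target = carryover_target,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  window: %s .. %s\n", format(x$window$start),
              format(x$window$end)))
  cat(sprintf("  hospitals: %s (total %d)\n",
              paste(sprintf("%s=%d", names(x$hospitals_per_type),
                            x$hospitals_per_type), collapse = ", "),
              sum(x$hospitals_per_type)))
  cat(sprintf("  LOS model: lognormal(meanlog=%.3f, sdlog=%.3f), P(same-day)=%.2f\n",
              x$los_meanlog, x$los_sdlog, x$same_day_prob))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read a generator configuration from YAML
#'
#' Reads a configuration file whose keys match the arguments of
#' [sim_config()]; keys not present keep their defaults. `window` is given
#' as a mapping with `start`, `end` and optional `weekend_days`;
#' `pccl_probs` as a mapping from type to a 5-vector.
#'
#' @param path YAML file path.
#' @return A `sim_config` object.
#' @export
sim_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$window)) {
    args$window <- calendar_window(
      raw$window$start, raw$window$end,
      weekend_days = raw$window$weekend_days %||% c("Saturday", "Sunday")
    )
  }
  vec_keys <- c("hospitals_per_type", "occupancy_scale", "dow_multipliers",
                "discharge_dow_multipliers")
  for (k in vec_keys) {
    if (!is.null(raw[[k]])) args[[k]] <- unlist(raw[[k]])
  }
  if (!is.null(raw$pccl_probs)) {
    args$pccl_probs <- do.call(rbind, raw$pccl_probs)[hospital_types(), ]
  }
  scalar_keys <- c("hospital_size_sdlog", "admission_rate_scale",
                   "summer_dip", "summer_weeks", "yearend_dip",
                   "yearend_days", "los_meanlog", "los_sdlog",
                   "same_day_prob", "pccl_los_link", "death_prob",
                   "female_prob", "age_mean", "age_sd", "carryover_target",
                   "seed")
  for (k in scalar_keys) {
    if (!is.null(raw[[k]])) args[[k]] <- unlist(raw[[k]])
  }
  do.call(sim_config, args)
}

# Expected occupied days per case (LOS + 1, inclusive counting) per
# hospital type, by numerical integration of the rounded, clamped,
# PCCL-inflated lognormal. Used to convert occupancy scales into
# admission rates via Little's law.
expected_occupied_days <- function(config) {
  p <- seq(0.0005, 0.9995, by = 0.001)
  q <- stats::qlnorm(p, config$los_meanlog, config$los_sdlog)
  e_los_level <- vapply(config$pccl_los_link, function(m) {
    mean(pmax(1, round(q * m)))
  }, numeric(1))
  e_los_type <- as.numeric(config$pccl_probs %*% e_los_level)
  (1 - config$same_day_prob) * e_los_type + 1
}
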