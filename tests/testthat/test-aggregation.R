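# Stratified summaries: arithmetic on known values, partition properties,
# and the case-level PCCL / LOS tables.

hosp_map <- tibble::tibble(hospital_id = c("H1", "H2"),
                           hospital_type = c("small_basic",
                                             "medium_basic"))

# A small panel with known values via a hand-built stay table.
toy_panel <- function(window = week1) {
  tbl <- stays_of(
    make_stay("A", admit = "2017-01-01", discharge = "2017-01-03",
              pccl = 4L),
    make_stay("B", admit = "2017-01-02", discharge = "2017-01-05",
              pccl = 0L),
    make_stay("C", hospital_id = "H2", hospital_type = "medium_basic",
              admit = "2017-01-01", discharge = "2017-01-07", pccl = 2L)
  )
  list(stays = tbl,
       panel = compute_demand_panel(tbl, window))
}

test_that("type summary reproduces textbook mean/sd/CI arithmetic", {
  # a stratum holding exactly the values 10, 20, 30
  panel <- tibble::tibble(
    hospital_id = "H1",
    date = as.Date("2017-01-01") + 0:2,
    census = 1L, admissions = 0L, discharges_alive = 0L, deaths = 0L,
    cu_pct = c(10, 20, 30)
  )
  attr(panel, "window") <- calendar_window("2017-01-01", "2017-01-03")
  s <- summarize_by_type(panel, hosp_map)
  row <- s[s$metric == "cu_pct", ]
  expect_equal(row$mean, 20)
  expect_equal(row$sd, 10)
  expect_equal(row$min, 10)
  expect_equal(row$max, 30)
  expect_equal(row$n, 3L)
  expect_equal(row$ci95_lo, 20 - 1.96 * 10 / sqrt(3))
  expect_equal(row$ci95_hi, 20 + 1.96 * 10 / sqrt(3))

  # single observation: sd 0, degenerate CI
  one <- panel[1, ]
  attr(one, "window") <- attr(panel, "window")
  s1 <- summarize_by_type(one, hosp_map)
  r1 <- s1[s1$metric == "cu_pct", ]
  expect_equal(r1$sd, 0)
  expect_equal(r1$ci95_lo, 10)
  expect_equal(r1$ci95_hi, 10)
})

test_that("summaries demand a complete hospital-type mapping", {
  tp <- toy_panel()
  expect_error(summarize_by_type(tp$panel,
                                 hosp_map[hosp_map$hospital_id == "H1", ]),
               "without a type mapping")
})

test_that("absent metric values are excluded, not zero-imputed", {
  tp <- toy_panel()
  s <- summarize_by_type(tp$panel, hosp_map)
  # H1 has patients on Jan 1-5 only: 5 turnover observations, 2 absent
  row <- s[s$metric == "turnover_pct" & s$hospital_type == "small_basic", ]
  expect_equal(row$n, 5L)
  # mean_pccl for H1 exists only while A or B is present
  row <- s[s$metric == "mean_pccl" & s$hospital_type == "small_basic", ]
  expect_equal(row$n, 5L)
  expect_equal(row$max, 4)
})

test_that("weekday/weekend split partitions the panel and flags empties", {
  tp <- toy_panel()
  ww <- weekday_weekend_summary(tp$panel, hosp_map)
  cu <- ww[ww$metric == "cu_pct", ]
  # strata n sum to total non-absent observations per type
  expect_equal(sum(cu$n), sum(!is.na(tp$panel$cu_pct)))
  # constant metric: weekday mean equals weekend mean (H2 at 100% all week)
  h2 <- cu[cu$hospital_type == "medium_basic", ]
  expect_equal(h2$mean, c(100, 100))

  # weekend-only window
  sat_sun <- calendar_window("2017-01-07", "2017-01-08")
  tbl <- make_stay("A", admit = "2017-01-07", discharge = "2017-01-08")
  p <- compute_demand_panel(tbl, sat_sun)
  expect_message(
    ww2 <- weekday_weekend_summary(p, hosp_map, sat_sun),
    "no days in stratum: weekday")
  expect_true(all(ww2$day_class == "weekend"))
})

test_that("day-of-week profile is flat for a constant panel", {
  tbl <- make_stay("A", admit = "2016-12-01", discharge = "2017-02-01")
  w <- calendar_window("2017-01-01", "2017-01-28")
  panel <- compute_demand_panel(tbl, w)
  prof <- dow_profile(panel, hosp_map, w)
  cu <- prof[prof$metric == "cu_pct", ]
  expect_equal(nrow(cu), 7)
  expect_true(all(cu$mean == 100))
  # single-day panel populates exactly one weekday
  one_day <- calendar_window("2017-01-04", "2017-01-04")
  p1 <- compute_demand_panel(make_stay("B", admit = "2017-01-04",
                                       discharge = "2017-01-04"), one_day)
  prof1 <- dow_profile(p1, hosp_map, one_day)
  expect_equal(unique(as.character(prof1$weekday)), "Wednesday")
})

test_that("weekly series indexes 7-day blocks and drops empty strata", {
  # 14-day window -> exactly 2 week indices
  w <- calendar_window("2017-01-02", "2017-01-15")
  tbl <- make_stay("A", admit = "2017-01-02", discharge = "2017-01-15")
  panel <- compute_demand_panel(tbl, w)
  wk <- weekly_series(panel, hosp_map, w)
  expect_equal(sort(unique(wk$week)), c(1L, 2L))

  # window starting Saturday with a weekend-only first week
  w2 <- calendar_window("2017-01-07", "2017-01-08")
  tbl2 <- make_stay("A", admit = "2017-01-07", discharge = "2017-01-08")
  p2 <- compute_demand_panel(tbl2, w2)
  wk2 <- weekly_series(p2, hosp_map, w2)
  expect_false(any(wk2$day_class == "weekday"))

  # partition: weekly strata n's sum to all window days per hospital
  tp <- toy_panel()
  wk3 <- weekly_series(tp$panel, hosp_map)
  cu3 <- wk3[wk3$metric == "cu_pct", ]
  expect_equal(sum(cu3$n), sum(!is.na(tp$panel$cu_pct)))
})

test_that("season summary strata follow the month mapping", {
  w <- calendar_window("2017-07-01", "2017-07-14")
  tbl <- make_stay("A", admit = "2017-07-01", discharge = "2017-07-14")
  panel <- compute_demand_panel(tbl, w)
  se <- season_summary(panel, hosp_map, w)
  expect_true(all(se$season == "summer"))
})

test_that("PCCL case distribution gives per-type and overall percentages", {
  one <- make_stay("A", pccl = 2L)
  d <- pccl_case_distribution(one)
  row <- d[d$hospital_type == "all" & d$pccl == 2, ]
  expect_equal(row$pct, 100)
  expect_equal(sum(d$n[d$hospital_type == "all"]), 1)
  # graded = discharged only: censored cases never enter the table
  two <- stays_of(one, make_stay("B", discharge = NA, pccl = NA))
  d2 <- pccl_case_distribution(two)
  expect_equal(sum(d2$n[d2$hospital_type == "all"]), 1)
})

test_that("LOS summary matches a brute-force recomputation", {
  w <- calendar_window("2017-01-01", "2017-03-31")
  same_day <- los_summary(make_stay("A", admit = "2017-01-05",
                                    discharge = "2017-01-05"), w)
  expect_equal(same_day$mean[same_day$group == "all"], 0)
  two <- stays_of(
    make_stay("A", admit = "2017-01-02", discharge = "2017-01-04"),
    make_stay("B", admit = "2017-01-02", discharge = "2017-01-08"))
  two_s <- los_summary(two, w)
  expect_equal(two_s$mean[two_s$group == "all"], 4)

  withr::local_seed(77)
  tbl <- random_stays(1000, w, n_hospitals = 5)
  s <- los_summary(tbl, w)
  keep <- !is.na(tbl$discharge_date)
  los <- as.numeric(tbl$discharge_date[keep] - tbl$admit_date[keep])
  all_row <- s[s$group == "all", ]
  expect_equal(all_row$n, length(los))
  expect_equal(all_row$mean, mean(los))
  expect_equal(all_row$median, stats::median(los))
  expect_equal(all_row$q1, unname(stats::quantile(los, 0.25)))
  expect_equal(all_row$ci95_lo,
               mean(los) - 1.96 * stats::sd(los) / sqrt(length(los)))
})

test_that("aggregations are invariant to panel row order", {
  tp <- toy_panel()
  shuffled <- tp$panel[rev(seq_len(nrow(tp$panel))), ]
  attr(shuffled, "window") <- attr(tp$panel, "window")
  a <- summarize_by_type(tp$panel, hosp_map)
  b <- summarize_by_type(shuffled, hosp_map)
  expect_equal(as.data.frame(a), as.data.frame(b))
})
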