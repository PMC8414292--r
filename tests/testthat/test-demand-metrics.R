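# Census construction and the three demand measures, checked against
# hand-derived panels and the brute-force membership oracle.

test_that("a 3-day stay occupies admission through discharge inclusive", {
  tbl <- make_stay("A", admit = "2017-01-02", discharge = "2017-01-04")
  panel <- daily_census(tbl, week1)
  expect_equal(panel$census, c(0, 1, 1, 1, 0, 0, 0))
  expect_equal(panel$admissions, c(0, 1, 0, 0, 0, 0, 0))
  expect_equal(panel$discharges_alive, c(0, 0, 0, 1, 0, 0, 0))
  expect_equal(panel$deaths, rep(0, 7))
  expect_equal(as.data.frame(panel),
               as.data.frame(census_bruteforce(tbl, week1)),
               ignore_attr = TRUE)
})

test_that("a same-day stay occupies exactly one day with both events", {
  tbl <- make_stay("A", admit = "2017-01-05", discharge = "2017-01-05")
  panel <- daily_census(tbl, week1)
  expect_equal(panel$census, c(0, 0, 0, 0, 1, 0, 0))
  expect_equal(panel$admissions[5], 1)
  expect_equal(panel$discharges_alive[5], 1)
  expect_equal(as.data.frame(panel),
               as.data.frame(census_bruteforce(tbl, week1)),
               ignore_attr = TRUE)
})

test_that("a carry-in case contributes presence but no admission event", {
  tbl <- make_stay("A", admit = "2016-12-28", discharge = "2017-01-03")
  panel <- daily_census(tbl, week1)
  expect_equal(panel$census, c(1, 1, 1, 0, 0, 0, 0))
  expect_equal(sum(panel$admissions), 0)
  expect_equal(panel$discharges_alive[3], 1)
  expect_equal(as.data.frame(panel),
               as.data.frame(census_bruteforce(tbl, week1)),
               ignore_attr = TRUE)
})

test_that("a censored case occupies through the window end", {
  tbl <- make_stay("A", admit = "2017-01-06", discharge = NA, pccl = NA)
  panel <- daily_census(tbl, week1)
  expect_equal(panel$census, c(0, 0, 0, 0, 0, 1, 1))
  expect_equal(sum(panel$discharges_alive) + sum(panel$deaths), 0)
})

test_that("deaths count as departures, separately from live discharges", {
  tbl <- stays_of(
    make_stay("A", admit = "2017-01-02", discharge = "2017-01-04",
              died = TRUE),
    make_stay("B", admit = "2017-01-02", discharge = "2017-01-04")
  )
  panel <- daily_census(tbl, week1)
  expect_equal(panel$deaths[4], 1)
  expect_equal(panel$discharges_alive[4], 1)
  panel <- patient_turnover(panel)
  # day 4: census 2, events = 1 live discharge + 1 death
  expect_equal(panel$turnover_pct[4], 100)
})

test_that("capacity utilization is census / annual max, per hospital", {
  tbl <- stays_of(
    make_stay("A", admit = "2017-01-02", discharge = "2017-01-03"),
    make_stay("B", admit = "2017-01-03", discharge = "2017-01-03",
              hospital_id = "H1"),
    make_stay("C", hospital_id = "H2", admit = "2017-01-01",
              discharge = "2017-01-07")
  )
  panel <- capacity_utilization(daily_census(tbl, week1))
  h1 <- panel[panel$hospital_id == "H1", ]
  # H1 max census is 2 (Jan 3); Jan 2 census 1 -> 50%
  expect_equal(h1$cu_pct[3], 100)
  expect_equal(h1$cu_pct[2], 50)
  # H2 is at its own max all week
  expect_true(all(panel$cu_pct[panel$hospital_id == "H2"] == 100))
})

test_that("an inactive hospital gets absent cu_pct and a warning", {
  tbl <- make_stay("A")
  panel <- daily_census(tbl, week1, hospitals = c("H1", "H9"))
  expect_warning(panel <- capacity_utilization(panel), "H9")
  expect_true(all(is.na(panel$cu_pct[panel$hospital_id == "H9"])))
  expect_false(anyNA(panel$cu_pct[panel$hospital_id == "H1"]))
})

test_that("turnover arithmetic: events over census, absent at census 0", {
  tbl <- stays_of(
    make_stay(sprintf("P%d", 1:10), admit = "2017-01-01",
              discharge = "2017-01-06"),
    make_stay(c("Q1", "Q2"), admit = "2017-01-02",
              discharge = "2017-01-07")
  )
  panel <- patient_turnover(daily_census(tbl, week1))
  # Jan 2: census 12, 2 admissions, 0 discharges
  expect_equal(panel$turnover_pct[2], 100 * 2 / 12)
  # Jan 3-5: 12 present, no events
  expect_equal(panel$turnover_pct[3:5], rep(0, 3))
  # empty day: no patients at all after Jan 7 -> test with a window day
  w2 <- calendar_window("2017-01-01", "2017-01-10")
  panel2 <- patient_turnover(daily_census(tbl, w2))
  expect_true(all(is.na(panel2$turnover_pct[8:10])))
  expect_true(all(panel2$turnover_pct <= 200, na.rm = TRUE))
})

test_that("a lone same-day patient yields the 200% turnover ceiling", {
  tbl <- make_stay("A", admit = "2017-01-05", discharge = "2017-01-05")
  panel <- patient_turnover(daily_census(tbl, week1))
  expect_equal(panel$turnover_pct[5], 200)
})

test_that("daily mean PCCL averages PCCL-bearing patients only", {
  tbl <- stays_of(
    make_stay("A", admit = "2017-01-02", discharge = "2017-01-04",
              pccl = 4L),
    make_stay("B", admit = "2017-01-02", discharge = "2017-01-04",
              pccl = 0L),
    make_stay("D", admit = "2017-01-06", discharge = NA, pccl = NA)
  )
  panel <- daily_mean_pccl(tbl, daily_census(tbl, week1))
  expect_equal(panel$mean_pccl[2:4], rep(2, 3))
  expect_equal(panel$n_pccl[2:4], rep(2L, 3))
  # Jan 6-7: only the censored case is present -> census 1, no PCCL
  expect_equal(panel$census[6:7], c(1, 1))
  expect_equal(panel$n_pccl[6:7], c(0L, 0L))
  expect_true(all(is.na(panel$mean_pccl[6:7])))
})

test_that("a constant-PCCL stay propagates its level to every stay day", {
  tbl <- make_stay("A", admit = "2017-01-03", discharge = "2017-01-05",
                   pccl = 3L)
  panel <- daily_mean_pccl(tbl, daily_census(tbl, week1))
  expect_equal(panel$mean_pccl[3:5], rep(3, 3))
})

test_that("sweep census equals the brute-force oracle on random instances", {
  withr::local_seed(424242)
  for (i in 1:200) {
    n_days <- sample(3:60, 1)
    window <- calendar_window("2017-03-01",
                              as.Date("2017-03-01") + n_days - 1)
    tbl <- random_stays(sample(0:40, 1), window,
                        n_hospitals = sample(1:10, 1))
    if (nrow(tbl) == 0) next
    fast <- daily_census(tbl, window)
    slow <- census_bruteforce(tbl, window)
    expect_equal(as.data.frame(fast), as.data.frame(slow),
                 ignore_attr = TRUE)
  }
})

test_that("conservation and recurrence hold on a simulated population", {
  cfg <- small_config(seed = 3L)
  stays <- simulate_population(cfg)
  panel <- daily_census(stays, cfg$window,
                        hospitals = attr(stays, "hospitals"))

  # conservation: total census person-days = total occupied days in window
  end <- dplyr::coalesce(stays$discharge_date, cfg$window$end)
  occupied <- as.integer(pmin(end, cfg$window$end) -
                           pmax(stays$admit_date, cfg$window$start)) + 1L
  expect_equal(sum(panel$census), sum(occupied))

  # recurrence: census(d) = census(d-1) - departures(d-1) + admissions(d)
  by_h <- split(panel, panel$hospital_id)
  for (h in by_h) {
    n <- nrow(h)
    lhs <- h$census[-1]
    rhs <- h$census[-n] - h$discharges_alive[-n] - h$deaths[-n] +
      h$admissions[-1]
    expect_equal(lhs, rhs)
  }

  # panel completeness and bounds
  expect_equal(nrow(panel),
               nrow(attr(stays, "hospitals")) *
                 length(window_days(cfg$window)))
  expect_true(all(panel$census >= panel$admissions))
  expect_true(all(panel$census >= panel$discharges_alive + panel$deaths))
  full <- daily_mean_pccl(stays, patient_turnover(
    capacity_utilization(panel)), cfg$window)
  expect_true(all(full$cu_pct > 0 & full$cu_pct <= 100, na.rm = TRUE))
  expect_true(all(full$turnover_pct >= 0 & full$turnover_pct <= 200,
                  na.rm = TRUE))
  expect_true(all(full$mean_pccl >= 0 & full$mean_pccl <= 4,
                  na.rm = TRUE))
  expect_true(all(full$n_pccl <= full$census))
  # each active hospital attains its own maximum at least once
  atmax <- tapply(full$cu_pct, full$hospital_id,
                  function(x) any(x == 100))
  expect_true(all(atmax))
})

test_that("mean PCCL is invariant to case relabelling and row order", {
  window <- calendar_window("2017-02-01", "2017-02-28")
  withr::local_seed(99)
  tbl <- random_stays(60, window, n_hospitals = 4)
  base <- daily_mean_pccl(tbl, daily_census(tbl, window), window)
  shuffled <- tbl[sample.int(nrow(tbl)), ]
  shuffled$case_id <- sprintf("Z%04d", seq_len(nrow(shuffled)))
  perm <- daily_mean_pccl(shuffled, daily_census(shuffled, window),
                          window)
  expect_equal(base$mean_pccl, perm$mean_pccl)
  expect_equal(base$n_pccl, perm$n_pccl)
})

test_that("empty records with named hospitals give an all-zero panel", {
  empty <- make_stay()[0, ]
  panel <- daily_census(empty, week1, hospitals = c("H1", "H2"))
  expect_equal(nrow(panel), 14)
  expect_true(all(panel$census == 0))
  expect_error(daily_census(empty, week1), "no hospitals")
})
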