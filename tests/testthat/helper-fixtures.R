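# Shared fixtures: hand-built stay tables, scaled-down simulation
# configurations, and a cache of full-scale runs reused across tests.

# One stay record with overridable fields.
make_stay <- function(case_id = "C1", hospital_id = "H1",
                      hospital_type = "small_basic",
                      admit = "2017-01-02", discharge = "2017-01-04",
                      died = FALSE, pccl = 2L, age = 60L,
                      sex = "female") {
  tibble::tibble(
    case_id = case_id, hospital_id = hospital_id,
    hospital_type = hospital_type,
    admit_date = as.Date(admit),
    discharge_date = as.Date(discharge),
    died = died, pccl = as.integer(pccl), age = as.integer(age),
    sex = sex, censored = is.na(as.Date(discharge))
  )
}

stays_of <- function(...) dplyr::bind_rows(...)

week1 <- calendar_window("2017-01-01", "2017-01-07")

# A small mixed-type configuration for fast mechanism tests.
small_config <- function(seed = 1L, ...) {
  sim_config(
    window = calendar_window("2017-01-01", "2017-03-31"),
    hospitals_per_type = c(university = 0L, tertiary = 1L,
                           large_basic = 1L, medium_basic = 1L,
                           small_basic = 2L),
    occupancy_scale = c(university = 988, tertiary = 120,
                        large_basic = 60, medium_basic = 35,
                        small_basic = 15),
    seed = seed,
    ...
  )
}

# Random small stay tables for oracle-equivalence and property tests.
random_stays <- function(n_cases, window, n_hospitals = 3,
                         p_censor_tail = 0.15) {
  n_days <- as.integer(window$end - window$start) + 1L
  admit <- window$start + sample(seq(-10L, n_days - 1L), n_cases,
                                 replace = TRUE)
  los <- stats::rpois(n_cases, 4)
  discharge <- admit + los
  drop <- discharge < window$start
  admit <- admit[!drop]
  discharge <- discharge[!drop]
  n <- length(admit)
  if (n == 0) return(make_stay()[0, ])
  died <- stats::runif(n) < 0.05
  censored <- discharge > window$end
  discharge[censored] <- NA
  died[censored] <- FALSE
  pccl <- sample(0:4, n, replace = TRUE)
  pccl[censored] <- NA
  tibble::tibble(
    case_id = sprintf("C%05d", seq_len(n)),
    hospital_id = sprintf("H%d", sample.int(n_hospitals, n,
                                            replace = TRUE)),
    hospital_type = "small_basic",
    admit_date = admit, discharge_date = as.Date(discharge,
                                                 origin = "1970-01-01"),
    died = died, pccl = as.integer(pccl),
    age = sample(0:100, n, replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE),
    censored = censored
  )
}

# Full-scale default runs are expensive; compute each seed once and share
# across test files.
.run_cache <- new.env(parent = emptyenv())

default_run <- function(seed) {
  key <- as.character(seed)
  if (is.null(.run_cache[[key]])) {
    cfg <- sim_config(seed = as.integer(seed))
    stays <- simulate_population(cfg)
    hosp <- attr(stays, "hospitals")[, c("hospital_id", "hospital_type")]
    panel <- compute_demand_panel(stays, cfg$window, hospitals = hosp)
    .run_cache[[key]] <- list(config = cfg, stays = stays,
                              hospitals = hosp, panel = panel)
  }
  .run_cache[[key]]
}

acceptance_seeds <- function() 1:10
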