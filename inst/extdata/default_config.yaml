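# Default synthetic-population configuration: a one-year national
# general-hospital inpatient population (102 hospitals in 5 classes).
# Every key matches an argument of sim_config(); omitted keys keep the
# package defaults. The window year starts on a Sunday.

window:
  start: "2017-01-01"
  end: "2017-12-31"
  weekend_days: ["Saturday", "Sunday"]

hospitals_per_type:
  university: 5
  tertiary: 39
  large_basic: 19
  medium_basic: 20
  small_basic: 19

# Target median daily census per hospital, by type.
occupancy_scale:
  university: 988
  tertiary: 298
  large_basic: 120
  medium_basic: 71
  small_basic: 19

hospital_size_sdlog: 0.35
admission_rate_scale: 1.0

# Relative admission intensity, Monday..Sunday (mean-normalized).
dow_multipliers:
  Monday: 1.30
  Tuesday: 1.15
  Wednesday: 1.10
  Thursday: 1.05
  Friday: 1.00
  Saturday: 0.70
  Sunday: 0.70

# Relative attractiveness of each weekday as a discharge day.
discharge_dow_multipliers:
  Monday: 1.35
  Tuesday: 1.05
  Wednesday: 1.00
  Thursday: 1.05
  Friday: 1.35
  Saturday: 0.65
  Sunday: 0.55

summer_dip: 0.08
summer_weeks: [20, 35]
yearend_dip: 0.55
yearend_days: 14

# Whole-day length of stay: lognormal(meanlog, sdlog) rounded, with a
# same-day point mass, inflated multiplicatively by PCCL level.
los_meanlog: 1.17
los_sdlog: 0.80
same_day_prob: 0.10

# PCCL case mix (levels 0..4) per hospital type.
pccl_probs:
  university:   [0.528017, 0.014135, 0.124122, 0.177312, 0.156414]
  tertiary:     [0.605628, 0.015371, 0.116475, 0.154728, 0.107798]
  large_basic:  [0.673530, 0.012750, 0.098574, 0.133154, 0.081992]
  medium_basic: [0.730867, 0.013592, 0.090966, 0.104145, 0.060430]
  small_basic:  [0.614503, 0.012544, 0.127678, 0.158036, 0.087239]

pccl_los_link: [1.00, 1.30, 1.80, 2.60, 3.50]

death_prob: 0.02
female_prob: 0.534
age_mean: 55
age_sd: 22
carryover_target: 0.0135

seed: 1
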