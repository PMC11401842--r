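default_nh <- natural_history_config()
default_econ <- econ_config()

test_that("policy validation catches band gaps and bad probabilities at load", {
  expect_error(screening_policy("male", attendance_prob = 1.2),
               "attendance_prob")
  gap <- data.frame(lower = c(3.0, 4.8), upper = c(4.5, 5.5),
                    interval = c(1, 0.25))
  expect_error(screening_policy("male", surveillance_bands = gap), "tile")
  expect_error(screening_policy("male", start_age = 96), "end_age")
  ## sex-specific defaults
  expect_equal(screening_policy("male")$attendance_prob, 0.75)
  expect_equal(screening_policy("female")$attendance_prob, 0.72)
  expect_equal(screening_policy("female")$start_age, 65)
})

test_that("a deterministic scenario is traced event-for-event", {
  ## hand-traced oracle: a 6 cm AAA at the invitation age, no measurement
  ## error, forced attendance, no operative mortality, no rupture risk ->
  ## invite, scan (6.0), referral, elective repair, then life-table death
  nh0 <- natural_history_config(
    growth = growth_params(mean_intercept = log(6), mean_slope = 0,
                           re_cov = matrix(0, 2, 2), measurement_sd = 0),
    rupture = rupture_params(alpha = -500),
    incidental_detection_rate = 0)
  pol0 <- screening_policy("male", invite_age = 65, attendance_prob = 1,
                           elective_30day_mortality = 0)
  tr <- run_person(list(susceptible = TRUE, b0 = log(6), b1 = 0,
                        death_age = 88, attend_u = 0), nh0, pol0, seed = 5)
  expect_identical(tr$type, c("invite", "attend_scan", "referral",
                              "elective_op", "nonaaa_death"))
  expect_equal(tr$age, c(65, 65, 65, 65, 88))
  expect_equal(tr$diameter_observed[2], 6.0)

  ## same but death beyond the end of follow-up: survived_to_end at 95
  tr2 <- run_person(list(susceptible = TRUE, b0 = log(6), b1 = 0,
                         death_age = 99, attend_u = 0), nh0, pol0, seed = 5)
  expect_identical(tr2$type[length(tr2$type)], "survived_to_end")
  expect_equal(tr2$age[length(tr2$age)], 95)
})

test_that("no attendance and no incidental detection produce no clinical events", {
  nh0 <- natural_history_config(incidental_detection_rate = 0)
  pol <- screening_policy("male", invite_age = 62, attendance_prob = 0)
  tr <- run_person(list(susceptible = TRUE, b0 = log(3.4), b1 = 0.02,
                        death_age = 70, attend_u = 0.5,
                        rupture_age = Inf), nh0, pol, seed = 3)
  expect_false(any(tr$type %in% c("attend_scan", "surveillance_scan",
                                  "referral", "elective_op")))
  ## a non-susceptible person with no invitation has a bare trace
  tr2 <- run_person(list(susceptible = FALSE, death_age = 75),
                    default_nh, screening_policy("male"), seed = 4)
  expect_identical(tr2$type, "nonaaa_death")
})

test_that("traces satisfy ordering, terminal-uniqueness and accounting identities", {
  out <- run_cohort(15000, 0.02, default_nh,
                    screening_policy("male", invite_age = 62),
                    default_econ, seed = 9, keep_traces = TRUE)
  terminals <- c("aaa_death", "nonaaa_death", "survived_to_end")
  rupture_deaths <- 0; op_deaths <- 0
  for (tr in out$traces) {
    expect_true(all(diff(tr$age) >= -1e-12)) # non-decreasing ages
    it <- which(tr$type %in% terminals)
    expect_length(it, 1L)
    expect_identical(it, nrow(tr)) # nothing after the terminal event
    ## at most one referral per person; no surveillance or repeat referral
    ## after it
    ref <- which(tr$type == "referral")
    expect_lte(length(ref), 1L)
    if (length(ref) == 1L) {
      later <- tr$type[-seq_len(ref)]
      expect_false(any(later %in% c("surveillance_scan", "referral",
                                    "attend_scan")))
    }
    ## every emergency op follows a rupture at the same age
    eo <- which(tr$type == "emergency_op")
    if (length(eo)) expect_identical(tr$type[eo - 1L], "rupture")
    ## classify AAA deaths
    ad <- which(tr$type == "aaa_death")
    if (length(ad)) {
      prev <- tr$type[ad - 1L]
      expect_true(prev %in% c("rupture", "elective_op", "emergency_op"))
      if (prev == "rupture") rupture_deaths <- rupture_deaths + 1
      else op_deaths <- op_deaths + 1
    }
  }
  ## conservation: terminal states sum to n
  expect_identical(sum(out$terminal), out$n)
  ## accounting: emergency ops cannot exceed ruptures; AAA deaths decompose
  cnt <- out$counts
  expect_lte(cnt[["emergency_ops"]], cnt[["ruptures"]])
  expect_identical(unname(cnt[["aaa_deaths"]]), rupture_deaths + op_deaths)
  expect_lte(cnt[["aaa_deaths"]], cnt[["ruptures"]] + cnt[["elective_ops"]])
})

test_that("cohort runs are reproducible and zero prevalence yields no AAA events", {
  pol <- screening_policy("male", invite_age = 65)
  a <- run_cohort(4000, 0.01, default_nh, pol, default_econ, seed = 3)
  b <- run_cohort(4000, 0.01, default_nh, pol, default_econ, seed = 3)
  expect_equal(a[setdiff(names(a), "policy")], b[setdiff(names(b), "policy")])

  z <- run_cohort(4000, 0, default_nh, pol, default_econ, seed = 3)
  expect_equal(unname(z$counts[c("elective_ops", "emergency_ops", "ruptures",
                                 "aaa_deaths")]), c(0, 0, 0, 0))
})

test_that("events_per_10000 normalises by invited and flags population rates", {
  pol <- screening_policy("male", invite_age = 62)
  out <- run_cohort(5000, 0.01, default_nh, pol, default_econ, seed = 5)
  r <- events_per_10000(out)
  expect_false(attr(r, "population_denominator"))
  expect_equal(r$per_10000, r$count * 1e4 / out$n_invited)

  out0 <- run_cohort(5000, 0.01, default_nh, screening_policy("male"),
                     default_econ, seed = 5)
  r0 <- events_per_10000(out0)
  expect_true(attr(r0, "population_denominator"))
  expect_identical(r0$per_10000[r0$event == "scans"], 0) # no invite: no scans
})

test_that("run_person draws missing natural-history fields reproducibly", {
  pol <- screening_policy("female", invite_age = 70)
  tr1 <- run_person(list(susceptible = TRUE), default_nh, pol, seed = 77)
  tr2 <- run_person(list(susceptible = TRUE), default_nh, pol, seed = 77)
  expect_identical(tr1, tr2)
})
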