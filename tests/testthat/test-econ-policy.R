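test_that("discounting reproduces closed forms", {
  expect_equal(discounted_value(c(60, 61, 62), rep(1, 3), 60, 0), 3)
  expect_equal(discounted_value(61, 1.035, 60, 0.035), 1, tolerance = 1e-12)
  ## 35-year unit annuity at 3.5%
  ann <- discounted_value(60 + 1:35, rep(1, 35), 60, 0.035)
  expect_equal(ann, sum(1.035^-(1:35)), tolerance = 1e-12)
  ## present value strictly decreasing in the rate for positive streams
  expect_gt(discounted_value(60 + 1:35, rep(1, 35), 60, 0.01), ann)
  expect_error(discounted_value(61, 1, 60, -0.01), "nonnegative")
  expect_error(discounted_value(59, 1, 60), ">=")
})

test_that("incremental net benefit is the defining identity", {
  expect_equal(incremental_net_benefit(0.001, 10, 30000), 20)
  expect_equal(incremental_net_benefit(0, 0, 30000), 0)
  expect_lt(incremental_net_benefit(0.001, 40, 30000), 0) # dc > wtp * dq
  expect_error(incremental_net_benefit(0.1, 0, 0), "> 0")
})

test_that("invitation-age optimisation picks the argmax with earliest-age ties", {
  expect_equal(optimize_invitation_age(c(`60` = 5, `62` = 7, `65` = 3)), 62)
  expect_true(is.na(optimize_invitation_age(c(`65` = -2, `70` = -8))))
  expect_equal(optimize_invitation_age(c(`65` = 4, `62` = 4, `70` = 1)), 62)
  expect_error(optimize_invitation_age(numeric(0)), "no candidate")
})

test_that("population INB aggregation is an exact weighted mean", {
  expect_equal(aggregate_population_inb(c(3, 6), c(0.5, 0.5)), 4.5)
  expect_equal(aggregate_population_inb(7.7, 1), 7.7)
  inb <- c(a = 1.2, b = -0.4, c = 5); w <- c(0.2, 0.3, 0.5)
  expect_equal(aggregate_population_inb(inb, w), sum(inb * w))
  perm <- c(3, 1, 2)
  expect_equal(aggregate_population_inb(inb[perm], w[perm]),
               aggregate_population_inb(inb, w))
  expect_error(aggregate_population_inb(c(1, 2), c(0.5, 0.4)), "sum to 1")
})

test_that("population net gain reproduces the published arithmetic", {
  expect_equal(round(population_net_gain(47.28, 11.03, 348000) / 1e6, 1), 12.6)
  expect_equal(round(population_net_gain(40.89, 11.03, 348000) / 1e6, 1), 10.4)
  expect_equal(population_net_gain(5, 5, 1e6), 0)
})

test_that("percent reductions and relative gains round as reported", {
  expect_identical(percent_event_reduction(9229, 5474), 41)
  expect_identical(percent_event_reduction(100, 100), 0)
  expect_identical(percent_event_reduction(100, 0), 100)
  expect_error(percent_event_reduction(0, 1), "> 0")
  expect_equal(relative_gain(0.00530, 0.00432), 22.7, tolerance = 0.05)
})

test_that("PSA intervals have nearest-rank centiles and reproduce", {
  ## degenerate distributions collapse to the point estimate
  spec <- list(m = list(dist = "fixed", value = 4))
  out <- psa_intervals(function(p) p$m, spec, n_samples = 50, seed = 1)
  expect_equal(unname(out[c("lower", "upper")]), c(4, 4))

  ## uniform INB: centiles near 0.05 and 0.95
  uspec <- list(u = list(dist = "uniform", min = 0, max = 1))
  out2 <- psa_intervals(function(p) p$u, uspec, n_samples = 100, seed = 2)
  expect_lt(abs(out2[["lower"]] - 0.05), 0.05)
  expect_lt(abs(out2[["upper"]] - 0.95), 0.05)

  expect_identical(psa_intervals(function(p) p$u, uspec, 100, seed = 7),
                   psa_intervals(function(p) p$u, uspec, 100, seed = 7))
  expect_error(psa_intervals(function(p) 1, list(x = list(mean = 1)), 10, 1),
               "no declared sampling distribution")
  expect_error(psa_intervals(function(p) 1, list(x = list(dist = "cauchy")),
                             10, 1), "unknown distribution")
})

test_that("strategy evaluation aggregates subgroups and prices genotyping linearly", {
  nh <- natural_history_config()
  polt <- screening_policy("male")
  subgroups <- data.frame(
    subgroup = c("low_risk", "high_risk"),
    prevalence = c(0.002, 0.015),
    weight = c(0.7, 0.3))
  strategies <- list(
    current = list(invite_age = c(low_risk = 65, high_risk = 65),
                   uses_prs = FALSE),
    stratified = list(invite_age = c(low_risk = NA, high_risk = 62),
                      uses_prs = TRUE),
    smoking_only = list(invite_age = c(low_risk = NA, high_risk = 65),
                        uses_prs = FALSE))
  run_eval <- function(gcost) {
    econ <- econ_config(genotyping_cost = gcost)
    evaluate_strategies(strategies, subgroups, nh, polt, econ,
                        n = 4000, seed = 11, current = "current",
                        population_size = 348000)
  }
  e0 <- run_eval(0)
  expect_s3_class(e0, "policy_evaluation")
  expect_equal(e0$net_gain[e0$strategy == "current"], 0)
  sub_inb <- attr(e0, "subgroup_inb")
  ## population INB is the exact weighted sum of subgroup INBs
  expect_equal(e0$mean_inb[e0$strategy == "stratified"],
               sum(sub_inb$stratified * subgroups$weight), tolerance = 1e-9)
  expect_equal(unname(sub_inb$stratified["low_risk"]), 0) # no-invite subgroup

  ## genotyping cost: linear decrease for PRS strategies, none otherwise
  e23 <- run_eval(23); e31 <- run_eval(31)
  inb_of <- function(e, s) e$mean_inb[e$strategy == s]
  expect_equal(inb_of(e23, "stratified"), inb_of(e0, "stratified") - 23,
               tolerance = 1e-9)
  expect_equal(inb_of(e31, "stratified"), inb_of(e0, "stratified") - 31,
               tolerance = 1e-9)
  expect_equal(inb_of(e23, "smoking_only"), inb_of(e0, "smoking_only"),
               tolerance = 1e-12)
  ## exact linearity across the three cost points
  slope1 <- (inb_of(e23, "stratified") - inb_of(e0, "stratified")) / 23
  slope2 <- (inb_of(e31, "stratified") - inb_of(e0, "stratified")) / 31
  expect_equal(slope1, slope2, tolerance = 1e-9)

  ## a strategy referencing an unknown subgroup errors by name
  bad <- list(x = list(invite_age = c(low_risk = 65), uses_prs = FALSE))
  expect_error(
    evaluate_strategies(bad, subgroups, nh, polt, econ_config(), n = 100,
                        seed = 1, current = "x"), "high_risk")
})
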