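#' Health-economic configuration
#'
#' Willingness-to-pay, discounting, unit costs and age-dependent utilities
#' used to turn simulated event histories into QALYs, costs and incremental
#' net benefit. The discount rate defaults to 3.5%/yr for both costs and
#' QALYs (UK appraisal convention). Unit costs and utilities are illustrative
#' defaults on the scale of published UK screening evaluations; genotyping is
#' free in the base case, with sensitivity values up to about 31 pounds per
#' test of interest.
#'
#' @param wtp willingness-to-pay per QALY gained (default 30,000; 20,000 is
#'   the usual sensitivity value).
#' @param discount_rate annual discount rate for costs and QALYs.
#' @param costs named numeric vector of unit costs (currency units):
#'   `scan`, `surveillance_scan`, `elective_op`, `emergency_op`.
#' @param utilities data frame with columns `age` (lower bound of the band)
#'   and `utility` (QALY weight per life-year); a step function of age.
#' @param genotyping_cost cost per person of generating a PRS profile,
#'   charged once per strategy arm that uses the PRS.
#' @param genotyping_charge whether the genotyping cost applies to every
#'   `"genotyped"` person (whole population) or only each `"invited"` person.
#' @return A validated list of class `"econ_config"`.
#' @export
econ_config <- function(wtp = 30000,
                        discount_rate = 0.035,
                        costs = c(scan = 50, surveillance_scan = 70,
                                  elective_op = 9500, emergency_op = 14500),
                        utilities = data.frame(
                          age = c(0, 65, 75, 85),
                          utility = c(0.80, 0.78, 0.73, 0.65)),
                        genotyping_cost = 0,
                        genotyping_charge = c("genotyped", "invited")) {
  check_number(wtp, "wtp", lower = 1e-9)
  check_number(discount_rate, "discount_rate", lower = 0)
  need <- c("scan", "surveillance_scan", "elective_op", "emergency_op")
  if (!all(need %in% names(costs))) {
    stop_config("'costs' must name %s", paste(need, collapse = ", "))
  }
  check_number(costs, "costs", lower = 0, len = length(costs))
  if (!all(c("age", "utility") %in% names(utilities))) {
    stop_config("'utilities' needs columns age, utility")
  }
  check_prob(utilities$utility, "utilities$utility", len = nrow(utilities))
  check_number(genotyping_cost, "genotyping_cost", lower = 0)
  genotyping_charge <- match.arg(genotyping_charge)
  utilities <- utilities[order(utilities$age), , drop = FALSE]
  structure(list(wtp = wtp, discount_rate = discount_rate, costs = costs,
                 utilities = utilities, genotyping_cost = genotyping_cost,
                 genotyping_charge = genotyping_charge),
            class = "econ_config")
}

utility_at <- function(econ, age) {
  u <- econ$utilities
  u$utility[pmax(findInterval(age, u$age), 1L)]
}

#' Present value of a dated stream
#'
#' Discounts a stream of amounts at given ages back to `start_age`:
#' `sum(amount * (1 + rate)^-(age - start_age))`. A zero rate returns the
#' plain sum.
#'
#' @param ages event ages (all `>= start_age`).
#' @param amounts amounts attached to each age.
#' @param start_age reference age for discounting.
#' @param rate annual discount rate (>= 0).
#' @return The present value (scalar).
#' @examples
#' discounted_value(61, 1.035, 60, 0.035) # 1
#' @export
discounted_value <- function(ages, amounts, start_age, rate = 0.035) {
  if (rate < 0) stop_config("'rate' must be nonnegative")
  if (length(ages) != length(amounts)) {
    stop_config("'ages' and 'amounts' must have equal length")
  }
  if (any(ages < start_age)) stop_config("all ages must be >= start_age")
  sum(amounts * (1 + rate)^-(ages - start_age))
}

#' Incremental net monetary benefit
#'
#' `INB = wtp * delta_QALY - delta_cost`, versus a comparator (conventionally
#' no invitation).
#'
#' @param dq incremental QALYs per person.
#' @param dc incremental cost per person.
#' @param wtp willingness-to-pay per QALY (> 0).
#' @return INB in currency units per person.
#' @examples
#' incremental_net_benefit(0.001, 10, 30000) # 20
#' @export
incremental_net_benefit <- function(dq, dc, wtp) {
  if (any(wtp <= 0)) stop_config("'wtp' must be > 0")
  wtp * dq - dc
}

#' Optimal invitation age for a subgroup
#'
#' Picks the candidate invitation age with the highest INB; when the best
#' achievable INB is not positive the subgroup is not invited. Ties go to
#' the earliest age.
#'
#' @param inb_by_age named numeric vector: INB (vs no invitation) at each
#'   candidate age; names are the ages.
#' @return The optimal age (numeric) or `NA` for no-invite.
#' @examples
#' optimize_invitation_age(c(`60` = 5, `62` = 7, `65` = 3)) # 62
#' @export
optimize_invitation_age <- function(inb_by_age) {
  if (!length(inb_by_age)) stop_config("no candidate ages supplied")
  if (is.null(names(inb_by_age))) {
    stop_config("'inb_by_age' must be named by candidate age")
  }
  best <- max(inb_by_age)
  if (best <= 0) return(NA_real_)
  ages <- as.numeric(names(inb_by_age))
  min(ages[inb_by_age == best])
}

#' Population-weighted INB
#'
#' Combines subgroup INBs into a population INB by the observed subgroup
#' proportions. Subgroups assigned no invitation contribute an INB of 0
#' (they are identical to the no-invite baseline).
#'
#' @param inb named numeric vector of subgroup INBs (use 0 for no-invite
#'   subgroups).
#' @param weights subgroup weights, same length/order, nonnegative, summing
#'   to 1 (tolerance 1e-9).
#' @return The weighted mean INB.
#' @export
aggregate_population_inb <- function(inb, weights) {
  if (length(inb) != length(weights)) {
    stop_config("'inb' and 'weights' must have equal length")
  }
  if (any(weights < 0)) stop_config("'weights' must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-9) {
    stop_config("'weights' must sum to 1 (got %.12f)", sum(weights))
  }
  sum(inb * weights)
}

#' Population net monetary gain of a strategy
#'
#' `(INB_strategy - INB_current) * population_size`, the total net gain of
#' switching the whole eligible population (e.g. one annual birth cohort at
#' the invitation age) from the current strategy to the proposed one.
#'
#' @param inb_strategy,inb_current per-person population INBs of the two
#'   strategies versus the same no-invite baseline.
#' @param population_size number of people in the eligible population.
#' @return Net gain in currency units (divide by 1e6 for millions).
#' @examples
#' population_net_gain(47.28, 11.03, 348000) / 1e6 # ~12.6
#' @export
population_net_gain <- function(inb_strategy, inb_current, population_size) {
  check_number(population_size, "population_size", lower = 1e-9)
  (inb_strategy - inb_current) * population_size
}

#' Percent reduction in an event rate
#'
#' `round(100 * (rate_reference - rate_strategy) / rate_reference)`, e.g. the
#' percentage reduction in scans relative to the current policy.
#'
#' @param rate_reference reference rate (> 0).
#' @param rate_strategy rate under the evaluated strategy.
#' @return Percent reduction, rounded to the nearest integer.
#' @examples
#' percent_event_reduction(9229, 5474) # 41
#' @export
percent_event_reduction <- function(rate_reference, rate_strategy) {
  if (rate_reference <= 0) stop_config("'rate_reference' must be > 0")
  round(100 * (rate_reference - rate_strategy) / rate_reference)
}

#' Relative improvement of one quantity over another
#'
#' `100 * (value - reference) / reference`, the percent gain of `value` over
#' `reference` (e.g. the relative improvement in explained variance of one
#' risk score over another).
#'
#' @param value improved quantity.
#' @param reference baseline quantity (nonzero).
#' @return Percent improvement (unrounded).
#' @examples
#' relative_gain(0.00530, 0.00432) # ~22.7
#' @export
relative_gain <- function(value, reference) {
  if (reference == 0) stop_config("'reference' must be nonzero")
  100 * (value - reference) / reference
}

#' Probabilistic sensitivity analysis intervals
#'
#' Re-runs an evaluation once per sampled parameter set and returns the
#' nearest-rank 5th and 95th centiles of the resulting INB distribution.
#' Every sampled parameter must declare its sampling distribution:
#' `fixed` (value), `normal` (mean, sd), `lognormal` (meanlog, sdlog),
#' `beta` (shape1, shape2), `gamma` (shape, rate), or `uniform` (min, max).
#'
#' @param runner function taking a named list of sampled parameter values
#'   and returning a scalar INB.
#' @param psa_spec named list; each element is a list with a `dist` field
#'   and that distribution's parameter fields.
#' @param n_samples number of PSA draws (>= 2; 100 by convention).
#' @param seed integer seed.
#' @return Named numeric vector `c(lower, upper, point = median)` of the
#'   empirical 5th/95th centiles (nearest rank) and median, with the full
#'   sample in attribute `"samples"`.
#' @export
psa_intervals <- function(runner, psa_spec, n_samples = 100, seed = 1) {
  if (n_samples < 2) stop_config("'n_samples' must be >= 2")
  set.seed(seed)
  draw_one <- function(spec, nm) {
    if (is.null(spec$dist)) {
      stop_config("parameter '%s' has no declared sampling distribution", nm)
    }
    switch(spec$dist,
      fixed = spec$value,
      normal = stats::rnorm(1, spec$mean, spec$sd),
      lognormal = stats::rlnorm(1, spec$meanlog, spec$sdlog),
      beta = stats::rbeta(1, spec$shape1, spec$shape2),
      gamma = stats::rgamma(1, spec$shape, spec$rate),
      uniform = stats::runif(1, spec$min, spec$max),
      stop_config("unknown distribution '%s' for parameter '%s'",
                  spec$dist, nm)
    )
  }
  vals <- numeric(n_samples)
  for (s in seq_len(n_samples)) {
    params <- lapply(seq_along(psa_spec), function(j) {
      draw_one(psa_spec[[j]], names(psa_spec)[j])
    })
    names(params) <- names(psa_spec)
    vals[s] <- runner(params)
  }
  sorted <- sort(vals)
  lo <- sorted[max(1L, ceiling(0.05 * n_samples))]
  hi <- sorted[max(1L, ceiling(0.95 * n_samples))]
  out <- c(lower = lo, upper = hi, point = stats::median(vals))
  attr(out, "samples") <- vals
  out
}

#' Evaluate a set of population screening strategies
#'
#' Evaluates strategies that assign each subgroup an invitation age (or no
#' invitation) for a single-sex population. Every required (prevalence,
#' invitation age) arm is simulated once against the shared no-invite
#' baseline under common random numbers and reused across strategies. The
#' population INB of a strategy is the subgroup-weighted mean of the
#' subgroup INBs; no-invite subgroups contribute 0. Strategies flagged as
#' using the PRS are charged the genotyping cost (per genotyped person or
#' per invited person, per the [econ_config()] switch).
#'
#' @param strategies named list; each element is a list with fields
#'   `invite_age` (named numeric vector over subgroups; `NA` = no invite)
#'   and `uses_prs` (logical).
#' @param subgroups data frame with columns `subgroup`, `prevalence`,
#'   `weight` (weights sum to 1).
#' @param nh a [natural_history_config()].
#' @param policy_template a [screening_policy()] supplying everything except
#'   the invitation age.
#' @param econ an [econ_config()].
#' @param n individuals simulated per arm.
#' @param seed integer seed (shared across arms: common random numbers).
#' @param current name of the strategy serving as the comparator for net
#'   gain.
#' @param population_size eligible population size for net gain.
#' @return A data frame of class `"policy_evaluation"`, one row per
#'   strategy: `strategy`, `mean_inb`, `mean_qalys`, `mean_costs`,
#'   `net_gain`, plus per-10,000 event rates; subgroup INBs in attribute
#'   `"subgroup_inb"`.
#' @export
evaluate_strategies <- function(strategies, subgroups, nh, policy_template,
                                econ = econ_config(), n = 20000, seed = 1,
                                current = names(strategies)[1],
                                population_size = 1) {
  stopifnot(is.list(strategies), length(strategies) >= 1)
  need <- c("subgroup", "prevalence", "weight")
  if (!all(need %in% names(subgroups))) {
    stop_config("'subgroups' must have columns %s", paste(need, collapse = ", "))
  }
  if (abs(sum(subgroups$weight) - 1) > 1e-9) {
    stop_config("subgroup weights must sum to 1")
  }
  for (nm in names(strategies)) {
    miss <- setdiff(subgroups$subgroup, names(strategies[[nm]]$invite_age))
    if (length(miss)) {
      stop_config("strategy '%s' is missing invitation arm(s) for subgroup(s): %s",
                  nm, paste(miss, collapse = ", "))
    }
  }
  if (!current %in% names(strategies)) {
    stop_config("'current' must name one of the strategies")
  }

  ## simulate each unique (prevalence, invite_age) arm once, plus baselines
  arm_cache <- new.env(parent = emptyenv())
  get_arm <- function(prev, age) {
    key <- sprintf("p%.10f_a%s", prev, if (is.na(age)) "none" else age)
    if (!is.null(arm_cache[[key]])) return(arm_cache[[key]])
    pol <- policy_template
    pol$invite_age <- age
    arm_cache[[key]] <- run_cohort(n, prev, nh, pol, econ, seed)
    arm_cache[[key]]
  }

  rows <- list()
  subgroup_inb <- list()
  for (nm in names(strategies)) {
    strat <- strategies[[nm]]
    inb_g <- qal_g <- cost_g <- numeric(nrow(subgroups))
    counts <- NULL
    n_inv_total <- 0
    for (g in seq_len(nrow(subgroups))) {
      prev <- subgroups$prevalence[g]
      age <- strat$invite_age[[subgroups$subgroup[g]]]
      base <- get_arm(prev, NA)
      if (is.na(age)) {
        inb_g[g] <- 0
        qal_g[g] <- base$mean_qalys
        cost_g[g] <- base$mean_costs
        cnt <- base$counts
      } else {
        arm <- get_arm(prev, age)
        dq <- arm$mean_qalys - base$mean_qalys
        dc <- arm$mean_costs - base$mean_costs
        inb_g[g] <- incremental_net_benefit(dq, dc, econ$wtp)
        qal_g[g] <- arm$mean_qalys
        cost_g[g] <- arm$mean_costs
        cnt <- arm$counts
        n_inv_total <- n_inv_total + subgroups$weight[g] * arm$n_invited
      }
      counts <- if (is.null(counts)) subgroups$weight[g] * cnt
      else counts + subgroups$weight[g] * cnt
    }
    geno <- 0
    if (isTRUE(strat$uses_prs) && econ$genotyping_cost > 0) {
      share <- if (econ$genotyping_charge == "genotyped") 1
      else n_inv_total / n
      geno <- econ$genotyping_cost * share
    }
    pop_inb <- aggregate_population_inb(inb_g, subgroups$weight) - geno
    subgroup_inb[[nm]] <- stats::setNames(inb_g, subgroups$subgroup)
    rates <- counts * 1e4 / max(n_inv_total, 1e-12)
    if (n_inv_total == 0) rates <- counts * 1e4 / n
    rows[[nm]] <- data.frame(
      strategy = nm,
      mean_inb = pop_inb,
      mean_qalys = sum(qal_g * subgroups$weight),
      mean_costs = sum(cost_g * subgroups$weight) + geno,
      scans_per_10000 = rates[["scans"]],
      elective_per_10000 = rates[["elective_ops"]],
      emergency_per_10000 = rates[["emergency_ops"]],
      ruptures_per_10000 = rates[["ruptures"]],
      aaa_deaths_per_10000 = rates[["aaa_deaths"]]
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$net_gain <- population_net_gain(out$mean_inb,
                                      out$mean_inb[out$strategy == current],
                                      population_size)
  attr(out, "subgroup_inb") <- subgroup_inb
  class(out) <- c("policy_evaluation", "data.frame")
  out
}

#' @export
print.policy_evaluation <- function(x, digits = 2, ...) {
  cat("Policy evaluation (per-person INB vs no invitation)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
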