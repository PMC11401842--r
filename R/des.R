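#' Screening policy specification
#'
#' Describes one arm of the screening pathway for a single-sex cohort:
#' whether and when to invite, attendance, surveillance bands, the referral
#' threshold and operative mortality. Surveillance bands must tile the
#' diameter interval from the diagnosis threshold (3.0 cm) to the referral
#' threshold without gaps or overlaps, which is checked at construction so a
#' band gap can never surface mid-simulation.
#'
#' @param sex `"male"` or `"female"`; sets the defaults for `invite_age`,
#'   `attendance_prob` and `start_age` (men are followed from 60, women from
#'   65, both to 95; default attendance 75% men / 72% women).
#' @param invite_age age of the one-off screening invitation, or `NA` for a
#'   no-invite arm.
#' @param attendance_prob probability of attending the invitation scan.
#' @param surveillance_bands data frame with columns `lower`, `upper`
#'   (diameter interval in cm) and `interval` (rescan interval in years);
#'   defaults: 3.0-4.5 cm yearly, 4.5-5.5 cm every 3 months.
#' @param referral_threshold diameter (cm) triggering referral for elective
#'   repair.
#' @param elective_30day_mortality,emergency_30day_mortality 30-day operative
#'   mortality of elective and emergency repair.
#' @param prop_rupture_reaching_surgery proportion of ruptures surviving to
#'   emergency surgery; the remainder die immediately.
#' @param start_age,end_age simulated age window.
#' @param diagnosis_threshold diameter (cm) defining AAA (band tiling is
#'   validated against it).
#' @return A validated list of class `"screening_policy"`.
#' @export
screening_policy <- function(sex = c("male", "female"),
                             invite_age = NA,
                             attendance_prob = NULL,
                             surveillance_bands = data.frame(
                               lower = c(3.0, 4.5),
                               upper = c(4.5, 5.5),
                               interval = c(1.0, 0.25)),
                             referral_threshold = 5.5,
                             elective_30day_mortality = 0.03,
                             emergency_30day_mortality = 0.37,
                             prop_rupture_reaching_surgery = 0.33,
                             start_age = NULL,
                             end_age = 95,
                             diagnosis_threshold = 3.0) {
  sex <- match.arg(sex)
  attendance_prob <- attendance_prob %||% if (sex == "male") 0.75 else 0.72
  start_age <- start_age %||% if (sex == "male") 60 else 65
  check_prob(attendance_prob, "attendance_prob")
  check_prob(elective_30day_mortality, "elective_30day_mortality")
  check_prob(emergency_30day_mortality, "emergency_30day_mortality")
  check_prob(prop_rupture_reaching_surgery, "prop_rupture_reaching_surgery")
  check_number(start_age, "start_age", lower = 0)
  check_number(end_age, "end_age", lower = 0)
  if (start_age >= end_age) stop_config("'start_age' must be below 'end_age'")
  if (!is.na(invite_age)) {
    check_number(invite_age, "invite_age", lower = start_age, upper = end_age)
  }
  b <- surveillance_bands
  if (!all(c("lower", "upper", "interval") %in% names(b))) {
    stop_config("'surveillance_bands' needs columns lower, upper, interval")
  }
  b <- b[order(b$lower), , drop = FALSE]
  if (abs(b$lower[1] - diagnosis_threshold) > 1e-9 ||
      abs(b$upper[nrow(b)] - referral_threshold) > 1e-9 ||
      (nrow(b) > 1 && any(abs(b$upper[-nrow(b)] - b$lower[-1]) > 1e-9))) {
    stop_config(paste0("'surveillance_bands' must tile [%.1f, %.1f) cm ",
                       "contiguously without gaps"), diagnosis_threshold,
                referral_threshold)
  }
  if (any(b$interval <= 0)) stop_config("rescan intervals must be > 0")
  structure(list(sex = sex, invite_age = invite_age,
                 attendance_prob = attendance_prob, surveillance_bands = b,
                 referral_threshold = referral_threshold,
                 elective_30day_mortality = elective_30day_mortality,
                 emergency_30day_mortality = emergency_30day_mortality,
                 prop_rupture_reaching_surgery = prop_rupture_reaching_surgery,
                 start_age = start_age, end_age = end_age,
                 diagnosis_threshold = diagnosis_threshold),
            class = "screening_policy")
}

band_interval <- function(policy, diameter) {
  b <- policy$surveillance_bands
  i <- findInterval(diameter, b$lower)
  b$interval[i]
}

#' Simulate one person through the screening pathway
#'
#' Processes a single individual's event queue in age order: invitation (if
#' the policy assigns one), Bernoulli attendance, observed diameter = latent
#' diameter + measurement error, then discharge (below the diagnosis
#' threshold), band-specific surveillance rescans, or referral and elective
#' repair (at or above the referral threshold) with 30-day operative
#' mortality. Undetected AAAs may rupture (emergency surgery for the fraction
#' reaching it, immediate AAA death otherwise) or be detected incidentally;
#' surveillance is subject to annual dropout; everything is truncated by
#' non-AAA death and the end of the simulated window. Same-age event chains
#' (scan, referral, operation, 30-day operative death) keep their clinical
#' order in the trace.
#'
#' @param person list describing the individual. Recognised fields (missing
#'   ones are drawn from `nh` using `seed`): `susceptible` (logical), `b0`,
#'   `b1` (growth random effects), `death_age` (non-AAA death age),
#'   `rupture_age` (latent rupture age from the unrepaired trajectory),
#'   `attend_u` (uniform draw compared to the attendance probability).
#' @param nh a [natural_history_config()].
#' @param policy a [screening_policy()].
#' @param seed optional integer seed.
#' @return A data frame trace of class `"person_trace"` with columns `age`,
#'   `type`, `diameter_observed` and `origin` (for scan events, whether the
#'   surveillance chain started at the screening invitation or at an
#'   incidental detection); exactly one terminal event (`aaa_death`,
#'   `nonaaa_death` or `survived_to_end`).
#' @export
run_person <- function(person, nh, policy, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  start <- policy$start_age
  end <- policy$end_age
  susceptible <- isTRUE(person$susceptible)
  if (is.null(person$death_age)) {
    person$death_age <- sample_nonaaa_death_age(nh$life_table, policy$sex, start)
  }
  if (susceptible && (is.null(person$b0) || is.null(person$b1))) {
    b <- sample_growth_trajectory(nh$growth, 1)
    person$b0 <- b[1, 1]; person$b1 <- b[1, 2]
  }
  rup <- nh$rupture
  if (policy$sex == "female") {
    rup$sex_multiplier <- rup$sex_multiplier * nh$female_rupture_multiplier
  }
  if (susceptible && is.null(person$rupture_age)) {
    person$rupture_age <- start +
      sample_rupture_time(person$b0, person$b1, rup, horizon = end - start)
  }
  if (is.null(person$attend_u)) person$attend_u <- stats::runif(1)

  death <- person$death_age
  horizon <- min(death, end)
  terminal_type <- if (death <= end) "nonaaa_death" else "survived_to_end"
  msd <- nh$growth$measurement_sd
  thr <- nh$diagnosis_threshold

  latent_d <- function(age) {
    if (!susceptible) return(nh$nonsusceptible_diameter)
    diameter_at(person$b0, person$b1, age - start)
  }
  cross_age <- if (!susceptible) Inf
  else if (exp(person$b0) >= thr) start
  else if (person$b1 <= 0) Inf
  else start + (log(thr) - person$b0) / person$b1

  age_v <- numeric(0); type_v <- character(0); diam_v <- numeric(0)
  orig_v <- character(0)
  add <- function(age, type, diam = NA_real_, origin = NA_character_) {
    age_v[[length(age_v) + 1L]] <<- age
    type_v[[length(type_v) + 1L]] <<- type
    diam_v[[length(diam_v) + 1L]] <<- diam
    orig_v[[length(orig_v) + 1L]] <<- origin
  }

  detected <- FALSE; repaired <- FALSE; under_surv <- FALSE; done <- FALSE
  next_scan <- Inf; dropout_age <- Inf
  ## surveillance chains are tagged with their origin ("screen" for the
  ## invitation scan, "incidental" otherwise) so programme scan counts
  ## exclude monitoring triggered outside systematic screening
  surv_origin <- NA_character_
  rupture_age <- person$rupture_age %||% Inf
  draw_incidental <- function(from) {
    if (nh$incidental_detection_rate <= 0 || cross_age == Inf) return(Inf)
    max(from, cross_age) + stats::rexp(1, nh$incidental_detection_rate)
  }
  incid_age <- draw_incidental(start)
  invite_pending <- !is.na(policy$invite_age) && policy$invite_age < horizon

  process_scan <- function(age, type) {
    obs <- latent_d(age) + if (msd > 0) stats::rnorm(1, 0, msd) else 0
    surv_origin <<- switch(type, attend_scan = "screen",
                           incidental_detection = "incidental",
                           surveillance_scan = surv_origin)
    add(age, type, obs, origin = surv_origin)
    if (obs < thr) {
      if (type != "incidental_detection") add(age, "discharge")
      detected <<- FALSE; under_surv <<- FALSE; next_scan <<- Inf
      incid_age <<- draw_incidental(age)
    } else if (obs >= policy$referral_threshold) {
      add(age, "referral", obs)
      add(age, "elective_op", obs)
      if (stats::runif(1) < policy$elective_30day_mortality) {
        add(age, "aaa_death")
        done <<- TRUE
      } else {
        repaired <<- TRUE; detected <<- TRUE
        under_surv <<- FALSE; next_scan <<- Inf
      }
    } else {
      detected <<- TRUE
      next_scan <<- age + band_interval(policy, obs)
      if (!under_surv) {
        under_surv <<- TRUE
        dropout_age <<- if (nh$surveillance_dropout_rate > 0) {
          age + stats::rexp(1, nh$surveillance_dropout_rate)
        } else Inf
      }
    }
  }

  while (!done) {
    cand <- c(
      rupture = if (!repaired && susceptible) rupture_age else Inf,
      dropout = if (under_surv) dropout_age else Inf,
      invite = if (invite_pending) policy$invite_age else Inf,
      scan = next_scan,
      incidental = if (!detected && !repaired) incid_age else Inf
    )
    nxt <- which.min(cand)
    if (horizon <= cand[nxt]) {
      add(horizon, terminal_type)
      break
    }
    age <- cand[[nxt]]
    switch(names(cand)[nxt],
      rupture = {
        add(age, "rupture")
        if (stats::runif(1) < policy$prop_rupture_reaching_surgery) {
          add(age, "emergency_op")
          if (stats::runif(1) < policy$emergency_30day_mortality) {
            add(age, "aaa_death")
            done <- TRUE
          } else {
            repaired <- TRUE; detected <- TRUE
            under_surv <- FALSE; next_scan <- Inf
          }
        } else {
          add(age, "aaa_death")
          done <- TRUE
        }
      },
      dropout = {
        add(age, "dropout")
        under_surv <- FALSE; next_scan <- Inf; detected <- FALSE
        incid_age <- draw_incidental(age)
      },
      invite = {
        add(age, "invite")
        invite_pending <- FALSE
        ## those already diagnosed (under surveillance) or repaired are not
        ## re-screened by the programme
        if (!detected && !repaired &&
            person$attend_u < policy$attendance_prob) {
          process_scan(age, "attend_scan")
        }
      },
      scan = process_scan(age, "surveillance_scan"),
      incidental = process_scan(age, "incidental_detection")
    )
  }
  out <- data.frame(age = age_v, type = type_v, diameter_observed = diam_v,
                    origin = orig_v)
  class(out) <- c("person_trace", "data.frame")
  out
}

## Discounted cumulative QALY lookup from start_age: returns a function of
## exit ages.  Utilities are a step function of age; mid-year discounting.
qaly_accumulator <- function(econ, start_age, end_age) {
  years <- seq(floor(start_age), ceiling(end_age) - 1)
  u <- utility_at(econ, years + 0.5)
  disc <- (1 + econ$discount_rate)^-(years + 0.5 - start_age)
  val <- u * disc
  ## adjust the first partial year when start_age is fractional
  first_frac <- 1 - (start_age - floor(start_age))
  val[1] <- val[1] * first_frac
  cum <- c(0, cumsum(val))
  function(exit_age) {
    e <- pmin(pmax(exit_age, start_age), end_age)
    f <- floor(e) - years[1]
    frac <- e - floor(e)
    cum[f + 1] + frac * val[pmin(f + 1, length(val))]
  }
}

discount_factor <- function(econ, age, start_age) {
  (1 + econ$discount_rate)^-(age - start_age)
}

## Aggregate one trace into counts and discounted costs.
trace_tally <- function(trace, econ, policy) {
  type <- trace$type
  disc <- discount_factor(econ, trace$age, policy$start_age)
  cost <- numeric(length(type))
  cost[type == "attend_scan"] <- econ$costs[["scan"]]
  cost[type == "surveillance_scan"] <- econ$costs[["surveillance_scan"]]
  cost[type == "incidental_detection"] <- econ$costs[["scan"]]
  cost[type == "elective_op"] <- econ$costs[["elective_op"]]
  cost[type == "emergency_op"] <- econ$costs[["emergency_op"]]
  term <- type %in% c("aaa_death", "nonaaa_death", "survived_to_end")
  list(
    counts = c(invited = sum(type == "invite"),
               scans = sum(type == "attend_scan") +
                 sum(type == "surveillance_scan" &
                       !is.na(trace$origin) & trace$origin == "screen"),
               elective_ops = sum(type == "elective_op"),
               emergency_ops = sum(type == "emergency_op"),
               ruptures = sum(type == "rupture"),
               aaa_deaths = sum(type == "aaa_death")),
    cost = sum(cost * disc),
    exit_age = trace$age[term][1],
    terminal = type[term][1]
  )
}

#' Simulate a screening arm for a cohort
#'
#' Runs [run_person()] over `n` individuals of one sex under a given policy
#' and baseline AAA prevalence at the start age. The susceptible fraction is
#' calibrated with [calibrate_susceptible_fraction()]; non-susceptible
#' individuals (who can experience at most an invitation, a normal scan and
#' non-AAA death) are processed by an equivalent vectorised fast path. All
#' natural-history randomness (susceptibility, growth effects, death age,
#' latent rupture age, attendance draw) is derived from per-person seeds, so
#' two arms run with the same `seed` but different policies share identical
#' natural histories (common random numbers), and raising the prevalence
#' enlarges the susceptible set monotonically.
#'
#' @param n cohort size.
#' @param prevalence baseline AAA prevalence at `policy$start_age`.
#' @param nh a [natural_history_config()].
#' @param policy a [screening_policy()].
#' @param econ an [econ_config()] used for discounted QALYs and costs.
#' @param seed integer seed.
#' @param keep_traces if `TRUE`, attach the individual `person_trace` list
#'   for susceptible individuals (for diagnostics and invariant checks).
#' @return An object of class `"cohort_outcome"`: `n`, `n_invited`, event
#'   `counts`, `mean_qalys`, `mean_costs`, `mean_life_years`,
#'   `terminal` tallies and (optionally) `traces`.
#' @export
run_cohort <- function(n, prevalence, nh, policy, econ = econ_config(),
                       seed = 1, keep_traces = FALSE) {
  check_number(n, "n", lower = 1)
  n <- as.integer(n)
  check_prob(prevalence, "prevalence")
  w <- calibrate_susceptible_fraction(prevalence, nh$growth,
                                      nh$diagnosis_threshold)
  start <- policy$start_age
  end <- policy$end_age
  set.seed(seed)
  u_susc <- stats::runif(n)
  death_age <- sample_nonaaa_death_age(nh$life_table, policy$sex, start, n)
  attend_u <- stats::runif(n)
  eps0 <- stats::rnorm(n, 0, nh$growth$measurement_sd)
  b <- sample_growth_trajectory(nh$growth, n)
  susceptible <- u_susc < w
  person_seeds <- derive_seeds(seed, n)

  qaly_of <- qaly_accumulator(econ, start, end)
  counts <- c(invited = 0, scans = 0, elective_ops = 0, emergency_ops = 0,
              ruptures = 0, aaa_deaths = 0)
  total_cost <- 0
  exit_age <- pmin(death_age, end)
  terminal <- ifelse(death_age <= end, "nonaaa_death", "survived_to_end")

  invite <- policy$invite_age
  has_invite <- !is.na(invite)

  ## --- non-susceptible fast path -------------------------------------
  ns <- which(!susceptible)
  if (length(ns)) {
    if (has_invite) {
      alive_at_invite <- death_age[ns] > invite & invite < end
      inv <- ns[alive_at_invite]
      counts[["invited"]] <- counts[["invited"]] + length(inv)
      att <- inv[attend_u[inv] < policy$attendance_prob]
      obs <- nh$nonsusceptible_diameter + eps0[att]
      abnormal <- att[obs >= nh$diagnosis_threshold]
      normal <- setdiff(att, abnormal)
      counts[["scans"]] <- counts[["scans"]] + length(normal)
      total_cost <- total_cost + length(normal) * econ$costs[["scan"]] *
        discount_factor(econ, invite, start)
      ## a falsely abnormal scan of a normal aorta: fall back to the full
      ## per-person pathway (surveillance of a non-growing 2 cm aorta)
      for (i in abnormal) {
        tr <- run_person(list(susceptible = FALSE, death_age = death_age[i],
                              attend_u = attend_u[i]),
                         nh, policy, seed = person_seeds[i])
        tl <- trace_tally(tr, econ, policy)
        counts <- counts + tl$counts[names(counts)]
        total_cost <- total_cost + tl$cost
      }
    }
  }

  ## --- susceptible individuals ---------------------------------------
  traces <- if (keep_traces) vector("list", sum(susceptible)) else NULL
  si <- which(susceptible)
  for (k in seq_along(si)) {
    i <- si[k]
    person <- list(susceptible = TRUE, b0 = b[i, 1], b1 = b[i, 2],
                   death_age = death_age[i], attend_u = attend_u[i])
    tr <- run_person(person, nh, policy, seed = person_seeds[i])
    tl <- trace_tally(tr, econ, policy)
    counts <- counts + tl$counts[names(counts)]
    total_cost <- total_cost + tl$cost
    exit_age[i] <- tl$exit_age
    terminal[i] <- tl$terminal
    if (keep_traces) traces[[k]] <- tr
  }

  qalys <- qaly_of(exit_age)
  out <- list(
    n = n,
    n_invited = unname(counts[["invited"]]),
    counts = counts[setdiff(names(counts), "invited")],
    terminal = table(factor(terminal, levels = c("aaa_death", "nonaaa_death",
                                                 "survived_to_end"))),
    mean_qalys = mean(qalys),
    mean_costs = total_cost / n,
    mean_life_years = mean(exit_age) - start,
    prevalence = prevalence,
    policy = policy,
    seed = seed
  )
  if (keep_traces) out$traces <- traces
  class(out) <- "cohort_outcome"
  out
}

#' Events per 10,000 invited
#'
#' Normalises the event counts of a [run_cohort()] outcome to rates per
#' 10,000 invited individuals. Under a no-invite policy (zero invited) rates
#' are reported per 10,000 population instead and flagged.
#'
#' @param outcome a `"cohort_outcome"`.
#' @return Data frame with columns `event`, `count`, `per_10000`; attribute
#'   `"population_denominator"` is `TRUE` when the population denominator
#'   was used.
#' @export
events_per_10000 <- function(outcome) {
  stopifnot(inherits(outcome, "cohort_outcome"))
  if (outcome$n <= 0) stop_config("outcome has no individuals")
  pop_denom <- outcome$n_invited == 0
  denom <- if (pop_denom) outcome$n else outcome$n_invited
  out <- data.frame(event = names(outcome$counts),
                    count = as.numeric(outcome$counts),
                    per_10000 = as.numeric(outcome$counts) * 1e4 / denom)
  attr(out, "population_denominator") <- pop_denom
  out
}

#' @export
print.cohort_outcome <- function(x, ...) {
  cat(sprintf("Cohort outcome: n = %d (%s, invite %s), prevalence %.3f%%\n",
              x$n, x$policy$sex,
              if (is.na(x$policy$invite_age)) "none"
              else sprintf("at %g", x$policy$invite_age),
              100 * x$prevalence))
  r <- events_per_10000(x)
  cat(sprintf("  per 10,000 %s:\n",
              if (attr(r, "population_denominator")) "population" else "invited"))
  for (i in seq_len(nrow(r))) {
    cat(sprintf("    %-15s %10.1f\n", r$event[i], r$per_10000[i]))
  }
  cat(sprintf("  mean QALYs %.4f, mean costs %.2f, mean life-years %.3f\n",
              x$mean_qalys, x$mean_costs, x$mean_life_years))
  invisible(x)
}

#' Compare an invitation policy with no invitation
#'
#' Runs the invited arm and a no-invite arm under common random numbers and
#' returns the per-person incremental net benefit.
#'
#' @inheritParams run_cohort
#' @param wtp willingness-to-pay per QALY (taken from `econ` if `NULL`).
#' @return List with `inb`, `delta_qalys`, `delta_costs`, and both
#'   `"cohort_outcome"` objects (`invited`, `no_invite`).
#' @export
compare_with_no_invite <- function(n, prevalence, nh, policy,
                                   econ = econ_config(), seed = 1,
                                   wtp = NULL) {
  wtp <- wtp %||% econ$wtp
  inv <- run_cohort(n, prevalence, nh, policy, econ, seed)
  pol0 <- policy
  pol0$invite_age <- NA
  base <- run_cohort(n, prevalence, nh, pol0, econ, seed)
  dq <- inv$mean_qalys - base$mean_qalys
  dc <- inv$mean_costs - base$mean_costs
  list(inb = incremental_net_benefit(dq, dc, wtp),
       delta_qalys = dq, delta_costs = dc,
       invited = inv, no_invite = base)
}
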