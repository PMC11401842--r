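## Independent oracles used across the test suite.  Each is a deliberately
## naive implementation (grid search, discrete-time simulation, numerical
## inversion) sharing no code with the estimators it checks.

## Grid-search maximiser of the Breslow partial likelihood for a single
## covariate, computed by direct enumeration of risk sets.
cox_grid_oracle <- function(x, entry, exit, d, grid = seq(-5, 5, by = 1e-4)) {
  te <- sort(unique(exit[d]))
  ll <- vapply(grid, function(b) {
    lp <- x * b
    s <- 0
    for (t in te) {
      at_risk <- entry < t & exit >= t
      ev <- d & exit == t
      s <- s + sum(lp[ev]) - sum(ev) * log(sum(exp(lp[at_risk])))
    }
    s
  }, numeric(1))
  grid[which.max(ll)]
}

## Discrete-time per-person competing-risks simulator: marches each person
## forward in steps of dt years with Bernoulli cause-specific events.
## Independent of the inversion sampling used by generate_cohort().
brute_force_cohort <- function(spec, dt = 0.05, seed = 999) {
  set.seed(seed)
  n <- spec$n
  sex <- ifelse(runif(n) < spec$sex_split, "male", "female")
  entry <- runif(n, spec$entry_age_range[1], spec$entry_age_range[2])
  prs <- rnorm(n)
  smoking <- sample(c("never", "ex", "current"), n, TRUE, spec$smoking_probs)
  cuts <- qnorm(c(1, 2) / 3)
  tert <- findInterval(prs, cuts) + 1L
  lp <- c(0, spec$log_hr_tertile)[tert] +
    c(0, spec$log_hr_smoking)[match(smoking, c("never", "ex", "current"))] +
    ifelse(sex == "male", spec$log_hr_male, 0)
  m <- exp(lp)
  lt <- spec$life_table
  qx_rate <- function(sexes, ages) { # annual death hazard by sex/age
    out <- numeric(length(ages))
    for (s in c("female", "male")) {
      idx <- sexes == s
      sub <- lt[lt$sex == s, ]
      q <- sub$qx[match(floor(ages[idx]), sub$age)]
      out[idx] <- -log(pmax(1 - q, 1e-12))
    }
    out
  }
  censor_t <- pmin(spec$censor_age, entry + spec$admin_followup)
  status <- rep("censored", n)
  active <- rep(TRUE, n)
  t_rel <- 0
  max_t <- max(censor_t - entry)
  while (t_rel < max_t && any(active)) {
    t_rel <- t_rel + dt
    idx <- which(active & entry + t_rel <= censor_t)
    if (!length(idx)) break
    age <- entry[idx] + t_rel
    h1 <- spec$baseline_aaa_hazard *
      exp(spec$age_slope * (age - spec$reference_age)) * m[idx]
    h2 <- qx_rate(sex[idx], age)
    u <- runif(length(idx))
    ev1 <- u < h1 * dt
    ev2 <- !ev1 & u < (h1 + h2) * dt
    status[idx[ev1]] <- "aaa_recorded"
    status[idx[ev2]] <- "nonaaa_death"
    active[idx[ev1 | ev2]] <- FALSE
    active[active & entry + t_rel > censor_t] <- FALSE
  }
  data.frame(sex = sex, status = status)
}

## Rupture time by numerical inversion of the cumulative hazard (oracle for
## the thinning sampler): Lambda(t) integrated on a fine grid.
rupture_inversion_oracle <- function(n, b0, b1, rupture, horizon,
                                     step = 0.005) {
  grid <- seq(0, horizon, by = step)
  lam <- rupture$sex_multiplier * exp(rupture$alpha +
                                        rupture$beta * exp(b0 + b1 * grid))
  lam <- pmin(lam, 1e30) # keep the cumulative hazard finite for inversion
  H <- c(0, cumsum((lam[-1] + lam[-length(lam)]) / 2 * diff(grid)))
  E <- rexp(n)
  out <- approx(H, grid, xout = E, ties = "ordered")$y
  out[E > max(H)] <- Inf
  out
}

## Small cohort with default structure for quick model fits.
small_cohort <- function(n = 4000, seed = 123, ...) {
  coh <- generate_cohort(cohort_spec(n = n, seed = seed, ...))
  coh$tertile <- assign_prs_tertiles(coh$prs)
  coh
}
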