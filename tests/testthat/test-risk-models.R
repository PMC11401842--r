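test_that("tertile assignment matches order statistics and handles ties", {
  t1 <- assign_prs_tertiles(1:9)
  expect_identical(as.vector(table(t1)), rep(3L, 3))
  expect_identical(as.character(t1[c(1, 5, 9)]),
                   c("low", "intermediate", "high"))

  ## location invariance
  x <- rnorm(100)
  expect_identical(as.character(assign_prs_tertiles(x)),
                   as.character(assign_prs_tertiles(x + 17.3)))

  ## ties always fall to the lower group
  tied <- assign_prs_tertiles(c(1, 2, 2, 2, 2, 3, 4, 5, 6))
  expect_true(all(tied[2:5] == "low"))

  expect_error(assign_prs_tertiles(rep(1, 10)), "identical")
  expect_error(assign_prs_tertiles(c(1, 2)), "at least 3")
})

test_that("tertile cut points converge to the normal quantiles", {
  set.seed(42)
  x <- rnorm(1e6)
  cp <- attr(assign_prs_tertiles(x), "cut_points")
  expect_lt(abs(cp[1] - qnorm(1 / 3)), 0.01)
  expect_lt(abs(cp[2] - qnorm(2 / 3)), 0.01)
})

test_that("Cox maximiser agrees with a grid-search oracle on a 4-subject dataset", {
  df <- data.frame(entry_age = 0, event_age = 1:4,
                   event_type = "aaa_recorded", x = c(1, 0, 1, 0))
  ## hand-written partial likelihood u/(2u+2) * 1/(u+2) * u/(u+1), u = e^b
  beta_grid <- cox_grid_oracle(df$x, df$entry_age, df$event_age,
                               rep(TRUE, 4))
  fit <- fit_cox_age_scale(~ x, df)
  expect_lt(abs(coef(fit)[["x"]] - beta_grid), 1e-4)

  ## and directly against the closed-form likelihood at the fitted value
  pl <- function(b) {
    u <- exp(b)
    log(u / (2 * u + 2)) + log(1 / (u + 2)) + log(u / (u + 1))
  }
  expect_equal(fit$loglik, pl(coef(fit)[["x"]]), tolerance = 1e-10)
})

test_that("Cox oracle equivalence holds on random small datasets", {
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    df <- data.frame(entry_age = runif(n, 0, 0.5),
                     event_age = runif(n, 1, 5),
                     event_type = sample(c("aaa_recorded", "censored"), n,
                                         TRUE, c(0.7, 0.3)),
                     x = rnorm(n))
    if (sum(df$event_type == "aaa_recorded") < 2) next
    b_grid <- cox_grid_oracle(df$x, df$entry_age, df$event_age,
                              df$event_type == "aaa_recorded")
    if (abs(b_grid) > 4.5) next # near-separation: grid edge
    fit <- fit_cox_age_scale(~ x, df)
    expect_lt(abs(coef(fit)[["x"]] - b_grid), 1e-4)
  }
})

test_that("Cox fit matches survival::coxph with Breslow ties and truncation", {
  skip_if_not_installed("survival")
  coh <- small_cohort(n = 8000, seed = 21)
  fit <- fit_cox_age_scale(~ tertile + smoking + sex, coh)
  ref <- survival::coxph(
    survival::Surv(entry_age, event_age, event_type == "aaa_recorded") ~
      tertile + smoking + sex,
    data = coh, ties = "breslow")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
})

test_that("Cox fit flags degenerate inputs instead of silently failing", {
  df <- data.frame(entry_age = 0, event_age = 1:6,
                   event_type = rep(c("aaa_recorded", "censored"), 3),
                   x = 1)
  expect_error(fit_cox_age_scale(~ x, df), "constant")
  df2 <- df; df2$event_type <- "censored"; df2$x <- rnorm(6)
  expect_error(fit_cox_age_scale(~ x, df2), "no events")
  ## complete separation: covariate perfectly orders the events
  sep <- data.frame(entry_age = 0, event_age = c(1, 2, 3, 10, 11, 12),
                    event_type = c(rep("aaa_recorded", 3), rep("censored", 3)),
                    x = c(5, 5, 5, -5, -5, -5))
  expect_warning(fsep <- fit_cox_age_scale(~ x, sep), "monotone")
  expect_false(fsep$converged)
})

test_that("null Cox model reports the null partial likelihood", {
  df <- data.frame(entry_age = 0, event_age = 1:4,
                   event_type = "aaa_recorded", x = c(1, 0, 1, 0))
  fit0 <- fit_cox_age_scale(~ 1, df)
  expect_length(coef(fit0), 0)
  expect_equal(fit0$loglik, -log(4) - log(3) - log(2), tolerance = 1e-12)
  expect_equal(fit0$loglik, fit0$loglik_null)
})

test_that("Aalen-Johansen matches the hand calculation on the 3-subject example", {
  df <- data.frame(entry_age = 0, event_age = c(1, 2, 3),
                   event_type = c("aaa_recorded", "nonaaa_death", "censored"))
  cf <- aalen_johansen_cif(df)
  expect_equal(cif_at(cf, 3, "aaa_recorded"), 1 / 3, tolerance = 1e-12)
  expect_equal(cif_at(cf, 3, "nonaaa_death"), 1 / 3, tolerance = 1e-12)
  expect_equal(cf$surv[length(cf$surv)], 1 / 3, tolerance = 1e-12)
})

test_that("Aalen-Johansen reduces to Kaplan-Meier with a single cause", {
  set.seed(17)
  n <- 300
  df <- data.frame(entry_age = 0, event_age = rexp(n) + 0.01,
                   event_type = sample(c("aaa_recorded", "censored"), n, TRUE))
  cf <- aalen_johansen_cif(df)
  expect_equal(unname(cf$cif[, "aaa_recorded"]), unname(1 - cf$surv),
               tolerance = 1e-12)
  ## no events at all: CIF identically zero
  df0 <- df; df0$event_type <- "censored"
  cf0 <- aalen_johansen_cif(df0)
  expect_identical(length(cf0$ages), 0L)
  expect_equal(cif_at(cf0, c(1, 5)), c(0, 0))
})

test_that("Aalen-Johansen satisfies surv + sum(CIF) = 1 and matches survfit", {
  skip_if_not_installed("survival")
  set.seed(23)
  n <- 1500
  df <- data.frame(
    entry_age = runif(n, 40, 60),
    x = rexp(n, 0.05))
  df$event_age <- df$entry_age + df$x
  df$event_type <- sample(c("aaa_recorded", "nonaaa_death", "censored"),
                          n, TRUE, c(0.2, 0.4, 0.4))
  cf <- aalen_johansen_cif(df)
  expect_lt(max(abs(cf$surv + rowSums(cf$cif) - 1)), 1e-10)
  st <- factor(df$event_type,
               levels = c("censored", "aaa_recorded", "nonaaa_death"))
  sf <- survival::survfit(
    survival::Surv(entry_age, event_age, st) ~ 1, data = df)
  ref <- sf$pstate[match(cf$ages, sf$time), match("aaa_recorded", sf$states)]
  expect_equal(unname(cf$cif[, "aaa_recorded"]), unname(ref),
               tolerance = 1e-10)
  expect_error(aalen_johansen_cif(transform(df, event_age = entry_age)),
               "exceed")
})

test_that("no-covariate Fine-Gray reproduces the Aalen-Johansen CIF", {
  ## spec 3-subject example
  df <- data.frame(entry_age = 0, event_age = c(1, 2, 3),
                   event_type = c("aaa_recorded", "nonaaa_death", "censored"))
  fg <- fit_fine_gray(~ 1, df)
  expect_equal(fg$cif$cif, 1 / 3, tolerance = 1e-12)

  ## random censored data, with and without left truncation
  set.seed(31)
  for (rep in 1:3) {
    n <- 400
    d <- data.frame(entry_age = if (rep == 1) rep(0, n) else runif(n, 0, 2))
    d$event_age <- d$entry_age + rexp(n, 0.5) + 0.01
    d$event_type <- sample(c("aaa_recorded", "nonaaa_death", "censored"),
                           n, TRUE)
    fg <- fit_fine_gray(~ 1, d)
    aj <- cif_at(aalen_johansen_cif(d), fg$cif$age, "aaa_recorded")
    expect_lt(max(abs(fg$cif$cif - aj)), 1e-8)
  }
})

test_that("Fine-Gray coefficients match cmprsk::crr", {
  skip_if_not_installed("cmprsk")
  set.seed(37)
  n <- 1200
  x <- cbind(z1 = rnorm(n), z2 = rbinom(n, 1, 0.5))
  tt <- rexp(n, exp(0.3 * x[, 1]))
  cause <- 1 + rbinom(n, 1, 0.4)
  cens <- runif(n, 0.2, 4)
  obst <- pmin(tt, cens)
  stat <- ifelse(tt <= cens, cause, 0)
  df <- data.frame(
    entry_age = 0, event_age = obst,
    event_type = c("censored", "aaa_recorded", "nonaaa_death")[stat + 1],
    z1 = x[, 1], z2 = x[, 2])
  fg <- fit_fine_gray(~ z1 + z2, df)
  cr <- cmprsk::crr(obst, stat, x)
  expect_equal(unname(coef(fg)), unname(cr$coef), tolerance = 1e-4)
})

test_that("Fine-Gray recovers a known subdistribution log-hazard ratio", {
  set.seed(41)
  n <- 50000
  x <- rbinom(n, 1, 0.5)
  beta <- 0.7
  p <- 0.15
  eta <- exp(beta * x)
  p1 <- 1 - (1 - p)^eta
  cause <- ifelse(runif(n) < p1, 1, 2)
  V <- runif(n)
  tt <- numeric(n)
  i1 <- cause == 1
  inner <- (1 - V[i1] * p1[i1])^(1 / eta[i1])
  tt[i1] <- -log(1 - (1 - inner) / p)
  tt[!i1] <- rexp(sum(!i1), 0.5)
  cens <- runif(n, 0.5, 6)
  obst <- pmin(tt, cens)
  stat <- ifelse(tt <= cens, cause, 0)
  df <- data.frame(
    entry_age = 0, event_age = obst,
    event_type = c("censored", "aaa_recorded", "nonaaa_death")[stat + 1],
    x = x)
  fg <- fit_fine_gray(~ x, df)
  expect_true(fg$converged)
  expect_lt(abs(coef(fg)[["x"]] - beta), 3 * fg$se[["x"]])

  ## constant covariate is flagged as non-identifiable
  df$z <- 1
  expect_error(fit_fine_gray(~ z, df), "non-identifiable|constant")
})

test_that("scaling factor and subgroup prevalence arithmetic", {
  expect_equal(compute_scaling_factor(0.91, 0.41), 2.2)
  expect_equal(compute_scaling_factor(0.5, 0.5), 1.0)
  expect_equal(compute_scaling_factor(2.0, 0.5), 4.0)
  expect_equal(compute_scaling_factor(0.91, 0.41, digits = NULL),
               0.91 / 0.41, tolerance = 1e-12)
  expect_error(compute_scaling_factor(0.91, 0), "zero")

  tab <- expand.grid(sex = c("female", "male"),
                     smoking = c("never", "ex", "current"),
                     tertile = c("low", "intermediate", "high"),
                     stringsAsFactors = FALSE)
  tab$index_age <- ifelse(tab$sex == "male", 60, 65)
  tab$cif_at_index <- 0.0041
  out <- subgroup_prevalence(tab, 2.2)
  expect_equal(out$prevalence, rep(0.0041 * 2.2, nrow(tab)), tolerance = 1e-12)
  expect_equal(out$prevalence[1], 0.00902, tolerance = 1e-12)
  ## linearity in F
  out2 <- subgroup_prevalence(tab, 4.4)
  expect_equal(out2$prevalence, 2 * out$prevalence, tolerance = 1e-12)
  ## zero CIF stays zero
  tab0 <- tab; tab0$cif_at_index <- 0
  expect_true(all(subgroup_prevalence(tab0, 5)$prevalence == 0))
  ## missing cell reported by name
  expect_error(subgroup_prevalence(tab[-1, ], 2.2), "female never low")
  ## capping warns
  tabc <- tab; tabc$cif_at_index <- 0.9
  expect_warning(capped <- subgroup_prevalence(tabc, 2.2), "capped")
  expect_true(all(capped$prevalence <= 1))
})

test_that("Wald coverage of generating log-HRs is nominal over replicates", {
  ## moderate-n version of the coverage property (the full-scale version
  ## runs in the acceptance suite)
  truth <- log(c(2.13, 3.70, 2.36, 7.74, 4.56))
  hits <- matrix(FALSE, 10, 5)
  for (r in 1:10) {
    coh <- small_cohort(n = 30000, seed = 100 + r)
    fit <- fit_cox_age_scale(~ tertile + smoking + sex, coh)
    ci <- confint(fit)
    hits[r, ] <- truth >= ci[, 1] & truth <= ci[, 2]
  }
  ## with 50 CI checks at nominal 95%, seeing <= 44 hits is very unlikely
  expect_gte(sum(hits), 45)
})
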