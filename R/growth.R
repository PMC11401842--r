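#' Natural-history growth model parameters
#'
#' The aortic diameter of a susceptible individual follows a log-linear
#' growth curve `d(t) = exp(b0 + b1 * t)` (t in years since the index age)
#' with person-level random intercept and slope `(b0, b1)` drawn from a
#' bivariate normal distribution. Observed scan measurements add independent
#' Gaussian error on the centimetre scale; the error never feeds back into
#' the latent state. All default numeric values are illustrative calibration
#' defaults (median diameter about 2.6 cm at the index age among
#' susceptibles with substantial spread, mean relative growth 3%/yr, i.e.
#' about 1 mm/yr at 3 cm), not published estimates.
#'
#' @param mean_intercept mean of `b0` (log cm at the index age).
#' @param mean_slope mean of `b1` (log cm per year).
#' @param re_cov 2x2 symmetric positive semidefinite covariance of
#'   `(b0, b1)`.
#' @param measurement_sd ultrasound measurement error SD (cm).
#' @return A validated list of class `"growth_params"`.
#' @export
growth_params <- function(mean_intercept = log(2.6), mean_slope = 0.03,
                          re_cov = matrix(c(0.40^2, -5e-4, -5e-4, 0.030^2), 2),
                          measurement_sd = 0.2) {
  check_number(mean_intercept, "mean_intercept")
  check_number(mean_slope, "mean_slope")
  if (!is.matrix(re_cov) || !identical(dim(re_cov), c(2L, 2L)) ||
      max(abs(re_cov - t(re_cov))) > 1e-12) {
    stop_config("'re_cov' must be a symmetric 2x2 matrix")
  }
  ev <- eigen(re_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop_config("'re_cov' must be positive semidefinite")
  }
  check_number(measurement_sd, "measurement_sd", lower = 0)
  structure(list(mean_intercept = mean_intercept, mean_slope = mean_slope,
                 re_cov = re_cov, measurement_sd = measurement_sd),
            class = "growth_params")
}

#' Sample person-level growth random effects
#'
#' @param params a [growth_params()].
#' @param n number of individuals.
#' @param seed optional integer seed.
#' @return An `n x 2` matrix with columns `b0`, `b1`.
#' @export
sample_growth_trajectory <- function(params, n = 1, seed = NULL) {
  stopifnot(inherits(params, "growth_params"))
  if (!is.null(seed)) set.seed(seed)
  ev <- eigen(params$re_cov, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2)
  z <- matrix(stats::rnorm(2 * n), n, 2)
  out <- z %*% t(L)
  out[, 1] <- out[, 1] + params$mean_intercept
  out[, 2] <- out[, 2] + params$mean_slope
  colnames(out) <- c("b0", "b1")
  out
}

#' Latent aortic diameter at a given time
#'
#' @param b0,b1 person-level log-scale intercept and slope.
#' @param t years since the index age (>= 0).
#' @return Diameter in cm, `exp(b0 + b1 * t)`.
#' @examples
#' diameter_at(log(3), 0.05, 2) # 3 * exp(0.1)
#' @export
diameter_at <- function(b0, b1, t) {
  if (any(t < 0)) stop_config("'t' must be nonnegative")
  exp(b0 + b1 * t)
}

#' Rupture hazard model parameters
#'
#' The instantaneous rupture hazard is log-linear in the current latent
#' diameter: `lambda(t) = sex_multiplier * exp(alpha + beta * d(t))` per
#' year. Defaults are illustrative calibration values giving about 0.03%/yr
#' at 3 cm, 1.5%/yr at 5.5 cm and about 80%/yr at 8 cm; women are conventionally
#' assigned a multiplier above 1 at the simulation layer to reflect their
#' higher rupture risk at a given diameter.
#'
#' @param alpha log baseline rupture rate (per year) at diameter 0.
#' @param beta log-hazard increase per cm of diameter.
#' @param sex_multiplier dimensionless proportional multiplier.
#' @return A validated list of class `"rupture_params"`.
#' @export
rupture_params <- function(alpha = -13.0, beta = 1.6, sex_multiplier = 1) {
  check_number(alpha, "alpha")
  check_number(beta, "beta")
  check_number(sex_multiplier, "sex_multiplier", lower = 0)
  structure(list(alpha = alpha, beta = beta, sex_multiplier = sex_multiplier),
            class = "rupture_params")
}

rupture_rate <- function(rupture, b0, b1, t) {
  rupture$sex_multiplier * exp(rupture$alpha + rupture$beta *
                                 diameter_at(b0, b1, t))
}

#' Sample a rupture time by thinning
#'
#' Draws the first event of the inhomogeneous Poisson rupture process with
#' rate `lambda(t) = sex_multiplier * exp(alpha + beta * d(t))` along the
#' growth path `d(t) = exp(b0 + b1 t)`, by thinning against a piecewise
#' (yearly segment) constant bounding rate. Returns `Inf` when no rupture
#' occurs before `horizon`.
#'
#' @param b0,b1 growth random effects.
#' @param rupture a [rupture_params()].
#' @param horizon length of the simulation window in years (> 0).
#' @param from start offset (years since the index age) of the window.
#' @param seed optional integer seed.
#' @return Rupture time in years since the index age, or `Inf`.
#' @export
sample_rupture_time <- function(b0, b1, rupture, horizon, from = 0,
                                seed = NULL) {
  stopifnot(inherits(rupture, "rupture_params"))
  if (horizon <= 0) stop_config("'horizon' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  end <- from + horizon
  t <- from
  while (t < end) {
    seg_end <- min(t + 1, end)
    lam_max <- max(rupture_rate(rupture, b0, b1, t),
                   rupture_rate(rupture, b0, b1, seg_end))
    if (!is.finite(lam_max)) {
      stop_config("rupture rate overflows within the horizon (diameter %.1f cm)",
                  diameter_at(b0, b1, seg_end))
    }
    if (lam_max <= 0) { t <- seg_end; next }
    u <- t
    repeat {
      u <- u + stats::rexp(1, rate = lam_max)
      if (u >= seg_end) break
      if (stats::runif(1) <= rupture_rate(rupture, b0, b1, u) / lam_max) {
        return(u)
      }
    }
    t <- seg_end
  }
  Inf
}

#' Calibrate the susceptible mixture fraction
#'
#' The population is a mixture: a fraction `w` of individuals carry an
#' AAA-prone growth trajectory (and may also develop an aneurysm after the
#' index age), the remainder never exceed the diagnostic threshold. Point
#' prevalence at the index age is `w * Pr[d(0) >= threshold]`; since `d(0)`
#' is log-normal this probability has a closed form and the calibration
#' equation is solved exactly for `w`.
#'
#' @param target_prevalence desired point prevalence at the index age,
#'   in `[0, 1)`.
#' @param growth a [growth_params()].
#' @param diagnosis_threshold diagnostic diameter threshold (cm, default 3).
#' @return The susceptible fraction `w` in `[0, 1]`.
#' @export
calibrate_susceptible_fraction <- function(target_prevalence, growth,
                                           diagnosis_threshold = 3.0) {
  check_number(target_prevalence, "target_prevalence", lower = 0, upper = 1)
  if (target_prevalence >= 1) stop_config("'target_prevalence' must be < 1")
  stopifnot(inherits(growth, "growth_params"))
  if (target_prevalence == 0) return(0)
  sd0 <- sqrt(growth$re_cov[1, 1])
  p_exceed <- if (sd0 == 0) {
    as.numeric(exp(growth$mean_intercept) >= diagnosis_threshold)
  } else {
    1 - stats::pnorm((log(diagnosis_threshold) - growth$mean_intercept) / sd0)
  }
  if (p_exceed <= 0 || target_prevalence > p_exceed) {
    stop_config(paste0("target prevalence %.4f unreachable: maximum ",
                       "attainable under these growth parameters is %.4f"),
                target_prevalence, p_exceed)
  }
  target_prevalence / p_exceed
}

#' Natural-history configuration for the simulation
#'
#' Bundles the growth model, rupture model, life table and detection/dropout
#' rates. All rates are per year; the diagnosis threshold of 3.0 cm is the
#' standard definition of AAA (abdominal aorta larger than 3 cm).
#'
#' @param growth a [growth_params()].
#' @param rupture a [rupture_params()] (male reference).
#' @param life_table a life table (see [make_life_table()]).
#' @param incidental_detection_rate per-year rate of opportunistic detection
#'   of an undiagnosed AAA outside systematic screening.
#' @param surveillance_dropout_rate per-year rate of dropping out of
#'   surveillance.
#' @param diagnosis_threshold diameter (cm) defining AAA.
#' @param nonsusceptible_diameter latent aortic diameter (cm) of
#'   non-susceptible individuals.
#' @param female_rupture_multiplier extra rupture-hazard multiplier applied
#'   to women.
#' @return A validated list of class `"natural_history_config"`.
#' @export
natural_history_config <- function(growth = growth_params(),
                                   rupture = rupture_params(),
                                   life_table = make_life_table(),
                                   incidental_detection_rate = 0.05,
                                   surveillance_dropout_rate = 0.02,
                                   diagnosis_threshold = 3.0,
                                   nonsusceptible_diameter = 2.0,
                                   female_rupture_multiplier = 1.5) {
  stopifnot(inherits(growth, "growth_params"),
            inherits(rupture, "rupture_params"))
  life_table <- validate_life_table(life_table)
  check_number(incidental_detection_rate, "incidental_detection_rate", lower = 0)
  check_number(surveillance_dropout_rate, "surveillance_dropout_rate", lower = 0)
  check_number(diagnosis_threshold, "diagnosis_threshold", lower = 0)
  check_number(nonsusceptible_diameter, "nonsusceptible_diameter", lower = 0,
               upper = diagnosis_threshold)
  check_number(female_rupture_multiplier, "female_rupture_multiplier", lower = 0)
  structure(list(growth = growth, rupture = rupture, life_table = life_table,
                 incidental_detection_rate = incidental_detection_rate,
                 surveillance_dropout_rate = surveillance_dropout_rate,
                 diagnosis_threshold = diagnosis_threshold,
                 nonsusceptible_diameter = nonsusceptible_diameter,
                 female_rupture_multiplier = female_rupture_multiplier),
            class = "natural_history_config")
}
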