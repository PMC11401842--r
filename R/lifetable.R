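#' Construct a synthetic period life table
#'
#' Builds an annual life table (age, sex, qx) from a Gompertz-Makeham annual
#' mortality hazard, `h(age) = makeham + a * exp(b * age)`, converted to annual
#' death probabilities `qx = 1 - exp(-h)`. The defaults approximate recent UK
#' all-cause mortality at the ages relevant to AAA screening (roughly 0.8% at
#' 60 and 6% at 80 in men, with lower female rates). `qx` is forced to 1 at the
#' terminal age so every sampled lifetime is finite.
#'
#' @param min_age,max_age integer age range covered (terminal row has qx = 1).
#' @param makeham age-independent annual hazard component.
#' @param a_male,a_female Gompertz level parameters by sex.
#' @param b Gompertz log-hazard slope per year of age.
#' @return A data frame with columns `age`, `sex` (`"female"`/`"male"`) and
#'   `qx`, one row per age and sex, of class `c("life_table", "data.frame")`.
#' @examples
#' lt <- make_life_table()
#' subset(lt, age == 65)
#' @export
make_life_table <- function(min_age = 40, max_age = 105, makeham = 2e-4,
                            a_male = 1.9e-5, a_female = 1.2e-5, b = 0.101) {
  check_number(min_age, "min_age", lower = 0)
  check_number(max_age, "max_age", lower = min_age + 1)
  ages <- seq(min_age, max_age)
  qx_for <- function(a) {
    h <- makeham + a * exp(b * ages)
    q <- 1 - exp(-h)
    q[length(q)] <- 1
    pmin(q, 1)
  }
  out <- rbind(
    data.frame(age = ages, sex = "female", qx = qx_for(a_female)),
    data.frame(age = ages, sex = "male", qx = qx_for(a_male))
  )
  validate_life_table(out)
}

#' Read a life table from delimited text
#'
#' Expects a CSV with header columns `age`, `sex`, `qx` (annual death
#' probability), one row per age and sex.
#'
#' @param path path to a CSV file.
#' @return A validated `life_table` data frame.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop_config("life table file '%s' does not exist", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_life_table(df)
}

#' @rdname read_life_table
#' @param df a data frame with columns `age`, `sex`, `qx`.
#' @export
validate_life_table <- function(df) {
  need <- c("age", "sex", "qx")
  if (!all(need %in% names(df))) {
    stop_config("life table must have columns %s", paste(need, collapse = ", "))
  }
  if (!all(df$sex %in% c("female", "male"))) {
    stop_config("life table 'sex' must be 'female' or 'male'")
  }
  check_prob(df$qx, "qx", len = nrow(df))
  for (s in unique(df$sex)) {
    a <- sort(df$age[df$sex == s])
    if (any(diff(a) != 1)) {
      stop_config("life table ages for sex '%s' must be contiguous", s)
    }
    if (df$qx[df$sex == s & df$age == max(a)] < 1) {
      stop_config("life table must have qx = 1 at the terminal age (sex '%s')", s)
    }
  }
  class(df) <- unique(c("life_table", class(df)))
  df
}

## Annual qx vector for one sex, from `from_age` (integer) to terminal age.
lt_qx <- function(life_table, sex, from_age) {
  sub <- life_table[life_table$sex == sex, , drop = FALSE]
  sub <- sub[order(sub$age), , drop = FALSE]
  if (from_age < min(sub$age)) {
    stop_config("life table does not cover age %.1f (sex '%s')", from_age, sex)
  }
  sub[sub$age >= from_age, , drop = FALSE]
}

#' Sample age at non-AAA death from a life table
#'
#' Draws the year of death by successive annual Bernoulli trials with the
#' life-table probabilities `qx`, starting in the year containing
#' `current_age`, then places the death uniformly within that year (annual
#' tables carry no sub-year information). Deaths never exceed the terminal
#' age, where `qx = 1`.
#'
#' @param life_table a `life_table` data frame (see [make_life_table()]).
#' @param sex `"female"` or `"male"`.
#' @param current_age age (years) from which survival is simulated; must be
#'   covered by the table.
#' @param n number of independent draws.
#' @param seed optional integer seed for reproducibility.
#' @return Numeric vector of `n` death ages, each `> current_age`.
#' @examples
#' lt <- make_life_table()
#' mean(sample_nonaaa_death_age(lt, "male", 65, n = 1000, seed = 1))
#' @export
sample_nonaaa_death_age <- function(life_table, sex, current_age, n = 1,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_number(current_age, "current_age", lower = 0)
  sub <- lt_qx(life_table, sex, floor(current_age))
  qx <- sub$qx
  ages <- sub$age
  ## P(death in year k) = prod_{j<k}(1-q_j) * q_k; terminal qx = 1 closes it.
  surv <- cumprod(1 - qx)
  pk <- qx * c(1, surv[-length(surv)])
  cdf <- cumsum(pk)
  u <- stats::runif(n)
  k <- findInterval(u, cdf, left.open = TRUE) + 1L
  k <- pmin(k, length(ages))
  lo <- pmax(ages[k], current_age)
  hi <- ages[k] + 1
  lo + stats::runif(n) * (hi - lo)
}
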