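#' Scaling factor between observed and modelled prevalence
#'
#' The cohort outcome definition (hospital-recorded AAA) captures only a
#' fraction of the AAAs a systematic ultrasound screening programme would
#' observe. The ratio of the screening-programme prevalence to the
#' cohort-modelled prevalence in men at the screening age is used as a
#' multiplicative scaling factor `F` to inflate cohort CIFs to population
#' prevalences; the same `F` is applied to women, for whom no screening
#' benchmark exists.
#'
#' @param p_reference prevalence observed in the reference screening
#'   programme (any scale, e.g. percent, as long as both arguments share it).
#' @param p_model prevalence modelled in the cohort, same scale.
#' @param digits rounding applied to the ratio (default 1 decimal place);
#'   `NULL` for no rounding.
#' @return The scaling factor `F = p_reference / p_model`.
#' @examples
#' compute_scaling_factor(0.91, 0.41) # 2.2
#' @export
compute_scaling_factor <- function(p_reference, p_model, digits = 1) {
  check_number(p_reference, "p_reference")
  check_number(p_model, "p_model")
  if (p_reference <= 0 || p_model < 0) {
    stop_config("prevalences must be positive")
  }
  if (p_model == 0) stop_config("p_model is zero: scaling factor undefined")
  f <- p_reference / p_model
  if (!is.null(digits)) f <- round(f, digits)
  f
}

#' Subgroup prevalence from CIFs and a scaling factor
#'
#' Converts subgroup CIFs at the index age (60 for men, 65 for women) into
#' baseline prevalences for the simulation by multiplying with the scaling
#' factor `F` from [compute_scaling_factor()]. Prevalences are capped at 1
#' with a warning. Every sex x smoking x tertile cell must be present.
#'
#' @param cif_table data frame with columns `sex`, `smoking`, `tertile`,
#'   `index_age`, `cif_at_index`.
#' @param scaling_factor positive scalar `F`.
#' @return The input with an added `scaling_factor` and `prevalence` column
#'   (`prevalence = cif_at_index * F`).
#' @export
subgroup_prevalence <- function(cif_table, scaling_factor) {
  check_number(scaling_factor, "scaling_factor", lower = 1e-12)
  need <- c("sex", "smoking", "tertile", "index_age", "cif_at_index")
  if (!all(need %in% names(cif_table))) {
    stop_config("cif_table must have columns %s", paste(need, collapse = ", "))
  }
  check_prob(cif_table$cif_at_index, "cif_at_index", len = nrow(cif_table))
  full <- expand.grid(sex = c("female", "male"),
                      smoking = c("never", "ex", "current"),
                      tertile = c("low", "intermediate", "high"),
                      stringsAsFactors = FALSE)
  have <- paste(cif_table$sex, cif_table$smoking, cif_table$tertile)
  missing_cells <- setdiff(paste(full$sex, full$smoking, full$tertile), have)
  if (length(missing_cells)) {
    stop_config("missing subgroup cell(s): %s",
                paste(missing_cells, collapse = "; "))
  }
  prev <- cif_table$cif_at_index * scaling_factor
  if (any(prev > 1)) {
    warning("prevalence capped at 1 for ", sum(prev > 1), " subgroup(s)",
            call. = FALSE)
    prev <- pmin(prev, 1)
  }
  out <- cif_table
  out$scaling_factor <- scaling_factor
  out$prevalence <- prev
  out
}

#' Estimate subgroup CIFs at the index age from a cohort
#'
#' Convenience wrapper: assigns empirical PRS tertiles, then estimates the
#' Aalen-Johansen CIF of recorded AAA within each sex x smoking x tertile
#' cell and evaluates it at the sex-specific index age (60 in men, 65 in
#' women by default, per the screening programme start ages).
#'
#' @param cohort an `aaa_cohort` data frame.
#' @param index_ages named vector of index ages by sex.
#' @return Data frame suitable for [subgroup_prevalence()].
#' @export
estimate_subgroup_cifs <- function(cohort,
                                   index_ages = c(male = 60, female = 65)) {
  tert <- assign_prs_tertiles(cohort$prs)
  grid <- expand.grid(sex = c("female", "male"),
                      smoking = c("never", "ex", "current"),
                      tertile = c("low", "intermediate", "high"),
                      stringsAsFactors = FALSE)
  grid$index_age <- index_ages[grid$sex]
  grid$cif_at_index <- NA_real_
  for (i in seq_len(nrow(grid))) {
    sel <- cohort$sex == grid$sex[i] & cohort$smoking == grid$smoking[i] &
      tert == grid$tertile[i]
    if (!any(sel)) next
    cf <- aalen_johansen_cif(cohort[sel, , drop = FALSE])
    grid$cif_at_index[i] <- cif_at(cf, grid$index_age[i], "aaa_recorded")
  }
  grid
}
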