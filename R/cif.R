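#' Aalen-Johansen cumulative incidence estimation
#'
#' Nonparametric cumulative incidence functions (CIFs) for competing events
#' on the age scale, supporting left truncation. The overall survival is the
#' product-limit estimator over all-cause events; the CIF of cause `k`
#' accumulates increments `S(t-) * d_k(t) / n(t)` at each event age. At every
#' event age `survival + sum of CIFs = 1` holds identically.
#'
#' @param data data frame with the columns named below.
#' @param entry,exit names of the entry-age and exit-age columns.
#' @param status name of the event column; values other than the named causes
#'   are treated as censoring.
#' @param causes character (or numeric) values of `status` identifying the
#'   competing causes.
#' @return An object of class `"cif_estimate"`: `ages` (sorted event ages),
#'   `cif` (matrix, one column per cause), `surv`, `n_risk`, `n_event`.
#' @examples
#' df <- data.frame(entry_age = 0, event_age = c(1, 2, 3),
#'                  event_type = c("aaa_recorded", "nonaaa_death", "censored"))
#' cf <- aalen_johansen_cif(df)
#' cif_at(cf, 3, "aaa_recorded")
#' @export
aalen_johansen_cif <- function(data, entry = "entry_age", exit = "event_age",
                               status = "event_type",
                               causes = c("aaa_recorded", "nonaaa_death")) {
  if (nrow(data) < 1L) stop_config("need at least one record")
  ent <- data[[entry]]
  ext <- data[[exit]]
  st <- as.character(data[[status]])
  if (any(ext <= ent)) stop_config("all exit ages must exceed entry ages")
  causes <- as.character(causes)
  is_event <- st %in% causes
  te <- sort(unique(ext[is_event]))
  K <- length(causes)
  if (length(te) == 0L) {
    out <- list(ages = numeric(0),
                cif = matrix(0, 0, K, dimnames = list(NULL, causes)),
                surv = numeric(0), n_risk = numeric(0),
                n_event = matrix(0, 0, K), causes = causes)
    class(out) <- "cif_estimate"
    return(out)
  }
  sorted_exit <- sort(ext)
  sorted_entry <- sort(ent)
  n <- length(ext)
  n_risk <- (n - count_less_than(te, sorted_exit)) -
    (n - count_less_than(te, sorted_entry))
  d_k <- vapply(causes, function(cc) {
    tabulate(match(ext[st == cc], te), nbins = length(te))
  }, numeric(length(te)))
  d_k <- matrix(d_k, ncol = K, dimnames = list(NULL, causes))
  d_tot <- rowSums(d_k)
  surv <- cumprod(1 - d_tot / n_risk)
  s_minus <- c(1, surv[-length(surv)])
  cif <- apply(d_k, 2, function(dk) cumsum(s_minus * dk / n_risk))
  cif <- matrix(cif, ncol = K, dimnames = list(NULL, causes))
  out <- list(ages = te, cif = cif, surv = surv, n_risk = n_risk,
              n_event = d_k, causes = causes)
  class(out) <- "cif_estimate"
  out
}

#' Evaluate a CIF step function
#'
#' @param object a `"cif_estimate"`.
#' @param age ages at which to evaluate.
#' @param cause which cause; defaults to the first.
#' @return CIF values (right-continuous step function; 0 before the first
#'   event age).
#' @export
cif_at <- function(object, age, cause = object$causes[1]) {
  stopifnot(inherits(object, "cif_estimate"))
  cause <- as.character(cause)
  if (!cause %in% object$causes) stop_config("unknown cause '%s'", cause)
  if (length(object$ages) == 0L) return(rep(0, length(age)))
  vals <- c(0, object$cif[, cause])
  vals[findInterval(age, object$ages) + 1L]
}

#' @export
print.cif_estimate <- function(x, ...) {
  cat(sprintf("Aalen-Johansen CIF estimate: %d event ages, causes: %s\n",
              length(x$ages), paste(x$causes, collapse = ", ")))
  if (length(x$ages)) {
    last <- length(x$ages)
    cat(sprintf("  at age %.2f: surv = %.4f, %s\n", x$ages[last], x$surv[last],
                paste(sprintf("CIF[%s] = %.4f", x$causes, x$cif[last, ]),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
plot.cif_estimate <- function(x, causes = x$causes, xlab = "Age (years)",
                              ylab = "Cumulative incidence", ...) {
  if (length(x$ages) == 0L) stop_config("nothing to plot: no events")
  graphics::plot(NA, xlim = range(x$ages), ylim = c(0, max(x$cif)),
                 xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(causes)) {
    graphics::lines(stats::stepfun(x$ages, c(0, x$cif[, causes[i]])),
                    col = i, do.points = FALSE)
  }
  graphics::legend("topleft", legend = causes, col = seq_along(causes),
                   lty = 1, bty = "n")
  invisible(x)
}
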