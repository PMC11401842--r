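#' Cox proportional hazards regression on the age time-scale
#'
#' Fits a Cox model by maximising the left-truncated partial likelihood with
#' Breslow handling of tied event ages. Age is the time-scale: an individual
#' is in the risk set at event age `t` when `entry_age < t <= exit_age`, which
#' implements delayed entry. Non-AAA deaths and administrative censoring are
#' treated as censoring (the cause-specific hazard model). Newton-Raphson
#' iterations stop when the score sup-norm falls below `gtol`.
#'
#' @param formula one-sided formula giving the covariates, e.g.
#'   `~ tertile + smoking + sex`. An intercept is never included.
#' @param data data frame containing the covariates and the columns named by
#'   `entry`, `exit` and `status`.
#' @param entry,exit names of the entry-age and exit-age columns.
#' @param status name of the event column.
#' @param event value of `status` counting as the event of interest; all
#'   other values are censoring.
#' @param standardise optional character vector of numeric covariates to
#'   centre and scale to unit variance in the analysis sample before fitting
#'   (used for per-SD hazard ratios).
#' @param gtol convergence tolerance on the score sup-norm.
#' @param maxiter maximum Newton-Raphson iterations.
#' @return An object of class `"cox_age_fit"` with components `coef`, `se`,
#'   `vcov`, `loglik`, `loglik_null`, `converged`, `iter`, `n`, `nevent`.
#'   Standard methods (`print`, `summary`, `coef`, `vcov`, `confint`,
#'   `logLik`) are available; `summary` reports hazard ratios with 95% Wald
#'   intervals `exp(coef +/- 1.96 se)`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n = 5000, seed = 7))
#' coh$tertile <- assign_prs_tertiles(coh$prs)
#' fit <- fit_cox_age_scale(~ tertile + smoking + sex, coh)
#' summary(fit)
#' @export
fit_cox_age_scale <- function(formula, data,
                              entry = "entry_age", exit = "event_age",
                              status = "event_type", event = "aaa_recorded",
                              standardise = NULL, gtol = 1e-8, maxiter = 30L) {
  stopifnot(is.data.frame(data))
  for (col in c(entry, exit, status)) {
    if (!col %in% names(data)) stop_config("column '%s' not found in data", col)
  }
  if (!is.null(standardise)) {
    for (col in standardise) {
      v <- data[[col]]
      if (!is.numeric(v)) stop_config("cannot standardise non-numeric '%s'", col)
      data[[col]] <- (v - mean(v)) / stats::sd(v)
    }
  }
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  X <- stats::model.matrix(formula, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  ent <- data[[entry]]
  ext <- data[[exit]]
  st <- data[[status]]
  d <- if (is.numeric(st)) st == event else as.character(st) == as.character(event)
  keep <- stats::complete.cases(X) & !is.na(ent) & !is.na(ext) & !is.na(d)
  X <- X[keep, , drop = FALSE]; ent <- ent[keep]; ext <- ext[keep]; d <- d[keep]
  if (any(ext <= ent)) stop_config("all exit ages must exceed entry ages")
  if (!any(d)) stop_config("no events of type '%s' in the data", event)
  if (ncol(X) > 0) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      stop_config("covariate(s) constant in the sample: %s",
                  paste(colnames(X)[sds == 0], collapse = ", "))
    }
  }
  fit <- cox_breslow_core(X, ent, ext, d, gtol = gtol, maxiter = maxiter)
  fit$call <- match.call()
  fit$event <- event
  class(fit) <- "cox_age_fit"
  fit
}

## Newton-Raphson maximiser of the Breslow partial likelihood with delayed
## entry.  Risk-set sums at every event time are obtained from suffix sums of
## exit-sorted and entry-sorted weighted covariate columns, so each iteration
## is O(n log n) regardless of the number of event times.
cox_breslow_core <- function(X, entry, exit, d, gtol = 1e-8, maxiter = 30L,
                             offset = NULL) {
  n <- length(exit)
  p <- ncol(X)
  te <- sort(unique(exit[d]))
  D <- length(te)
  ev_idx <- match(exit[d], te)
  dt <- tabulate(ev_idx, nbins = D)
  if (p > 0) {
    sum_x_events <- rowsum(X[d, , drop = FALSE], group = ev_idx)
  }
  ord_exit <- order(exit)
  ord_entry <- order(entry)
  cnt_exit <- count_less_than(te, exit[ord_exit])
  cnt_entry <- count_less_than(te, entry[ord_entry])
  ## column layout: [S0 | S1 (p) | S2 upper-triangle pairs]; reorder the
  ## covariate products once so each iteration is pure vector arithmetic
  if (p > 0) {
    pr <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
    XP <- X[, pr[, 1], drop = FALSE] * X[, pr[, 2], drop = FALSE]
    base_cols <- cbind(1, X, XP)
  } else {
    base_cols <- matrix(1, n, 1)
  }
  M <- ncol(base_cols)
  base_exit <- base_cols[ord_exit, , drop = FALSE]
  base_entry <- base_cols[ord_entry, , drop = FALSE]

  eval_at <- function(beta) {
    lp <- if (p > 0) drop(X %*% beta) else numeric(n)
    if (!is.null(offset)) lp <- lp + offset
    w <- exp(lp)
    w_exit <- w[ord_exit]
    w_entry <- w[ord_entry]
    risk_sums <- matrix(0, D, M)
    for (j in seq_len(M)) {
      ## sum over risk set \{entry < t <= exit\} as a difference of prefix sums
      pe <- cumsum(base_exit[, j] * w_exit)
      pn <- cumsum(base_entry[, j] * w_entry)
      risk_sums[, j] <- (pe[n] - prefix_at(pe, cnt_exit)) -
        (pn[n] - prefix_at(pn, cnt_entry))
    }
    S0 <- risk_sums[, 1]
    ll <- sum(lp[d]) - sum(dt * log(S0))
    if (p == 0) return(list(ll = ll))
    S1 <- risk_sums[, 2:(p + 1), drop = FALSE]
    S2p <- risk_sums[, (p + 2):M, drop = FALSE]
    E1 <- S1 / S0
    U <- colSums(sum_x_events) - colSums(dt * E1)
    I <- matrix(0, p, p)
    t1 <- colSums(S2p * (dt / S0))
    I[cbind(pr[, 1], pr[, 2])] <- t1
    I[cbind(pr[, 2], pr[, 1])] <- t1
    T2 <- crossprod(E1 * sqrt(dt))
    I <- I - T2
    list(ll = ll, U = U, I = I)
  }

  null_ll <- eval_at(rep(0, max(p, 1))[seq_len(p)])$ll
  if (p == 0) {
    return(list(coef = stats::setNames(numeric(0), character(0)),
                se = numeric(0), vcov = matrix(0, 0, 0),
                loglik = null_ll, loglik_null = null_ll,
                converged = TRUE, iter = 0L, n = n, nevent = sum(d)))
  }

  beta <- rep(0, p)
  cur <- eval_at(beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxiter)) {
    if (max(abs(cur$U)) < gtol) { converged <- TRUE; break }
    step <- tryCatch(solve(cur$I, cur$U), error = function(e) {
      stop_config(paste0("information matrix is singular: a covariate is ",
                         "constant within the event risk sets"))
    })
    new_beta <- beta + step
    nxt <- eval_at(new_beta)
    halvings <- 0L
    while ((!is.finite(nxt$ll) || nxt$ll < cur$ll - 1e-12) && halvings < 20L) {
      step <- step / 2
      new_beta <- beta + step
      nxt <- eval_at(new_beta)
      halvings <- halvings + 1L
    }
    beta <- new_beta
    cur <- nxt
  }
  if (max(abs(cur$U)) < gtol) converged <- TRUE
  ## monotone likelihood check: a per-SD log hazard ratio beyond 10 means
  ## the likelihood is still climbing towards an infinite coefficient
  sdX <- apply(X, 2, stats::sd)
  if (any(abs(beta) * pmax(sdX, 1e-12) > 10)) {
    converged <- FALSE
    warning("possible monotone partial likelihood (complete separation); ",
            "coefficients are not reliable", call. = FALSE)
  }
  vc <- tryCatch(solve(cur$I), error = function(e) matrix(NA_real_, p, p))
  nm <- colnames(X)
  list(coef = stats::setNames(beta, nm),
       se = stats::setNames(sqrt(diag(vc)), nm),
       vcov = structure(vc, dimnames = list(nm, nm)),
       loglik = cur$ll, loglik_null = null_ll,
       converged = converged, iter = iter, n = n, nevent = sum(d))
}

#' @export
coef.cox_age_fit <- function(object, ...) object$coef

#' @export
vcov.cox_age_fit <- function(object, ...) object$vcov

#' @export
logLik.cox_age_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coef), class = "logLik")
}

#' @export
confint.cox_age_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coef - z * object$se, object$coef + z * object$se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.cox_age_fit <- function(x, ...) {
  cat("Cox regression on the age time-scale (Breslow ties)\n")
  cat(sprintf("  n = %d, events = %d, loglik = %.3f%s\n", x$n, x$nevent,
              x$loglik, if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$coef)) {
    print(round(rbind(coef = x$coef, `HR` = exp(x$coef), se = x$se), 4))
  } else {
    cat("  (null model)\n")
  }
  invisible(x)
}

#' @export
summary.cox_age_fit <- function(object, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  tab <- data.frame(
    coef = object$coef,
    se = object$se,
    HR = exp(object$coef),
    lower = exp(object$coef - z * object$se),
    upper = exp(object$coef + z * object$se),
    z = object$coef / object$se,
    p = 2 * stats::pnorm(-abs(object$coef / object$se))
  )
  out <- list(table = tab, n = object$n, nevent = object$nevent,
              loglik = object$loglik, loglik_null = object$loglik_null,
              converged = object$converged, level = level)
  class(out) <- "summary.cox_age_fit"
  out
}

#' @export
print.summary.cox_age_fit <- function(x, ...) {
  cat(sprintf("Cox age-scale fit: n = %d, events = %d\n", x$n, x$nevent))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  stats::printCoefmat(as.matrix(x$table), digits = 4, P.values = TRUE,
               has.Pvalue = TRUE, cs.ind = 1:2, tst.ind = 6)
  invisible(x)
}
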