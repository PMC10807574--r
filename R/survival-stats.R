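# Survival machinery behind the signature pipeline: Kaplan-Meier + log-rank,
# Cox proportional hazards (Efron ties, via the survival package), and
# Harrell's concordance index implemented directly from its definition.

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit estimator per group; with two or more groups, the log-rank
#' chi-square statistic and p-value are reported.
#'
#' @param records tibble with `sample_id`, `time`, `event`.
#' @param group label per sample: a vector aligned with `records`, or the
#'   name of a column of `records`.
#' @return List of class `reosig_km`: `curves` (tibble `group`, `time`,
#'   `n_risk`, `n_event`, `surv`), `chisq`, `df`, `p_value` (NA for a
#'   single group), `n` (samples per group).
#' @export
km_curve <- function(records, group) {
  check_records(records)
  if (length(group) == 1 && is.character(group) && group %in% names(records)) {
    group <- records[[group]]
  }
  if (length(group) != nrow(records)) {
    abort("`group` must supply one label per record.")
  }
  group <- as.factor(group)
  if (any(table(group) == 0) || nlevels(group) == 0) {
    abort("every group must contain at least one sample.")
  }
  if (sum(records$event) < 1) abort("need at least one observed event.")

  d <- data.frame(time = records$time, event = records$event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  strata_lab <- if (is.null(fit$strata)) {
    rep(levels(group)[1], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  curves <- tibble::tibble(
    group = strata_lab,
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    surv = fit$surv
  )

  chisq <- df <- p <- NA_real_
  if (nlevels(group) >= 2) {
    lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    df <- nlevels(group) - 1
    chisq <- unname(lr$chisq)
    p <- pchisq(chisq, df = df, lower.tail = FALSE)
  }
  structure(
    list(curves = curves, chisq = chisq, df = df, p_value = p,
         n = table(group)),
    class = "reosig_km"
  )
}

#' Cox proportional hazards fit
#'
#' Maximises the Cox partial likelihood with the Efron approximation for
#' tied event times. Non-convergence and (quasi-)complete separation are
#' flagged on the returned object rather than silently reported.
#'
#' @param records tibble with `sample_id`, `time`, `event` and covariate
#'   columns.
#' @param covariate_names character vector of covariate column names.
#' @return Object of class `reosig_cox`: `terms` tibble (`term`,
#'   `estimate`, `hazard_ratio`, `std_error`, `statistic`, `p_value`),
#'   `n`, `n_events`, `converged`, `flagged` (TRUE when convergence is
#'   suspect), `loglik`, and the underlying `coxph` fit.
#' @export
cox_fit <- function(records, covariate_names) {
  check_records(records)
  if (sum(records$event) < 1) abort("need at least one observed event.")
  missing <- setdiff(covariate_names, names(records))
  if (length(missing)) {
    abort(sprintf("covariate(s) not found: %s.", paste(missing, collapse = ", ")))
  }
  for (cv in covariate_names) {
    v <- records[[cv]]
    if (is.character(v)) v <- as.factor(v)
    if (length(unique(v[!is.na(v)])) < 2) {
      abort(sprintf("covariate `%s` is constant.", cv))
    }
    records[[cv]] <- v
  }

  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariate_names), collapse = " + ")
  ))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = records, ties = "efron"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- beta / se
  # huge coefficients signal separation even without an explicit warning
  if (any(abs(beta) > 15)) flagged <- TRUE
  structure(
    list(
      terms = tibble::tibble(
        term = names(beta),
        estimate = unname(beta),
        hazard_ratio = exp(unname(beta)),
        std_error = unname(se),
        statistic = unname(z),
        p_value = 2 * stats::pnorm(-abs(unname(z)))
      ),
      n = fit$n, n_events = fit$nevent,
      converged = !flagged, flagged = flagged,
      loglik = fit$loglik,
      fit = fit
    ),
    class = "reosig_cox"
  )
}

#' @export
tidy.reosig_cox <- function(x, ...) x$terms

#' @export
glance.reosig_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 loglik = x$loglik[length(x$loglik)],
                 converged = x$converged)
}

#' @export
print.reosig_cox <- function(x, ...) {
  cat(sprintf("Cox proportional hazards fit (n = %d, events = %d%s)\n",
              x$n, x$n_events,
              if (x$flagged) ", FLAGGED: convergence suspect" else ""))
  print(x$terms)
  invisible(x)
}

# Precompute the comparability mask once; returns a closure over risk
# scores. Comparable ordered pair (i, j): t_i < t_j and subject i had an
# event. Concordant when risk_i > risk_j; tied risks count 0.5.
cindex_engine <- function(time, event) {
  comp <- outer(time, time, "<") & (event == 1)
  compn <- comp * 1          # numeric copy for matrix-vector products
  den <- sum(comp)
  function(risk, mask = NULL) {
    # fast path for binary risks (the half-vote label): three mat-vec
    # products instead of two n x n outer allocations
    if (is.null(mask) && !anyNA(risk) && all(risk == 0 | risk == 1)) {
      if (den == 0) return(NA_real_)
      hi <- risk
      lo <- 1 - risk
      mlo <- compn %*% lo
      mhi <- compn %*% hi
      num <- sum(hi * mlo) + 0.5 * (sum(hi * mhi) + sum(lo * mlo))
      return(num / den)
    }
    cm <- if (is.null(mask)) comp else comp & mask
    d <- if (is.null(mask)) den else sum(cm)
    if (d == 0) return(NA_real_)
    (sum(cm & outer(risk, risk, ">")) +
       0.5 * sum(cm & outer(risk, risk, "=="))) / d
  }
}

#' Harrell's concordance index
#'
#' Over all comparable ordered pairs of samples (the one with the shorter
#' observed time experienced an event), the fraction in which the shorter
#' survival carries the higher risk score; tied scores count one half.
#'
#' @param records tibble with `sample_id`, `time`, `event`.
#' @param risk_score numeric risk per sample, aligned with `records`.
#' @return Concordance index in \[0, 1\].
#' @export
c_index <- function(records, risk_score) {
  check_records(records)
  if (length(risk_score) != nrow(records)) {
    abort("`risk_score` must supply one value per record.")
  }
  ok <- !is.na(risk_score)
  if (!all(ok)) {
    records <- records[ok, , drop = FALSE]
    risk_score <- risk_score[ok]
  }
  eng <- cindex_engine(records$time, records$event)
  ci <- eng(risk_score)
  if (is.na(ci)) abort("no comparable sample pairs (no usable events).")
  ci
}
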