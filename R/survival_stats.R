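#' Prepare a clinical table for survival modelling
#'
#' Validates the clinical schema, joins the dichotomized aneuploidy status
#' from a score table, and recomputes the dichotomized covariates from raw
#' values (CTC count >= 5; WHO performance status 0 vs 1-2). Dichotomies
#' are never trusted from input columns.
#'
#' @param clinical Data frame with at least `sample_id`, `os_months`,
#'   `event`, `ctc_count`, `who_status`.
#' @param scores Optional `"aneuploidy_scores"` table (from
#'   [score_cohort()]) joined on `sample_id` to add the `aneuploid` flag.
#' @return The clinical data frame with logical `ctc_high`, `who_high`
#'   and (if scores given) `aneuploid` columns.
#' @export
prepare_clinical <- function(clinical, scores = NULL) {
  need <- c("sample_id", "os_months", "event", "ctc_count", "who_status")
  missing <- setdiff(need, names(clinical))
  if (length(missing) > 0)
    stop("clinical table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(clinical$os_months < 0, na.rm = TRUE)) stop("negative survival time")
  if (!all(clinical$event %in% c(0, 1))) stop("event must be 0/1")
  clinical$ctc_high <- clinical$ctc_count >= 5
  clinical$who_high <- clinical$who_status >= 1
  if (!is.null(scores)) {
    idx <- match(clinical$sample_id, scores$sample_id)
    if (anyNA(idx))
      stop("no score for sample(s): ",
           paste(utils::head(clinical$sample_id[is.na(idx)], 3), collapse = ", "))
    clinical$score <- scores$score[idx]
    clinical$gw_z <- scores$gw_z[idx]
    clinical$aneuploid <- scores$status[idx] == "aneuploid"
  }
  clinical
}

#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator; censored observations leave the risk set
#' without contributing an event. The median is the earliest observed time
#' at which the estimated survival drops to 0.5 or below, `NA` when never
#' reached.
#'
#' @param times Follow-up times (>= 0).
#' @param events Event indicators (1 = death, 0 = censored).
#' @return Object of class `"km_curve"`: `time`, `surv`, `n_risk`,
#'   `n_event`, `median`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  stopifnot(length(times) == length(events), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  med <- unname(summary(fit)$table["median"])
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, median = med),
            class = "km_curve")
}

#' Log-rank test between survival curves
#'
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param group Group labels (>= 2 non-empty groups).
#' @return Object of class `"logrank_result"`: `chisq`, `df`, `p`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) stop("need at least 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- length(sd$n) - 1
  structure(list(chisq = unname(sd$chisq), df = df,
                 p = stats::pchisq(sd$chisq, df, lower.tail = FALSE)),
            class = "logrank_result")
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood (Efron tie correction by default)
#' for overall survival on the selected covariates and reports per-term
#' hazard ratios with Wald 95% confidence intervals, the partial-likelihood
#' AIC, and complete-case counts. Rows with missing values in the selected
#' covariates are dropped (complete-case per model) and counted.
#'
#' @param records Clinical data frame from [prepare_clinical()] with
#'   `os_months` and `event`.
#' @param covariates Character vector of covariate column names (numeric
#'   or logical/0-1).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `"cox_fit"` with `terms` (data.frame: term,
#'   beta, se, hr, ci_lo, ci_hi, p), `aic`, `loglik`, `n`, `n_events`,
#'   `n_dropped`, `ties`.
#' @export
cox_fit <- function(records, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(length(covariates) >= 1)
  missing <- setdiff(covariates, names(records))
  if (length(missing) > 0)
    stop("unknown covariate(s): ", paste(missing, collapse = ", "))
  keep <- stats::complete.cases(records[, c("os_months", "event", covariates)])
  d <- records[keep, ]
  if (sum(d$event) < 1) stop("no events in complete cases; model undefined")
  for (cv in covariates) {
    v <- d[[cv]]
    if (is.logical(v)) v <- as.numeric(v)
    if (!is.numeric(v)) stop("covariate ", cv, " is not numeric or logical")
    if (stats::var(v) == 0)
      stop("covariate ", cv, " is constant; hazard ratio not identifiable")
    d[[cv]] <- v
  }
  fml <- stats::as.formula(paste("survival::Surv(os_months, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = ties)
  if (!is.null(fit$info) && !fit$info$converged) stop("Cox fit did not converge")
  sm <- summary(fit)
  beta <- stats::coef(fit)
  se <- sm$coefficients[, "se(coef)"]
  terms <- data.frame(term = names(beta),
                      beta = unname(beta),
                      se = unname(se),
                      hr = unname(exp(beta)),
                      ci_lo = unname(exp(beta - 1.96 * se)),
                      ci_hi = unname(exp(beta + 1.96 * se)),
                      p = unname(sm$coefficients[, "Pr(>|z|)"]),
                      stringsAsFactors = FALSE, row.names = NULL)
  ll <- fit$loglik[length(fit$loglik)]
  structure(list(terms = terms,
                 aic = 2 * length(beta) - 2 * ll,
                 loglik = ll,
                 n = nrow(d), n_events = sum(d$event),
                 n_dropped = sum(!keep), ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s, AIC = %.2f\n",
              x$n, x$n_events, x$ties, x$aic))
  if (nrow(x$terms) == 0) { cat("  (empty model)\n"); return(invisible(x)) }
  t <- x$terms
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-22s HR %.*g (95%% CI %.*g-%.*g), p = %.3g\n",
                t$term[i], digits, t$hr[i], digits, t$ci_lo[i],
                digits, t$ci_hi[i], t$p[i]))
  invisible(x)
}

#' Univariate Cox screen over candidate covariates
#'
#' Fits one single-covariate Cox model per candidate and retains those
#' with Wald p below `p_keep` (default 0.1), the pre-filter feeding the
#' multivariable model.
#'
#' @param records Clinical data frame.
#' @param candidates Covariate names to screen.
#' @param p_keep Retention threshold on the Wald p-value (strict `<`).
#' @param ties Passed to [cox_fit()].
#' @return List with `retained` (character vector) and `table`
#'   (per-candidate data.frame: term, hr, ci_lo, ci_hi, p, n, n_events).
#' @export
univariate_screen <- function(records, candidates, p_keep = 0.1,
                              ties = "efron") {
  if (length(candidates) == 0)
    return(list(retained = character(0),
                table = data.frame(term = character(0))))
  rows <- lapply(candidates, function(cv) {
    f <- cox_fit(records, cv, ties = ties)
    cbind(f$terms[1, c("term", "hr", "ci_lo", "ci_hi", "p")],
          n = f$n, n_events = f$n_events)
  })
  tab <- do.call(rbind, rows)
  tab$term <- candidates  # original names (one row per single-covariate fit)
  list(retained = candidates[tab$p < p_keep], table = tab)
}

#' Backward selection for the multivariable Cox model
#'
#' Starting from the full model over `covariates`, repeatedly refits after
#' removing the term with the largest Wald p-value at or above `p_drop`
#' (default 0.1), until every remaining term is below the threshold. The
#' procedure is deterministic given the data.
#'
#' @param records Clinical data frame.
#' @param covariates Starting covariate set (typically the univariate
#'   screen's survivors).
#' @param p_drop Removal threshold (terms with Wald p >= `p_drop` are
#'   candidates for removal).
#' @param ties Passed to [cox_fit()].
#' @return A `"cox_fit"` for the final model, with the removal order in
#'   `$dropped`. When every term is removed, an explicit empty-model
#'   result (`terms` with zero rows) is returned.
#' @export
backward_selection <- function(records, covariates, p_drop = 0.1,
                               ties = "efron") {
  current <- covariates
  dropped <- character(0)
  while (length(current) > 0) {
    fit <- cox_fit(records, current, ties = ties)
    worst <- which.max(fit$terms$p)
    if (fit$terms$p[worst] < p_drop) {
      fit$dropped <- dropped
      return(fit)
    }
    dropped <- c(dropped, current[worst])
    current <- current[-worst]
  }
  structure(list(terms = data.frame(term = character(0), beta = numeric(0),
                                    se = numeric(0), hr = numeric(0),
                                    ci_lo = numeric(0), ci_hi = numeric(0),
                                    p = numeric(0)),
                 aic = NA_real_, loglik = NA_real_,
                 n = nrow(records), n_events = sum(records$event),
                 n_dropped = 0L, ties = ties, dropped = dropped),
            class = "cox_fit")
}

#' Combined CTC-count and aneuploidy strata
#'
#' Crosses the two dichotomized markers into four groups with
#' `CTC < 5 & euploid` as reference, fits a Cox model with the three
#' indicator terms, and also returns the four Kaplan-Meier curves and the
#' overall log-rank test. The double-positive group (CTC >= 5 and
#' aneuploid) is the worst-prognosis stratum under additive log-hazards.
#'
#' @param records Clinical data frame from [prepare_clinical()] carrying
#'   `ctc_high` and `aneuploid`.
#' @param ties Passed to [cox_fit()].
#' @return List with `fit` (a `"cox_fit"` over the 3 non-reference
#'   groups), `km` (named list of [km_estimate()] curves), `logrank`
#'   (overall [logrank_test()]), `group` (per-patient factor).
#' @export
combined_strata_fit <- function(records, ties = "efron") {
  if (!all(c("ctc_high", "aneuploid") %in% names(records)))
    stop("records must carry ctc_high and aneuploid flags")
  lev <- c("ctc_low.euploid", "ctc_low.aneuploid",
           "ctc_high.euploid", "ctc_high.aneuploid")
  group <- factor(paste(ifelse(records$ctc_high, "ctc_high", "ctc_low"),
                        ifelse(records$aneuploid, "aneuploid", "euploid"),
                        sep = "."), levels = lev)
  if (sum(group == lev[1], na.rm = TRUE) == 0)
    stop("empty reference group (CTC < 5 and euploid)")
  present <- lev[lev %in% levels(droplevels(group))]
  if (length(present) < 2) stop("all patients fall in a single stratum")
  d <- records
  for (g in present[-1]) d[[g]] <- as.numeric(group == g)
  fit <- cox_fit(d, present[-1], ties = ties)
  km <- lapply(stats::setNames(present, present), function(g)
    km_estimate(records$os_months[group == g], records$event[group == g]))
  lr <- logrank_test(records$os_months, records$event, group)
  list(fit = fit, km = km, logrank = lr, group = group)
}

#' Required number of events for a Cox/log-rank comparison
#'
#' Schoenfeld's formula for the number of events needed to detect a hazard
#' ratio between two groups:
#' `D = ceil((z_{1-alpha/2} + z_{power})^2 / (p (1-p) (log hr)^2))`,
#' with `p` the fraction of patients in one group.
#'
#' @param hr Hazard ratio to detect (> 0, != 1).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param power Target power (default 0.8).
#' @param p_group Fraction of patients in one of the two groups
#'   (default 0.5).
#' @return Integer number of required events.
#' @examples
#' required_events(hr = 2)  # 66
#' @export
required_events <- function(hr, alpha = 0.05, power = 0.8, p_group = 0.5) {
  if (hr <= 0 || hr == 1) stop("hazard ratio must be > 0 and != 1")
  if (p_group <= 0 || p_group >= 1) stop("p_group must be in (0, 1)")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  as.integer(ceiling(z^2 / (p_group * (1 - p_group) * log(hr)^2)))
}
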