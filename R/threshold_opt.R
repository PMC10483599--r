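#' Sensitivity and specificity of a score threshold
#'
#' Classification rule: `score >= t` predicts the positive class (dead).
#' Sensitivity is the fraction of deaths classified positive, specificity
#' the fraction of survivors classified negative.
#'
#' @param scores Numeric scores.
#' @param status 0/1 indicator of the positive class (1 = dead).
#' @param t Threshold (finite or +/-Inf).
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
evaluate_threshold <- function(scores, status, t) {
  stopifnot(length(scores) == length(status))
  pred <- scores >= t
  c(sensitivity = if (sum(status == 1) > 0) mean(pred[status == 1]) else NA_real_,
    specificity = if (sum(status == 0) > 0) mean(!pred[status == 0]) else NA_real_)
}

# one sweep over candidate thresholds; returns the optimum
.cutpoint_sweep <- function(scores, status, candidates = c("midpoint", "observed")) {
  candidates <- match.arg(candidates)
  u <- sort(unique(scores))
  cand <- if (candidates == "midpoint") {
    c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  } else c(-Inf, u, Inf)
  n_dead <- sum(status == 1)
  n_alive <- sum(status == 0)
  # vectorized confusion rates: for rule score >= t
  sens <- vapply(cand, function(t) sum(scores >= t & status == 1), 0) / n_dead
  spec <- vapply(cand, function(t) sum(scores < t & status == 0), 0) / n_alive
  youden_sum <- sens + spec
  best <- which(youden_sum == max(youden_sum))[1]  # ties -> smallest threshold
  list(table = data.frame(threshold = cand, sensitivity = sens,
                          specificity = spec),
       optimal_threshold = cand[best],
       sensitivity = sens[best], specificity = spec[best],
       youden = youden_sum[best] - 1)
}

#' Data-driven dichotomization threshold for a prognostic score
#'
#' Chooses the score threshold maximizing sensitivity + specificity
#' (equivalently the Youden index) for separating patients by survival
#' status at end of follow-up (dead vs alive; follow-up time is
#' deliberately ignored, a known simplification of this cutpoint style).
#' Candidate thresholds are the midpoints between consecutive distinct
#' scores plus -Inf/+Inf sentinels, which enumerate every achievable
#' classification; ties are broken toward the smallest threshold.
#' Threshold variability is assessed by resampling patients with
#' replacement and recording each replicate's optimum.
#'
#' @param scores Numeric aneuploidy scores.
#' @param status_dead 0/1 survival status (1 = dead).
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed Integer seed for the bootstrap.
#' @param candidates `"midpoint"` (default) or `"observed"` candidate set.
#' @return Object of class `"cutpoint_result"`: `optimal_threshold`,
#'   `sensitivity`, `specificity`, `youden`, `table` (per-candidate
#'   rates), `bootstrap` (per-replicate optima, NA where a replicate drew
#'   a single class), `boot_median`, `boot_ci` (2.5/97.5 percentiles),
#'   `n_boot`, `seed`.
#' @export
optimize_cutpoint <- function(scores, status_dead, n_boot = 10000,
                              seed = 1L, candidates = "midpoint") {
  stopifnot(length(scores) == length(status_dead))
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (!all(status_dead %in% c(0, 1))) stop("status must be 0/1")
  if (length(unique(status_dead)) < 2)
    stop("both survival classes (dead and alive) must be present")
  if (n_boot < 1) stop("n_boot must be >= 1")
  opt <- .cutpoint_sweep(scores, status_dead, candidates)
  set.seed(seed)
  n <- length(scores)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(status_dead[idx])) < 2) return(NA_real_)
    .cutpoint_sweep(scores[idx], status_dead[idx], candidates)$optimal_threshold
  }, 0)
  finite_boot <- boot[is.finite(boot)]
  structure(c(opt,
              list(bootstrap = boot,
                   boot_median = if (length(finite_boot)) stats::median(finite_boot) else NA_real_,
                   boot_ci = if (length(finite_boot))
                     stats::quantile(finite_boot, c(0.025, 0.975), names = FALSE)
                   else c(NA_real_, NA_real_),
                   n_boot = n_boot, seed = seed)),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(paste0("<cutpoint_result> optimal threshold %.6g ",
                     "(sens %.3f, spec %.3f, Youden %.3f)\n"),
              x$optimal_threshold, x$sensitivity, x$specificity, x$youden))
  cat(sprintf("  bootstrap (n = %d): median %.6g, 95%% interval [%.6g, %.6g]\n",
              x$n_boot, x$boot_median, x$boot_ci[1], x$boot_ci[2]))
  invisible(x)
}
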