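#' Normalize arm counts to fractions
#'
#' Divides each included-arm count by the sample's total retained count so
#' the result is a probability vector over the analyzed arms. This removes
#' sequencing depth from the profile; only the relative representation of
#' each arm carries copy-number signal.
#'
#' @param v An [arm_counts()] object.
#' @return Named numeric vector of fractions summing to 1.
#' @export
normalize_counts <- function(v) {
  stopifnot(inherits(v, "arm_counts"))
  if (v$total_reads == 0) stop("no retained reads for sample ", v$sample_id)
  v$counts / v$total_reads
}

#' Build a reference panel from healthy-control samples
#'
#' Computes, per included arm, the mean and standard deviation (n-1
#' denominator) of the normalized read counts across healthy controls.
#' These are the location and scale against which patient profiles are
#' standardized. The panel additionally records the resubstitution sum of
#' squared Z-scores of each control, whose mean and SD standardize the
#' genome-wide score of new samples (see [score_cohort()]).
#'
#' @param panel List of [arm_counts()] objects from healthy/diploid
#'   subjects (the canonical panel has n = 17); at least 2 required.
#' @return An object of class `"reference_panel"` with fields `arm_names`,
#'   `mean`, `sd`, `n_panel`, `panel_scores`, `score_mean`, `score_sd`.
#' @export
build_reference <- function(panel) {
  if (length(panel) < 2)
    stop("reference panel needs at least 2 samples (SD undefined otherwise)")
  arm_names <- names(panel[[1]]$counts)
  fr <- vapply(panel, function(s) {
    if (!identical(names(s$counts), arm_names))
      stop("panel samples differ in arm set")
    normalize_counts(s)
  }, numeric(length(arm_names)))
  mu <- rowMeans(fr)
  sdev <- apply(fr, 1, stats::sd)
  if (any(sdev == 0))
    stop("degenerate panel: zero SD on arm ",
         paste(arm_names[sdev == 0], collapse = ", "))
  panel_scores <- colSums(((fr - mu) / sdev)^2)
  structure(list(arm_names = arm_names,
                 mean = stats::setNames(mu, arm_names),
                 sd = stats::setNames(sdev, arm_names),
                 n_panel = length(panel),
                 panel_scores = unname(panel_scores),
                 score_mean = mean(panel_scores),
                 score_sd = stats::sd(panel_scores)),
            class = "reference_panel")
}

#' Write / read a reference panel as TSV
#'
#' Two-section TSV: per-arm mean/SD rows plus a trailing metadata block, so
#' a panel built once from controls can be reused across cohorts.
#'
#' @param ref A `"reference_panel"`.
#' @param path File path.
#' @export
write_reference <- function(ref, path) {
  df <- data.frame(arm = ref$arm_names, mean = ref$mean, sd = ref$sd)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#n_panel\t%d", ref$n_panel), con)
  writeLines(sprintf("#score_mean\t%.10g", ref$score_mean), con)
  writeLines(sprintf("#score_sd\t%.10g", ref$score_sd), con)
  writeLines(sprintf("#panel_scores\t%s",
                     paste(sprintf("%.10g", ref$panel_scores), collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  get <- function(key) sub(paste0("#", key, "\t"), "", meta[startsWith(meta, paste0("#", key, "\t"))])
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  structure(list(arm_names = df$arm,
                 mean = stats::setNames(df$mean, df$arm),
                 sd = stats::setNames(df$sd, df$arm),
                 n_panel = as.integer(get("n_panel")),
                 panel_scores = as.numeric(strsplit(get("panel_scores"), ",")[[1]]),
                 score_mean = as.numeric(get("score_mean")),
                 score_sd = as.numeric(get("score_sd"))),
            class = "reference_panel")
}

#' Per-arm Z-scores against a reference panel
#'
#' Standardizes a sample's normalized arm fractions: `z_a = (f_a - mu_a) /
#' sigma_a` with the panel's per-arm mean and SD, quantifying over- and
#' under-representation of each arm.
#'
#' @param v An [arm_counts()] object.
#' @param ref A `"reference_panel"` from [build_reference()].
#' @return Named numeric vector of Z-scores over the included arms.
#' @export
arm_zscores <- function(v, ref) {
  stopifnot(inherits(ref, "reference_panel"))
  if (!identical(names(v$counts), ref$arm_names))
    stop("arm set of sample ", v$sample_id, " does not match reference panel")
  (normalize_counts(v) - ref$mean) / ref$sd
}

#' Genome-wide aneuploidy score from per-arm Z-scores
#'
#' Squares and sums the per-arm Z-scores into a single genome-wide
#' aneuploidy score `S = sum(z_a^2)` and dichotomizes it: `S >= threshold`
#' is called aneuploid (boundary inclusive). Note that the raw sum grows
#' with the number of arms even for a perfectly diploid sample (each z has
#' roughly unit variance), so on full-genome profiles the dichotomization
#' threshold is conventionally applied to the panel-standardized score
#' computed by [score_cohort()]; the raw-sum rule here is what one uses on
#' small or hand-built Z-score sets.
#'
#' @param z Named numeric vector of per-arm Z-scores.
#' @param threshold Dichotomization threshold (default 5).
#' @param sample_id Optional sample label.
#' @return Object of class `"aneuploidy_result"` with fields `sample_id`,
#'   `z`, `score`, `threshold`, `status` (`"aneuploid"`/`"euploid"`).
#' @export
genome_wide_score <- function(z, threshold = 5, sample_id = NA_character_) {
  if (length(z) == 0) stop("empty Z-score vector")
  s <- sum(z^2)
  structure(list(sample_id = sample_id, z = z, score = s,
                 threshold = threshold,
                 status = if (s >= threshold) "aneuploid" else "euploid"),
            class = "aneuploidy_result")
}

#' @export
print.aneuploidy_result <- function(x, ...) {
  cat(sprintf("<aneuploidy_result> %s: S = %.4g (threshold %.4g) -> %s\n",
              x$sample_id, x$score, x$threshold, x$status))
  invisible(x)
}

#' Score a cohort of samples against a reference panel
#'
#' For each sample computes per-arm Z-scores, the raw genome-wide score
#' `S = sum(z^2)`, and (by default) the panel-standardized genome-wide
#' Z-score `G = (S - mu_S) / sigma_S`, where `mu_S` and `sigma_S` are the
#' mean and SD of the panel controls' own scores. Because each per-arm z
#' is standardized, S concentrates near the number of arms for any healthy
#' sample; standardizing against the panel's score distribution centres
#' healthy samples near zero so that one fixed threshold separates
#' aneuploid from euploid profiles regardless of how many arms are
#' analyzed. Dichotomization uses G when `standardize = TRUE` (the
#' default, matching the assay's published >= 5 call) and raw S otherwise.
#'
#' @param samples List of [arm_counts()] objects.
#' @param ref A `"reference_panel"`.
#' @param threshold Aneuploidy threshold (default 5), applied to the
#'   standardized score (or to raw S when `standardize = FALSE`).
#' @param standardize Standardize S against the panel score distribution.
#' @param per_arm_z_min Optional per-arm magnitude cut: per-arm Z-scores
#'   with `|z|` below this are zeroed before squaring and summing (some
#'   assay variants apply such a cut; default `NULL`, off).
#' @return `data.frame` of class `"aneuploidy_scores"` with one row per
#'   sample (`sample_id`, `score` = raw S, `gw_z` = standardized score or
#'   `NA`, `status`, `qc_low_yield`) and the per-arm Z-score matrix in
#'   `attr(, "z_matrix")` (arms in rows, samples in columns).
#' @export
score_cohort <- function(samples, ref, threshold = 5, standardize = TRUE,
                         per_arm_z_min = NULL) {
  stopifnot(length(samples) > 0)
  zmat <- vapply(samples, arm_zscores, numeric(length(ref$arm_names)), ref = ref)
  rownames(zmat) <- ref$arm_names
  colnames(zmat) <- vapply(samples, `[[`, "", "sample_id")
  zsum <- zmat
  if (!is.null(per_arm_z_min)) zsum[abs(zsum) < per_arm_z_min] <- 0
  s <- colSums(zsum^2)
  if (standardize) {
    if (ref$score_sd == 0) stop("panel score SD is zero; cannot standardize")
    gw <- (s - ref$score_mean) / ref$score_sd
    call_on <- gw
  } else {
    gw <- rep(NA_real_, length(s))
    call_on <- s
  }
  out <- data.frame(sample_id = colnames(zmat),
                    score = unname(s),
                    gw_z = unname(gw),
                    status = ifelse(call_on >= threshold, "aneuploid", "euploid"),
                    qc_low_yield = vapply(samples, `[[`, TRUE, "qc_low_yield"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "z_matrix") <- zmat
  attr(out, "threshold") <- threshold
  attr(out, "standardized") <- standardize
  class(out) <- c("aneuploidy_scores", "data.frame")
  out
}

#' Write per-sample scores and the per-arm Z-score matrix
#'
#' @param scores An `"aneuploidy_scores"` table from [score_cohort()].
#' @param path Output TSV for the per-sample table.
#' @param z_path Optional output TSV for the arms-by-samples Z matrix.
#' @export
write_scores <- function(scores, path, z_path = NULL) {
  df <- as.data.frame(scores)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(z_path)) {
    z <- attr(scores, "z_matrix")
    utils::write.table(data.frame(arm = rownames(z),
                                  apply(z, 2, function(x) sprintf("%.10g", x)),
                                  check.names = FALSE),
                       z_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
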