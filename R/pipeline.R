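#' Candidate prognostic covariates for the univariate screen
#'
#' The baseline characteristics screened for overall-survival prognosis:
#' age at registration, total Gleason score, PSA, dichotomized WHO status
#' (0 vs 1-2), albumin, absolute neutrophil count, haemoglobin, white
#' blood cells, alkaline phosphatase, lactate dehydrogenase, dichotomized
#' aneuploidy status and dichotomized CTC count.
#'
#' @return Character vector of column names.
#' @export
default_candidates <- function() {
  c("age", "gleason", "psa", "who_high", "alb", "anc", "hbg", "wbc",
    "alp", "ldh", "aneuploid", "ctc_high")
}

.as_tidy_terms <- function(fit) {
  lapply(seq_len(nrow(fit$terms)), function(i) as.list(fit$terms[i, ]))
}

#' Run the full aneuploidy-score analysis pipeline
#'
#' Chains every stage on one cohort: build the reference panel from
#' healthy-control counts, score the patient samples (per-arm Z-scores,
#' genome-wide score, dichotomization), then run the survival analyses
#' (univariate Cox screen, backward-selected multivariable model, combined
#' CTC-by-aneuploidy strata with Kaplan-Meier curves and log-rank tests),
#' the data-driven cutpoint optimization, and the rank correlations of the
#' score with maximum variant allele frequency and CTC counts. Inputs may
#' be in-memory objects or file paths (arm-count TSVs and a clinical CSV).
#'
#' @param counts Patient arm counts: list of [arm_counts()] or a TSV path.
#' @param reference Healthy-panel arm counts: list or TSV path.
#' @param clinical Clinical table: data.frame or CSV path (schema of
#'   [prepare_clinical()]).
#' @param arms Arm definitions; default the packaged hg19-style table.
#' @param threshold Aneuploidy dichotomization threshold (default 5).
#' @param standardize Use the panel-standardized genome-wide Z-score for
#'   the dichotomization (default TRUE; see [score_cohort()]).
#' @param ties Cox tie handling (default `"efron"`).
#' @param p_keep,p_drop Univariate-screen and backward-selection
#'   thresholds (default 0.1 each).
#' @param n_boot Bootstrap replicates for the cutpoint (default 10000).
#' @param seed Seed for the bootstrap.
#' @param candidates Covariates for the univariate screen; defaults to the
#'   intersection of [default_candidates()] with available columns.
#' @param outdir Optional directory; when given, writes scores TSV,
#'   per-arm Z matrix TSV, and `summary.json`.
#' @return List of class `"aneuscore_summary"` with elements `scores`,
#'   `clinical`, `univariate`, `multivariable`, `combined`, `cutpoint`,
#'   `associations`, `km`, and `summary` (the flat machine-readable
#'   summary that is serialized to JSON).
#' @export
run_pipeline <- function(counts, reference, clinical, arms = NULL,
                         threshold = 5, standardize = TRUE,
                         ties = "efron", p_keep = 0.1, p_drop = 0.1,
                         n_boot = 10000, seed = 1L,
                         candidates = NULL, outdir = NULL) {
  if (is.null(arms))
    arms <- load_arm_definitions(system.file("extdata",
      "cytoband_hg19_synthetic.tsv", package = "aneuscore"))
  if (is.character(counts)) counts <- read_count_table(counts, arms)
  if (is.character(reference)) reference <- read_count_table(reference, arms)
  if (is.character(clinical)) {
    if (!file.exists(clinical)) stop("clinical file not found: ", clinical)
    clinical <- utils::read.csv(clinical, stringsAsFactors = FALSE)
  }

  ref <- build_reference(reference)
  scores <- score_cohort(counts, ref, threshold = threshold,
                         standardize = standardize)
  clin <- prepare_clinical(clinical, scores)

  if (is.null(candidates))
    candidates <- intersect(default_candidates(), names(clin))
  screen <- univariate_screen(clin, candidates, p_keep = p_keep, ties = ties)
  multi <- backward_selection(clin, screen$retained, p_drop = p_drop,
                              ties = ties)
  combined <- combined_strata_fit(clin, ties = ties)

  km <- list(
    aneuploid = lapply(split(clin, clin$aneuploid), function(d)
      km_estimate(d$os_months, d$event)),
    ctc_high = lapply(split(clin, clin$ctc_high), function(d)
      km_estimate(d$os_months, d$event)))
  logrank <- list(
    aneuploid = logrank_test(clin$os_months, clin$event, clin$aneuploid),
    ctc_high = logrank_test(clin$os_months, clin$event, clin$ctc_high))

  score_for_cut <- if (standardize) clin$gw_z else clin$score
  cut <- optimize_cutpoint(score_for_cut, clin$event, n_boot = n_boot,
                           seed = seed)

  assoc <- list()
  if ("max_vaf" %in% names(clin))
    assoc$score_vs_max_vaf <- spearman_assoc(score_for_cut, clin$max_vaf)
  assoc$score_vs_ctc <- spearman_assoc(score_for_cut, clin$ctc_count)

  summary <- list(
    schema_version = "1.0",
    n_patients = nrow(clin),
    n_events = sum(clin$event),
    n_aneuploid = sum(clin$aneuploid),
    threshold = threshold,
    univariate = stats::setNames(lapply(seq_len(nrow(screen$table)),
      function(i) as.list(screen$table[i, -1])), screen$table$term),
    retained = screen$retained,
    multivariable = list(terms = .as_tidy_terms(multi), aic = multi$aic,
                         dropped = multi$dropped),
    combined = list(terms = .as_tidy_terms(combined$fit),
                    logrank_p = combined$logrank$p),
    logrank = list(aneuploid_p = logrank$aneuploid$p,
                   ctc_p = logrank$ctc_high$p),
    cutpoint = list(optimal_threshold = cut$optimal_threshold,
                    youden = cut$youden,
                    boot_median = cut$boot_median,
                    boot_ci = cut$boot_ci, n_boot = cut$n_boot,
                    seed = seed),
    associations = lapply(assoc, function(a)
      list(rho = a$rho, p = a$p_two_sided, n = a$n,
           slope = unname(a$linear["slope"]),
           intercept = unname(a$linear["intercept"]))))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_scores(scores, file.path(outdir, "scores.tsv"),
                 z_path = file.path(outdir, "arm_zscores.tsv"))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(scores = scores, clinical = clin,
                 univariate = screen, multivariable = multi,
                 combined = combined, cutpoint = cut,
                 associations = assoc, km = km, logrank = logrank,
                 summary = summary),
            class = "aneuscore_summary")
}

#' @export
print.aneuscore_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<aneuscore_summary> %d patients (%d events), %d aneuploid\n",
              s$n_patients, s$n_events, s$n_aneuploid))
  cat("Multivariable model:\n"); print(x$multivariable)
  cat(sprintf("Cutpoint: %.6g (Youden %.3f)\n",
              s$cutpoint$optimal_threshold, s$cutpoint$youden))
  for (nm in names(x$associations))
    cat(sprintf("  %s: rho = %.3f\n", nm, x$associations[[nm]]$rho))
  invisible(x)
}
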