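#' Configuration for the synthetic-cohort generator
#'
#' Bundles every knob of the generative model behind the simulated cohorts:
#' arm-level read counts whose expected proportions shift with tumour
#' fraction under an arm-level copy-number profile, overdispersion between
#' healthy subjects, CTC counts that rise with tumour fraction, and
#' exponential survival whose hazard increases with aneuploidy and CTC
#' status under independent exponential censoring.
#'
#' Defaults encode the cohort structure the analysis targets: a 17-subject
#' healthy reference panel, 131 patients, around 200,000 reads per sample,
#' hazard ratios of 3.24 (aneuploidy) and 2.92 (CTC >= 5), and a censoring
#' rate giving roughly 70% observed deaths.
#'
#' @param n_reference Healthy reference-panel size (default 17).
#' @param n_patients Patient cohort size (default 131).
#' @param depth_mean Mean retained reads per sample (default 200000).
#' @param depth_dispersion Dirichlet dispersion (1/concentration) governing
#'   between-sample variability of arm proportions; 0 gives pure
#'   multinomial counts. Default 2e-5, i.e. ~3% CV on a typical arm
#'   fraction, the scale of amplicon-assay arm variability.
#' @param tf_zero_prob Probability a patient has no detectable ctDNA
#'   (tumour fraction exactly 0; default 0.35).
#' @param tf_beta Beta shape parameters for the non-zero tumour fractions
#'   (default `c(1.2, 3.5)`).
#' @param cna_profile_generator Function `(arm_names) -> integer copy
#'   numbers` drawn per patient; default [default_cna_profile()].
#' @param baseline_hazard Death hazard (1/month) for marker-negative
#'   patients (default 0.02, median ~35 months).
#' @param log_hr_aneuploidy Log hazard ratio of true aneuploidy
#'   (default `log(3.24)`).
#' @param log_hr_ctc Log hazard ratio of CTC count >= 5 (default `log(2.92)`).
#' @param censoring_rate Independent exponential censoring hazard
#'   (1/month, default 0.02).
#' @param ctc_intercept,ctc_slope,ctc_size Negative-binomial CTC model:
#'   `log mean = ctc_intercept + ctc_slope * tumour fraction`, dispersion
#'   `size` (defaults log(2), 6, 0.8).
#' @param deterministic Replace count sampling by rounded expected counts
#'   (exact-test mode; depth fixed at `depth_mean`).
#' @param seed Integer seed; fully determines all outputs.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_reference = 17,
                              n_patients = 131,
                              depth_mean = 200000,
                              depth_dispersion = 2e-5,
                              tf_zero_prob = 0.35,
                              tf_beta = c(1.2, 3.5),
                              cna_profile_generator = default_cna_profile,
                              baseline_hazard = 0.02,
                              log_hr_aneuploidy = log(3.24),
                              log_hr_ctc = log(2.92),
                              censoring_rate = 0.02,
                              ctc_intercept = log(2),
                              ctc_slope = 6,
                              ctc_size = 0.8,
                              deterministic = FALSE,
                              seed = 1L) {
  stopifnot(n_reference >= 2, n_patients >= 1, depth_mean > 0,
            depth_dispersion >= 0, tf_zero_prob >= 0, tf_zero_prob <= 1,
            baseline_hazard > 0, censoring_rate >= 0, ctc_size > 0)
  structure(as.list(environment()), class = "simulation_config")
}

#' Draw a prostate-cancer-like arm-level copy-number profile
#'
#' Each arm is altered independently with probability `p_alter`; an
#' alteration is a gain (copy number 3 or 4) with probability `p_gain`,
#' otherwise a single-copy loss. Unaltered arms stay diploid (copy 2).
#'
#' @param arm_names Names of the included arms.
#' @param p_alter Per-arm alteration probability (default 0.25).
#' @param p_gain Probability an alteration is a gain (default 0.6).
#' @return Named integer vector of per-arm copy numbers.
#' @export
default_cna_profile <- function(arm_names, p_alter = 0.25, p_gain = 0.6) {
  n <- length(arm_names)
  cn <- rep(2L, n)
  hit <- stats::runif(n) < p_alter
  gain <- stats::runif(n) < p_gain
  cn[hit & gain] <- sample(c(3L, 4L), sum(hit & gain), replace = TRUE)
  cn[hit & !gain] <- 1L
  stats::setNames(cn, arm_names)
}

# one Dirichlet draw via gamma variates; dispersion = 1/concentration
.rdirichlet <- function(weights, dispersion) {
  if (dispersion <= 0) return(weights / sum(weights))
  g <- stats::rgamma(length(weights), shape = weights / sum(weights) / dispersion)
  if (sum(g) == 0) return(weights / sum(weights))
  g / sum(g)
}

# arm weights: arm length as a proxy for LINE-1 element density
.arm_weights <- function(arms) {
  incl <- arms[arms$included, ]
  stats::setNames((incl$end - incl$start) / sum(incl$end - incl$start), incl$name)
}

# tumour/normal mixture: expected arm weight before renormalization is
# w_a * (2(1-f) + f*c_a) / 2
.mixture_weights <- function(w, f, cna) {
  w2 <- w * (2 * (1 - f) + f * cna[names(w)]) / 2
  w2 / sum(w2)
}

.sample_counts <- function(sample_id, w, cfg) {
  if (cfg$deterministic) {
    counts <- round(cfg$depth_mean * w)
  } else {
    depth <- if (cfg$depth_dispersion > 0)
      stats::rnbinom(1, mu = cfg$depth_mean, size = 1 / cfg$depth_dispersion)
    else stats::rpois(1, cfg$depth_mean)
    p <- .rdirichlet(w, cfg$depth_dispersion)
    counts <- as.integer(stats::rmultinom(1, max(depth, 1), p))
  }
  arm_counts(sample_id, stats::setNames(counts, names(w)))
}

#' Simulate a healthy reference panel
#'
#' Draws `cfg$n_reference` diploid samples whose expected arm proportions
#' are proportional to arm length, with Dirichlet-multinomial noise
#' between subjects.
#'
#' @param cfg A [simulation_config()].
#' @param arms Arm definitions from [load_arm_definitions()].
#' @return List of [arm_counts()] objects.
#' @export
simulate_reference_panel <- function(cfg, arms) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$n_reference < 2) stop("need at least 2 reference samples")
  validate_arms(arms)
  w <- .arm_weights(arms)
  lapply(seq_len(cfg$n_reference), function(i)
    .sample_counts(sprintf("ref_%02d", i), w, cfg))
}

#' Simulate one tumour-bearing cfDNA sample
#'
#' Mixes a diploid background with a tumour copy-number profile at
#' fraction `f`: the expected weight of arm `a` is proportional to
#' `w_a * (2(1-f) + f*c_a)/2`, renormalized. `f = 0` reduces exactly to
#' the healthy model.
#'
#' @param f Tumour fraction in \[0, 1\].
#' @param cna Named integer vector of per-arm copy numbers (>= 0) over the
#'   included arms.
#' @param cfg A [simulation_config()].
#' @param arms Arm definitions.
#' @param sample_id Sample label.
#' @return An [arm_counts()] object.
#' @export
simulate_tumor_sample <- function(f, cna, cfg, arms, sample_id = "tumor") {
  if (f < 0 || f > 1) stop("tumour fraction must be in [0, 1]")
  if (any(cna < 0)) stop("copy numbers must be >= 0")
  validate_arms(arms)
  w <- .arm_weights(arms)
  .sample_counts(sample_id, .mixture_weights(w, f, cna), cfg)
}

#' Simulate a full patient cohort with clinical outcomes
#'
#' Per patient: a tumour fraction is drawn from a point mass at zero mixed
#' with a Beta distribution; a copy-number profile from
#' `cfg$cna_profile_generator`; arm counts from the tumour/normal mixture
#' model; a CTC count from a negative binomial whose log-mean rises with
#' tumour fraction; and an exponential survival time with hazard
#' `baseline_hazard * exp(log_hr_aneuploidy * I[aneuploid] + log_hr_ctc *
#' I[CTC >= 5])`, censored by an independent exponential time. The true
#' aneuploidy label is positive when the patient has non-zero tumour
#' fraction and a non-diploid profile. Covariates without a modelled
#' association (age, WHO status, labs) are drawn from distributions typical
#' of a metastatic castration-resistant prostate-cancer cohort.
#'
#' @param cfg A [simulation_config()].
#' @param arms Arm definitions; defaults to the packaged hg19-style table.
#' @param generate_counts Set `FALSE` to skip arm-count simulation (fast
#'   mode for survival-only studies; truth labels still drawn).
#' @return List of class `"simulated_cohort"`: `reference` (panel
#'   [arm_counts()]), `patients` (patient [arm_counts()]), `clinical`
#'   (data.frame, one row per patient), `truth` (per-patient tumour
#'   fraction, copy-number profiles, true labels), `arms`, `config`.
#' @export
simulate_cohort <- function(cfg, arms = NULL, generate_counts = TRUE) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(arms))
    arms <- load_arm_definitions(system.file("extdata",
      "cytoband_hg19_synthetic.tsv", package = "aneuscore"))
  n <- cfg$n_patients
  ids <- sprintf("pt_%03d", seq_len(n))
  w <- .arm_weights(arms)

  f <- ifelse(stats::runif(n) < cfg$tf_zero_prob, 0,
              stats::rbeta(n, cfg$tf_beta[1], cfg$tf_beta[2]))
  cna <- lapply(seq_len(n), function(i) cfg$cna_profile_generator(names(w)))
  aneuploid_true <- f > 0 & vapply(cna, function(cn) any(cn != 2L), TRUE)

  ctc <- stats::rnbinom(n, mu = exp(cfg$ctc_intercept + cfg$ctc_slope * f),
                        size = cfg$ctc_size)
  hazard <- cfg$baseline_hazard *
    exp(cfg$log_hr_aneuploidy * aneuploid_true + cfg$log_hr_ctc * (ctc >= 5))
  t_event <- stats::rexp(n, hazard)
  t_cens <- if (cfg$censoring_rate > 0) stats::rexp(n, cfg$censoring_rate)
            else rep(Inf, n)
  os <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  clinical <- data.frame(
    sample_id = ids,
    os_months = os,
    event = event,
    ctc_count = ctc,
    who_status = sample(0:2, n, replace = TRUE, prob = c(0.38, 0.55, 0.07)),
    age = round(pmin(90, pmax(45, stats::rnorm(n, 70, 7)))),
    gleason = sample(6:10, n, replace = TRUE, prob = c(0.05, 0.2, 0.3, 0.3, 0.15)),
    psa = round(exp(stats::rnorm(n, log(86), 1.5)), 1),
    alb = round(stats::rnorm(n, 40, 4), 1),
    anc = round(pmax(0.5, stats::rnorm(n, 5.4, 2.4)), 1),
    hbg = round(pmax(4, stats::rnorm(n, 7.7, 0.9)), 1),
    wbc = round(pmax(2, stats::rnorm(n, 8, 2.5)), 1),
    alp = round(exp(stats::rnorm(n, log(122), 0.7))),
    ldh = round(exp(stats::rnorm(n, log(240), 0.6))),
    max_vaf = ifelse(f > 0,
                     pmin(0.95, 0.5 * f * exp(stats::rnorm(n, 0, 0.5))),
                     stats::runif(n, 0, 0.02)),
    stringsAsFactors = FALSE)
  clinical$max_vaf[stats::runif(n) < 0.1] <- NA  # assay not run for some

  reference <- patients <- NULL
  if (generate_counts) {
    reference <- simulate_reference_panel(cfg, arms)
    patients <- lapply(seq_len(n), function(i)
      .sample_counts(ids[i], .mixture_weights(w, f[i], cna[[i]]), cfg))
  }
  structure(list(reference = reference, patients = patients,
                 clinical = clinical,
                 truth = list(sample_id = ids, tumor_fraction = f,
                              cna = cna, aneuploid_true = aneuploid_true,
                              ctc_high_true = ctc >= 5),
                 arms = arms, config = cfg),
            class = "simulated_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits the patient and reference arm-count matrices as TSV, the clinical
#' table as CSV, and the generative truth as JSON.
#'
#' @param cohort A `"simulated_cohort"` with counts generated.
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (is.null(cohort$patients))
    stop("cohort was simulated without counts; rerun with generate_counts = TRUE")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(cohort$patients, file.path(outdir, "counts.tsv"))
  write_count_table(cohort$reference, file.path(outdir, "reference_counts.tsv"))
  utils::write.csv(cohort$clinical, file.path(outdir, "clinical.csv"),
                   row.names = FALSE)
  truth <- cohort$truth
  truth$cna <- lapply(truth$cna, as.list)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
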