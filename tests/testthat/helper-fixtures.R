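# Shared fixtures and independent oracles used across the suite.

# Toy arm table: two chromosomes, four arms, all included.
toy_arms <- function(included = rep(TRUE, 4)) {
  structure(data.frame(
    chrom = c("chrT1", "chrT1", "chrT2", "chrT2"),
    arm = c("p", "q", "p", "q"),
    name = c("T1p", "T1q", "T2p", "T2q"),
    start = c(0, 1000, 0, 500),
    end = c(1000, 3000, 500, 2000),
    included = included,
    stringsAsFactors = FALSE),
    class = c("arm_definitions", "data.frame"))
}

packaged_cytoband <- function() {
  system.file("extdata", "cytoband_hg19_synthetic.tsv", package = "aneuscore")
}

# Write a SAM file for the toy chromosomes. reads: data.frame with
# columns qname, flag, rname, pos, mapq.
write_toy_sam <- function(reads, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           "@SQ\tSN:chrT1\tLN:3000",
           "@SQ\tSN:chrT2\tLN:2000",
           "@SQ\tSN:chrUn\tLN:1000")  # present in header, absent from arm table
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t50M\t*\t0\t0\t*\t*",
                  reads$qname, reads$flag, reads$rname, reads$pos, reads$mapq)
  writeLines(c(hdr, body), path)
  path
}

# Independent oracle: Cox partial log-likelihood for a single covariate,
# Breslow form (equal to Efron on tie-free data), maximized numerically.
brute_force_cox_beta <- function(times, events, x, interval = c(-10, 10)) {
  loglik <- function(beta) {
    ll <- 0
    for (i in which(events == 1)) {
      risk <- times >= times[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }
  stats::optimize(loglik, interval, maximum = TRUE, tol = 1e-10)$maximum
}

# Exhaustive cutpoint oracle: scan every candidate with evaluate_threshold.
brute_force_cutpoint <- function(scores, status) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  ss <- vapply(cand, function(t) sum(evaluate_threshold(scores, status, t)), 0)
  best <- which(ss == max(ss))[1]
  list(threshold = cand[best], youden = ss[best] - 1)
}

# Small fast simulation config for cohort-level tests.
fast_config <- function(...) {
  simulation_config(n_reference = 6, n_patients = 30, depth_mean = 20000, ...)
}
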