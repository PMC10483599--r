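#' Construct an arm count vector
#'
#' Container for one sample's read counts over the included chromosome arms.
#' `total_reads` is always recomputed as the sum over included arms, and the
#' low-yield QC flag marks samples whose retained read count falls below the
#' re-sequencing threshold of the assay.
#'
#' @param sample_id Sample identifier.
#' @param counts Named non-negative integer vector over the included arms.
#' @param n_retained Number of mapped, MAPQ-passing reads before arm
#'   exclusion; defaults to `sum(counts)` when counts are the only evidence.
#' @param min_reads Low-yield QC threshold (default 90000 retained reads).
#' @param discards Optional named list tallying dropped reads
#'   (`unmapped`, `secondary`, `low_mapq`, `excluded_arm`, `unassigned`).
#' @return An object of class `"arm_counts"`.
#' @export
arm_counts <- function(sample_id, counts, n_retained = sum(counts),
                       min_reads = 90000, discards = list()) {
  if (is.null(names(counts)) || anyNA(names(counts)))
    stop("counts must be named by arm")
  counts <- stats::setNames(as.integer(round(counts)), names(counts))
  if (any(counts < 0)) stop("negative arm count for sample ", sample_id)
  structure(list(sample_id = sample_id,
                 counts = counts,
                 total_reads = sum(counts),
                 n_retained = n_retained,
                 qc_low_yield = n_retained < min_reads,
                 discards = discards),
            class = "arm_counts")
}

#' @export
print.arm_counts <- function(x, ...) {
  cat("<arm_counts> sample", x$sample_id, "-", length(x$counts), "arms,",
      x$total_reads, "reads",
      if (x$qc_low_yield) "[QC: low yield]" else "", "\n")
  invisible(x)
}

# SAM flag bits
.FLAG_UNMAPPED <- 4L
.FLAG_SECONDARY <- 256L
.FLAG_SUPPLEMENTARY <- 2048L

#' Count aligned reads per chromosome arm
#'
#' Assigns each primary aligned read to the chromosome arm containing its
#' leftmost aligned base (1-based SAM position converted to the 0-based
#' half-open arm intervals). Unmapped reads and reads with mapping quality
#' below `mapq_min` are discarded; secondary and supplementary records are
#' skipped to avoid double counting. Reads on excluded arms or on
#' chromosomes absent from the arm table are tallied separately and do not
#' enter `total_reads`. PCR duplicates are deliberately kept: the assay is
#' amplicon-based, so deduplication would destroy the signal.
#'
#' @param path SAM or BAM file of single-end alignments.
#' @param arms Arm definitions from [load_arm_definitions()].
#' @param mapq_min Minimum mapping quality to retain a read (default 15;
#'   reads with MAPQ < 15 are excluded).
#' @param min_reads Retained-read threshold below which the sample is
#'   flagged for re-sequencing (default 90000). Applied to the count of
#'   mapped, MAPQ-passing reads before arm exclusion.
#' @param sample_id Sample identifier; defaults to the file name.
#' @return An [arm_counts()] object. Its `discards` field tallies every
#'   dropped category so that retained + discarded reads sum to the number
#'   of input records.
#' @export
count_reads_per_arm <- function(path, arms, mapq_min = 15, min_reads = 90000,
                                sample_id = sub("\\.(sam|bam)$", "", basename(path))) {
  validate_arms(arms)
  bam_path <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam_path <- Rsamtools::asBam(path,
                                 destination = tempfile(),
                                 overwrite = TRUE, indexDestination = FALSE)
  }
  rec <- Rsamtools::scanBam(bam_path,
    param = Rsamtools::ScanBamParam(what = c("flag", "rname", "pos", "mapq")))[[1]]
  flag <- rec$flag
  n_input <- length(flag)

  secondary <- bitwAnd(flag, .FLAG_SECONDARY) > 0L |
    bitwAnd(flag, .FLAG_SUPPLEMENTARY) > 0L
  unmapped <- !secondary & bitwAnd(flag, .FLAG_UNMAPPED) > 0L
  mapq <- rec$mapq
  mapq[is.na(mapq)] <- 0L
  low_mapq <- !secondary & !unmapped & mapq < mapq_min
  keep <- !secondary & !unmapped & !low_mapq

  chrom <- as.character(rec$rname)[keep]
  pos0 <- rec$pos[keep] - 1L  # leftmost aligned base, 0-based

  arm_of <- rep(NA_character_, length(chrom))
  for (i in seq_len(nrow(arms))) {
    hit <- chrom == arms$chrom[i] & pos0 >= arms$start[i] & pos0 < arms$end[i]
    arm_of[hit] <- arms$name[i]
  }
  unassigned <- sum(is.na(arm_of))
  incl <- included_arm_names(arms)
  on_excluded <- sum(!is.na(arm_of) & !(arm_of %in% incl))
  counts <- table(factor(arm_of[arm_of %in% incl], levels = incl))
  counts <- stats::setNames(as.integer(counts), incl)

  arm_counts(sample_id, counts,
             n_retained = sum(keep),
             min_reads = min_reads,
             discards = list(n_input = n_input,
                             secondary = sum(secondary),
                             unmapped = sum(unmapped),
                             low_mapq = sum(low_mapq),
                             excluded_arm = on_excluded,
                             unassigned = unassigned))
}

#' Write an arm-count matrix to TSV
#'
#' Rows are arms, columns are samples, first column `arm`.
#'
#' @param samples List of [arm_counts()] objects sharing one arm set.
#' @param path Output TSV path.
#' @export
write_count_table <- function(samples, path) {
  stopifnot(length(samples) > 0)
  arms <- names(samples[[1]]$counts)
  mat <- vapply(samples, function(s) {
    if (!identical(names(s$counts), arms)) stop("samples differ in arm set")
    s$counts
  }, integer(length(arms)))
  colnames(mat) <- vapply(samples, `[[`, "", "sample_id")
  df <- data.frame(arm = arms, mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an arm-count matrix from TSV
#'
#' Validates the arm set against the supplied definitions: every included
#' arm must be present, no unknown or excluded arm may appear, and all
#' cells must be non-negative integers. Totals and QC flags are recomputed,
#' never trusted from the file.
#'
#' @param path TSV written by [write_count_table()] (arms in rows, samples
#'   in columns).
#' @param arms Arm definitions; when supplied, the table's arm set must
#'   equal the included arms.
#' @param min_reads Low-yield QC threshold passed to [arm_counts()].
#' @return List of [arm_counts()] objects, one per sample column.
#' @export
read_count_table <- function(path, arms = NULL, min_reads = 90000) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "arm") stop("first column must be 'arm'")
  arm_names <- df$arm
  mat <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(is.na(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-integer or negative count at arm ", arm_names[bad[1, 1]],
         ", sample ", colnames(mat)[bad[1, 2]])
  if (!is.null(arms)) {
    validate_arms(arms)
    incl <- included_arm_names(arms)
    missing <- setdiff(incl, arm_names)
    if (length(missing) > 0)
      stop("count table missing included arm(s): ", paste(missing, collapse = ", "))
    extra <- setdiff(arm_names, incl)
    if (length(extra) > 0)
      stop("count table contains excluded or unknown arm(s): ",
           paste(extra, collapse = ", "))
    mat <- mat[match(incl, arm_names), , drop = FALSE]
    arm_names <- incl
  }
  lapply(colnames(mat), function(s)
    arm_counts(s, stats::setNames(as.integer(mat[, s]), arm_names),
               min_reads = min_reads))
}
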