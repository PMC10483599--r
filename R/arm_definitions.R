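#' Default excluded chromosome arms
#'
#' The short arms of the acrocentric chromosomes 13, 14, 15 and 22 carry too
#' few LINE-1 elements for stable arm-level counting, and chromosome Y is
#' dropped entirely; these arms are excluded from scoring by default.
#'
#' @param exclude_21p Also exclude 21p. Chromosome 21 is acrocentric too, but
#'   the canonical mFast-SeqS exclusion list keeps it; set `TRUE` to drop it.
#' @return Character vector of arm names (e.g. `"13p"`, `"Yq"`).
#' @export
default_excluded_arms <- function(exclude_21p = FALSE) {
  out <- c("13p", "14p", "15p", "22p", "Yp", "Yq")
  if (exclude_21p) out <- c(out, "21p")
  out
}

#' Load chromosome-arm definitions from a cytoband file
#'
#' Parses a UCSC cytoBand-style TSV (chrom, start, end, band, stain; no
#' header) into one p and one q interval per chromosome. The p arm spans
#' `[0, b)` and the q arm `[b, chromosome end)` where `b` is the p/q band
#' transition, using 0-based half-open coordinates. Arms on the exclusion
#' list are flagged `included = FALSE` but kept in the table so that reads
#' falling on them can be tallied separately.
#'
#' @param path Path to the cytoband TSV. A simplified hg19 file
#'   (real chromosome lengths and centromere boundaries, synthetic banding)
#'   ships with the package; see
#'   `system.file("extdata", "cytoband_hg19_synthetic.tsv", package = "aneuscore")`.
#' @param excluded Arms to flag as excluded; defaults to
#'   [default_excluded_arms()]. Names absent from the file are an error
#'   when `require_complete = TRUE` and ignored otherwise.
#' @param require_complete Require the full chr1-22, X, Y complement
#'   (default TRUE). Set `FALSE` for toy fixtures covering fewer
#'   chromosomes.
#' @return A `data.frame` of class `"arm_definitions"` with columns
#'   `chrom`, `arm` (`"p"`/`"q"`), `name` (e.g. `"1p"`), `start`, `end`,
#'   `included`.
#' @examples
#' cyto <- system.file("extdata", "cytoband_hg19_synthetic.tsv",
#'                     package = "aneuscore")
#' arms <- load_arm_definitions(cyto)
#' sum(arms$included)  # 42
#' @export
load_arm_definitions <- function(path, excluded = default_excluded_arms(),
                                 require_complete = TRUE) {
  bands <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end", "band", "stain"))
  if (any(!grepl("^[pq]", bands$band)))
    stop("unparseable band name(s): ",
         paste(utils::head(bands$band[!grepl("^[pq]", bands$band)], 3), collapse = ", "))
  need <- paste0("chr", c(1:22, "X", "Y"))
  if (require_complete) {
    missing <- setdiff(need, unique(bands$chrom))
    if (length(missing) > 0)
      stop("cytoband file lacks chromosome(s): ", paste(missing, collapse = ", "))
  } else {
    need <- unique(bands$chrom)
  }

  arms <- do.call(rbind, lapply(need, function(ch) {
    b <- bands[bands$chrom == ch, ]
    p <- b[startsWith(b$band, "p"), ]
    q <- b[startsWith(b$band, "q"), ]
    if (nrow(p) == 0 || nrow(q) == 0)
      stop("chromosome ", ch, " lacks p or q bands")
    boundary <- max(p$end)
    if (min(q$start) != boundary)
      stop("p/q bands of ", ch, " do not abut at the centromere")
    short <- sub("^chr", "", ch)
    data.frame(chrom = ch, arm = c("p", "q"),
               name = paste0(short, c("p", "q")),
               start = c(0, boundary),
               end = c(boundary, max(q$end)),
               stringsAsFactors = FALSE)
  }))
  unknown <- setdiff(excluded, arms$name)
  if (length(unknown) > 0) {
    if (require_complete)
      stop("excluded arm(s) not in definition set: ",
           paste(unknown, collapse = ", "))
    excluded <- intersect(excluded, arms$name)
  }
  arms$included <- !(arms$name %in% excluded)
  class(arms) <- c("arm_definitions", "data.frame")
  arms
}

included_arm_names <- function(arms) arms$name[arms$included]

validate_arms <- function(arms) {
  stopifnot(is.data.frame(arms),
            all(c("chrom", "arm", "name", "start", "end", "included") %in% names(arms)))
  if (any(arms$start >= arms$end)) stop("arm with start >= end")
  invisible(arms)
}
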