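#' Spearman correlation with an orthogonal tumour-burden marker
#'
#' Two-sided Spearman rank correlation between the aneuploidy score and a
#' second marker (e.g. maximum variant allele frequency or CTC count),
#' with average ranks for ties and the t-approximation on n-2 degrees of
#' freedom for the p-value. Pairs with a missing value are dropped and
#' counted. A descriptive least-squares line of `y` on `x` is attached.
#'
#' @param x,y Equal-length numeric vectors (x: aneuploidy score).
#' @return Object of class `"association_result"`: `rho`, `p_two_sided`,
#'   `n`, `n_dropped`, `linear` (slope, intercept).
#' @export
spearman_assoc <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  n_dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: rank correlation undefined")
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  lin <- linear_fit(x, y)
  structure(list(rho = unname(ct$estimate),
                 p_two_sided = ct$p.value,
                 n = length(x), n_dropped = n_dropped,
                 linear = lin),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association> rho = %.3f, p = %.3g, n = %d (dropped %d)\n",
              x$rho, x$p_two_sided, x$n, x$n_dropped))
  invisible(x)
}

#' Ordinary least-squares line
#'
#' @param x,y Numeric vectors; `x` must not be constant.
#' @return Named vector `c(slope, intercept)`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::var(x) == 0) stop("constant x: slope undefined")
  co <- stats::coef(stats::lm(y ~ x))
  c(slope = unname(co[2]), intercept = unname(co[1]))
}
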