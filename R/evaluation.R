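#' Predictive ability: Pearson correlation of predicted and observed values
#'
#' The evaluation statistic of genomic prediction: the sample Pearson
#' correlation between GEBVs and observed phenotypes in a testing set.
#' Missing values or degenerate (zero-variance) inputs raise errors rather
#' than being dropped silently.
#'
#' @param predicted,observed numeric vectors of equal length (>= 3).
#' @return The Pearson correlation, in `[-1, 1]`.
#' @export
predictive_ability <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length")
  }
  if (length(predicted) < 3L) stop("at least 3 pairs are required")
  if (anyNA(predicted) || anyNA(observed)) {
    stop("missing values are not allowed")
  }
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    stop("zero variance in predicted or observed values")
  }
  stats::cor(predicted, observed)
}

# round half away from zero (for positive x: 0.5 -> 1)
round_half_up <- function(x) floor(x + 0.5)

#' Overlap ratio of top-ranked accessions
#'
#' Fraction of accessions shared between the top `k` by predicted value and
#' the top `k` by observed value — the "ratio (predicted/observed)" used to
#' judge whether a model ranks the best material correctly. Either an
#' absolute `k` (e.g. top 30) or a `fraction` of the cohort (e.g. top 30%,
#' converted to `k = max(1, round(fraction * n))`, rounding half away from
#' zero) may be given. `direction` sets whether large (`"descending"`, the
#' default) or small (`"ascending"`) values are "top"; ties are broken by
#' the stable original (accession) order, so the result is deterministic.
#'
#' @param predicted,observed numeric vectors of equal length.
#' @param k top-set size (`0 < k <= n`); exactly one of `k`/`fraction`.
#' @param fraction top fraction in `(0, 1]`.
#' @param direction `"descending"` (larger is better) or `"ascending"`.
#' @return The overlap ratio, in `[0, 1]`.
#' @export
topk_overlap <- function(predicted, observed, k = NULL, fraction = NULL,
                         direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  n <- length(predicted)
  if (n == 0L || length(observed) != n) {
    stop("predicted and observed must be non-empty and of equal length")
  }
  if (is.null(k) == is.null(fraction)) {
    stop("supply exactly one of k or fraction")
  }
  if (!is.null(fraction)) {
    if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
    k <- max(1L, as.integer(round_half_up(fraction * n)))
  }
  if (k <= 0 || k > n) stop("k must lie in (0, n]")
  top_set <- function(v) {
    key <- if (direction == "descending") -v else v
    order(key, seq_len(n))[seq_len(k)]
  }
  length(intersect(top_set(predicted), top_set(observed))) / k
}
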