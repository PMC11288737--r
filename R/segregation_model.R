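# Fertility algebra under random univalent segregation, Mendelian
# segregation-ratio testing, and fold-change arithmetic.

#' Probability of balanced segregation of univalents
#'
#' Each achiasmate homolog pair resolves as two univalents that migrate
#' independently at anaphase I; the pair is balanced (one univalent to
#' each pole) with probability 1/2. With `u` univalent pairs the chance
#' that a daughter nucleus receives the complete chromosome set is
#' `(1/2)^u`. A fractional `u` is allowed as a plug-in of a mean
#' univalent-pair count.
#'
#' @param u_pairs univalent pair count, >= 0 (possibly fractional).
#' @return probability `(1/2)^u_pairs`.
#' @examples
#' p_balanced(5)  * 100  # 3.125% — 10 univalents
#' p_balanced(10) * 100  # ~0.10% — 20 univalents
#' p_balanced(13.6) * 100 # ~0.008% — plug-in for 6.4 bivalents out of 20
#' @export
p_balanced <- function(u_pairs) {
  if (any(!is.finite(u_pairs)) || any(u_pairs < 0))
    stop("u_pairs must be >= 0")
  0.5^u_pairs
}

#' Expected balanced-set probability from bivalent counts
#'
#' Converts observed bivalent formation into the probability that a
#' meiotic product carries one copy of every chromosome, under random
#' univalent segregation. Two estimators are provided:
#'
#' * `plugin` (default): `u = n_pairs - mean_bivalents` and
#'   `p = 2^-u` — the mean is plugged into the exponent, the convention
#'   used when quoting a single headline probability.
#' * `distributional`: the exact expectation
#'   `mean(2^-(n_pairs - b_cell))` over per-cell bivalent counts. By
#'   Jensen's inequality this is never smaller than the plug-in value,
#'   with equality only for constant counts.
#'
#' @param mean_bivalents mean bivalents per meiocyte (ignored when
#'   `bivalent_counts` is given and NULL).
#' @param bivalent_counts per-cell bivalent counts (required for
#'   `mode = "distributional"`).
#' @param n_pairs karyotype pair count (soybean: 20).
#' @param mode `"plugin"` or `"distributional"`.
#' @return list with `u_effective`, `p_balanced`, `percent` (half-up,
#'   3 decimals) and `mode`.
#' @examples
#' expected_balanced_from_bivalents(6.40)$percent  # 0.008
#' @export
expected_balanced_from_bivalents <- function(mean_bivalents = NULL,
                                             bivalent_counts = NULL,
                                             n_pairs = 20L,
                                             mode = c("plugin", "distributional")) {
  mode <- match.arg(mode)
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (!is.null(bivalent_counts)) {
    if (any(bivalent_counts < 0 | bivalent_counts > n_pairs))
      stop("bivalent counts must lie in [0, n_pairs]")
    mean_bivalents <- mean_bivalents %||% mean(bivalent_counts)
  }
  if (is.null(mean_bivalents)) stop("supply mean_bivalents or bivalent_counts")
  if (mean_bivalents < 0 || mean_bivalents > n_pairs)
    stop("mean_bivalents must lie in [0, n_pairs]")
  if (mode == "distributional") {
    if (is.null(bivalent_counts))
      stop("distributional mode requires per-cell bivalent_counts")
    p <- mean(p_balanced(n_pairs - bivalent_counts))
    u <- -log2(p)
  } else {
    u <- n_pairs - mean_bivalents
    p <- p_balanced(u)
  }
  list(u_effective = u, p_balanced = p,
       percent = round_half_up(100 * p, 3), mode = mode)
}

#' Chi-squared test of a Mendelian segregation ratio
#'
#' Goodness of fit of observed phenotype-class counts to a stated ratio
#' (3:1 by default, the F2 expectation for a single recessive mutation).
#' The statistic is the uncorrected Pearson chi-squared
#' `sum((O - E)^2 / E)`; a Yates continuity correction is available via
#' `correct = TRUE` but is off by default. The `consistent` flag compares
#' the statistic against the critical value at `alpha` (3.84 for df = 1,
#' alpha = 0.05).
#'
#' @param counts integer vector of observed class counts, e.g.
#'   `c(fertile = 142, sterile = 39)`.
#' @param ratio positive expected ratio, same length as `counts`
#'   (default `c(3, 1)`).
#' @param correct apply the Yates continuity correction.
#' @param alpha level for the consistency verdict (default 0.05).
#' @return classes `ratio_chisq` and `htest`, with `statistic`,
#'   `parameter` (df), `p.value`, `expected`, `critical_value` and
#'   `consistent`.
#' @examples
#' chi_square_ratio_test(c(142, 39))$statistic  # ~1.15, consistent with 3:1
#' @export
chi_square_ratio_test <- function(counts, ratio = c(3, 1),
                                  correct = FALSE, alpha = 0.05) {
  if (length(counts) != length(ratio) || length(counts) < 2L)
    stop("counts and ratio must have equal length >= 2")
  if (any(ratio <= 0)) stop("ratio components must be > 0")
  if (any(counts < 0) || sum(counts) < 1) stop("need non-negative counts, total >= 1")
  p <- ratio / sum(ratio)
  expected <- sum(counts) * p
  if (any(expected < 1)) stop("expected count below 1 in some class")
  df <- length(counts) - 1L
  if (correct) {
    chi2 <- sum((pmax(abs(counts - expected) - 0.5, 0))^2 / expected)
    pval <- stats::pchisq(chi2, df, lower.tail = FALSE)
  } else {
    ct <- suppressWarnings(stats::chisq.test(counts, p = p, correct = FALSE))
    chi2 <- unname(ct$statistic)
    pval <- ct$p.value
  }
  crit <- stats::qchisq(1 - alpha, df)
  structure(list(
    statistic = c(`X-squared` = chi2),
    parameter = c(df = df),
    p.value = pval,
    expected = expected,
    method = sprintf("Chi-squared goodness of fit to a %s ratio%s",
                     paste(ratio, collapse = ":"),
                     if (correct) " (Yates-corrected)" else ""),
    data.name = deparse1(substitute(counts)),
    critical_value = crit,
    alpha = alpha,
    consistent = chi2 < crit
  ), class = c("ratio_chisq", "htest"))
}

#' Fold change between two frequencies
#'
#' Simple ratio `treated / untreated`, reported to two decimals
#' (half-up); used for aberrant-mitosis frequencies after mutagen
#' treatment.
#'
#' @param treated_freq frequency in treated material.
#' @param untreated_freq frequency in untreated material, > 0.
#' @return fold change rounded to 2 decimals.
#' @examples
#' fold_change(2.67, 1.19)  # 2.24
#' @export
fold_change <- function(treated_freq, untreated_freq) {
  if (!is.finite(untreated_freq) || untreated_freq <= 0)
    stop("untreated_freq must be > 0")
  round_half_up(treated_freq / untreated_freq, 2)
}
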