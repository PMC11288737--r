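# Chiasma-count statistics: morphology scoring, summaries, Poisson
# prediction and a discrete Kolmogorov-Smirnov goodness-of-fit test.
#
# Interference-sensitive (Class I) crossovers are under-dispersed across
# meiocytes; interference-insensitive (Class II) crossovers are Poisson.
# Comparing the per-cell chiasma-count distribution with its fitted
# Poisson prediction therefore discriminates the two pathways.

#' Chiasma count from bivalent morphology
#'
#' Scores chiasmata from chromosome morphology at diakinesis/metaphase I
#' using the standard cytogenetic convention: a ring bivalent (chiasmata
#' in both arms) counts 2, a rod bivalent (one arm) counts 1, and a
#' univalent pair (no chiasmate association) counts 0.
#'
#' @param n_ring number of ring bivalents (vectorised).
#' @param n_rod number of rod bivalents.
#' @param n_univalent_pairs number of achiasmate homolog pairs; they
#'   contribute no chiasmata and are accepted only so a full karyotype
#'   can be passed through.
#' @return integer vector of chiasma counts, `2*n_ring + n_rod`.
#' @examples
#' chiasmata_from_morphology(18, 2)   # 38, a typical wild-type soybean cell
#' chiasmata_from_morphology(0, 0, 20) # 0, fully asynaptic
#' @export
chiasmata_from_morphology <- function(n_ring, n_rod, n_univalent_pairs = 0L) {
  for (v in list(n_ring, n_rod, n_univalent_pairs)) {
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
      stop("morphology counts must be non-negative integers")
  }
  as.integer(2L * n_ring + n_rod + 0L * n_univalent_pairs)
}

#' Assemble a per-meiocyte chiasma dataset
#'
#' Builds the container consumed by [chiasma_summary()] and
#' [ks_poisson_test()]. Either per-cell chiasma counts are supplied
#' directly, or they are derived from ring/rod morphology via
#' [chiasmata_from_morphology()].
#'
#' @param x a numeric vector of per-cell chiasma counts, or a data frame
#'   with columns among `cell_id`, `n_ring`, `n_rod`, `n_bivalents`,
#'   `n_chiasmata`, `n_lagging` (the cytology-table layout read by
#'   [read_cytology()]).
#' @param n_pairs karyotype size (homolog pairs); soybean has 20. Used
#'   only to validate `n_bivalents`.
#' @return an object of class `chiasma_dataset`: a data frame of
#'   observations with at least `cell_id` and `n_chiasmata`.
#' @export
chiasma_dataset <- function(x, n_pairs = 20L) {
  if (is.numeric(x)) {
    x <- data.frame(cell_id = paste0("cell", seq_along(x)),
                    n_chiasmata = as.integer(x))
  }
  stopifnot(is.data.frame(x))
  obs <- as.data.frame(x)
  has <- function(nm) nm %in% names(obs) && !all(is.na(obs[[nm]]))

  if (!has("cell_id")) obs$cell_id <- paste0("cell", seq_len(nrow(obs)))
  if (has("n_ring") && has("n_rod")) {
    derived_chi <- chiasmata_from_morphology(obs$n_ring, obs$n_rod)
    derived_biv <- as.integer(obs$n_ring + obs$n_rod)
    if (has("n_chiasmata")) {
      if (any(obs$n_chiasmata != derived_chi))
        stop("n_chiasmata inconsistent with ring/rod morphology (2*ring + rod)")
    } else obs$n_chiasmata <- derived_chi
    if (has("n_bivalents")) {
      if (any(obs$n_bivalents != derived_biv))
        stop("n_bivalents inconsistent with ring/rod morphology (ring + rod)")
    } else obs$n_bivalents <- derived_biv
  }
  if (!has("n_chiasmata"))
    stop("supply n_chiasmata or ring/rod morphology columns")
  if (any(obs$n_chiasmata < 0)) stop("chiasma counts must be >= 0")
  if (has("n_bivalents")) {
    if (any(obs$n_bivalents < 0 | obs$n_bivalents > n_pairs))
      stop("n_bivalents must lie in [0, n_pairs]")
    if (any(obs$n_chiasmata < obs$n_bivalents))
      stop("every bivalent carries >= 1 chiasma, so n_chiasmata >= n_bivalents")
  }
  structure(obs, class = c("chiasma_dataset", "data.frame"),
            n_pairs = as.integer(n_pairs))
}

#' @export
print.chiasma_dataset <- function(x, ...) {
  cat(sprintf("<chiasma_dataset> %d meiocytes (karyotype: %d pairs)\n",
              nrow(x), attr(x, "n_pairs")))
  if (nrow(x) >= 2L) {
    s <- chiasma_summary(x)
    cat(sprintf("  chiasmata/cell: mean %.2f, sd %.2f, dispersion index %.4f\n",
                s$mean, s$sd, s$dispersion_index))
  }
  invisible(x)
}

#' Summary statistics of per-cell chiasma counts
#'
#' @param x a `chiasma_dataset` or a numeric vector of per-cell counts.
#' @return a list with `n_cells`, `mean`, `sd` (sample SD, n-1
#'   denominator) and `dispersion_index` (variance/mean; 1 for Poisson
#'   counts, below 1 under crossover interference; defined as 0 when the
#'   mean is 0).
#' @examples
#' chiasma_summary(c(7, 9))  # mean 8, sd sqrt(2), dispersion 0.25
#' @export
chiasma_summary <- function(x) {
  counts <- if (inherits(x, "chiasma_dataset")) x$n_chiasmata else x
  if (length(counts) == 0L) stop("empty dataset")
  if (length(counts) < 2L) stop("at least 2 cells required (sample SD undefined)")
  m <- mean(counts)
  s <- stats::sd(counts)
  list(n_cells = length(counts), mean = m, sd = s,
       dispersion_index = if (m == 0) 0 else s^2 / m)
}

#' Percent reduction relative to a reference mean
#'
#' `100 * (reference - mutant) / reference`, reported to two decimals
#' (half-up), the form in which crossover and bivalent losses are quoted.
#'
#' @param reference_mean reference (e.g. wild-type) mean, must be > 0.
#' @param mutant_mean comparison mean.
#' @return percentage reduction rounded to 2 decimals.
#' @examples
#' percent_reduction(38.50, 8.41)  # 78.16
#' percent_reduction(20, 6.40)     # 68.00
#' @export
percent_reduction <- function(reference_mean, mutant_mean) {
  if (!is.finite(reference_mean) || reference_mean <= 0)
    stop("reference_mean must be > 0")
  round_half_up(100 * (reference_mean - mutant_mean) / reference_mean, 2)
}

#' Expected cell counts under a Poisson chiasma model
#'
#' Tabulates `n_cells * dpois(k, lam)` for k = 0..`support_max`, the
#' "predicted" series plotted against observed chiasma-count histograms.
#' The truncated tail mass beyond `support_max` is folded into the last
#' bin so the table sums exactly to `n_cells`.
#'
#' @param lam Poisson mean (chiasmata per cell), > 0.
#' @param n_cells number of cells the expectation is scaled to.
#' @param support_max largest tabulated count; defaults to
#'   `ceiling(lam + 10*sqrt(lam))`.
#' @param fold_tail fold tail mass into the last bin (default TRUE).
#' @return named numeric vector of expected cell counts for k = 0..support_max.
#' @export
predicted_poisson_counts <- function(lam, n_cells,
                                     support_max = NULL, fold_tail = TRUE) {
  if (!is.finite(lam) || lam <= 0) stop("lam must be > 0")
  if (n_cells < 1) stop("n_cells must be >= 1")
  support_max <- as.integer(support_max %||% ceiling(lam + 10 * sqrt(lam)))
  k <- 0:support_max
  e <- n_cells * stats::dpois(k, lam)
  if (fold_tail)
    e[length(e)] <- n_cells * stats::ppois(support_max - 1L, lam,
                                           lower.tail = FALSE)
  stats::setNames(e, k)
}

#' Observed versus predicted chiasma-count table
#'
#' Convenience table for plotting the observed count histogram against
#' its fitted Poisson prediction.
#'
#' @inheritParams chiasma_summary
#' @param lam Poisson mean; defaults to the sample mean.
#' @param support_max see [predicted_poisson_counts()]; defaults to
#'   covering both the data and the Poisson bulk.
#' @return data frame with columns `k`, `observed`, `expected`.
#' @export
poisson_expectation_table <- function(x, lam = NULL, support_max = NULL) {
  counts <- if (inherits(x, "chiasma_dataset")) x$n_chiasmata else x
  lam <- lam %||% mean(counts)
  support_max <- as.integer(
    support_max %||% max(max(counts), ceiling(lam + 10 * sqrt(lam))))
  k <- 0:support_max
  obs <- tabulate(counts + 1L, nbins = support_max + 1L)
  data.frame(k = k, observed = obs,
             expected = unname(predicted_poisson_counts(
               lam, length(counts), support_max)))
}

# D = sup_k |F_n(k) - F_lambda(k)| over the integer support 0..max(counts).
# Beyond max(counts) the empirical CDF is 1 and |1 - F_lambda(k)| only
# shrinks, so this range attains the supremum over all integers.
ks_stat_poisson <- function(counts, lambda) {
  kmax <- max(counts)
  fn <- cumsum(tabulate(counts + 1L, nbins = kmax + 1L)) / length(counts)
  max(abs(fn - stats::ppois(0:kmax, lambda)))
}

# Survival function of the Kolmogorov distribution at t = sqrt(n) * D.
kolmogorov_sf <- function(t) {
  if (t < 1e-8) return(1)
  j <- 1:100
  min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))))
}

# Vectorised bootstrap D* for B Poisson resamples of size n.
# Returns the vector of B statistics; lambda re-estimated per resample
# when estimate is TRUE.
ks_boot_stats <- function(B, n, lambda, estimate = TRUE) {
  x <- matrix(stats::rpois(B * n, lambda), nrow = B)
  lam <- if (estimate) rowMeans(x) else rep(lambda, B)
  kmax <- max(x)
  # row-wise tabulation via a single tabulate() call; linear index is
  # column-major in the B x (kmax+1) layout: value k of row r sits at
  # k*B + r
  idx <- as.vector(x) * B + rep.int(seq_len(B), n)
  tab <- matrix(tabulate(idx, nbins = B * (kmax + 1L)),
                nrow = B, ncol = kmax + 1L)
  fn <- tab
  for (k in seq_len(kmax)) fn[, k + 1L] <- fn[, k + 1L] + fn[, k]
  fn <- fn / n
  d <- numeric(B)
  for (k in 0:kmax) {
    diff_k <- abs(fn[, k + 1L] - stats::ppois(k, lam))
    d <- pmax(d, diff_k)
  }
  d
}

#' Kolmogorov-Smirnov goodness of fit of chiasma counts to a Poisson model
#'
#' One-sample KS test of integer per-cell counts against a Poisson
#' distribution, with the D statistic evaluated correctly on the discrete
#' support: `D = sup_k |F_n(k) - F_lambda(k)|` over integers k. Because
#' the null is discrete and lambda is estimated from the data, the
#' classical asymptotic p-value is misspecified (conservative); the
#' default is therefore a parametric bootstrap in which each resample is
#' drawn from Poisson(lambda-hat) and lambda re-estimated, with
#' `p = (1 + #{D* >= D}) / (B + 1)`. The asymptotic mode (Kolmogorov
#' limiting distribution at `sqrt(n) * D`) is retained for comparability
#' with reports that used it.
#'
#' A non-rejection says the counts are compatible with a Poisson
#' (interference-free, Class II-like) crossover process; a rejection with
#' dispersion index < 1 indicates interference.
#'
#' @param counts integer per-cell chiasma counts (or a `chiasma_dataset`);
#'   at least 5 cells.
#' @param model null model family; only `"poisson"`.
#' @param method `"bootstrap"` (default) or `"asymptotic"`.
#' @param n_boot bootstrap replicates B (default 2000).
#' @param lambda optional fixed Poisson mean; when NULL (default) the
#'   sample mean is used and the bootstrap re-estimates it per resample.
#' @param alpha rejection level for the `reject_at_alpha` flag; 0.01 by
#'   convention for this comparison.
#' @param seed optional integer seed for the bootstrap (the caller's RNG
#'   state is untouched).
#' @return an object of classes `poisson_ks` and `htest` with `statistic`
#'   (D), `p.value`, `estimate` (lambda-hat), and additionally `n`,
#'   `n_boot`, `alpha`, `reject_at_alpha` and `ks_method`.
#' @examples
#' ks_poisson_test(c(0, 1, 2), lambda = 1, method = "asymptotic")$statistic
#' @export
ks_poisson_test <- function(counts, model = "poisson",
                            method = c("bootstrap", "asymptotic"),
                            n_boot = 2000L, lambda = NULL,
                            alpha = 0.01, seed = NULL) {
  dname <- deparse1(substitute(counts))
  if (inherits(counts, "chiasma_dataset")) counts <- counts$n_chiasmata
  model <- match.arg(model, "poisson")
  method <- match.arg(method)
  if (length(counts) < 5L && is.null(lambda))
    stop("at least 5 cells required")
  if (any(counts < 0 | counts != round(counts)))
    stop("counts must be non-negative integers")
  n <- length(counts)
  estimate <- is.null(lambda)
  lam_hat <- lambda %||% mean(counts)

  if (lam_hat == 0) {
    warning("all counts are zero: degenerate data, p set to 1")
    d <- 0
    p <- 1
  } else {
    d <- ks_stat_poisson(counts, lam_hat)
    p <- if (method == "asymptotic") {
      kolmogorov_sf(sqrt(n) * d)
    } else {
      dstar <- with_seed_if(seed,
                            ks_boot_stats(n_boot, n, lam_hat, estimate))
      (1 + sum(dstar >= d)) / (n_boot + 1)
    }
  }
  structure(list(
    statistic = c(D = d),
    p.value = p,
    estimate = c(lambda = lam_hat),
    parameter = c(n = n),
    method = sprintf("One-sample Kolmogorov-Smirnov test against Poisson (%s p-value)",
                     method),
    data.name = dname,
    n = n, n_boot = if (method == "bootstrap") n_boot else NA_integer_,
    alpha = alpha, ks_method = method,
    reject_at_alpha = p < alpha
  ), class = c("poisson_ks", "htest"))
}

#' Read a per-meiocyte cytology table
#'
#' Reads a delimited text table with header columns among `cell_id`,
#' `n_ring`, `n_rod`, `n_bivalents`, `n_chiasmata`, `n_lagging`.
#' Morphology columns may be omitted when `n_chiasmata` is given, and
#' vice versa. Comment lines starting with `#` (e.g. a simulation
#' parameter echo) are skipped.
#'
#' @param path file path; `.tsv`/`.txt` are read as tab-separated,
#'   anything else as comma-separated unless `sep` is given.
#' @param sep field separator; inferred from the extension by default.
#' @param n_pairs karyotype pair count used for validation.
#' @return a [chiasma_dataset()].
#' @export
read_cytology <- function(path, sep = NULL, n_pairs = 20L) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- sep %||% if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  chiasma_dataset(df, n_pairs = n_pairs)
}

#' Write a per-meiocyte cytology table
#'
#' @param x a `chiasma_dataset` (or compatible data frame).
#' @param path output path; separator chosen as in [read_cytology()].
#' @param header_lines optional character vector written as `#` comment
#'   lines before the table (used to echo simulation parameters).
#' @return `path`, invisibly.
#' @export
write_cytology <- function(x, path, header_lines = NULL) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines))
    writeLines(paste0("# ", header_lines), con)
  utils::write.table(as.data.frame(x), con, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
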