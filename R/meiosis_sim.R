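# Forward simulator of meiosis I crossover assignment and segregation.
#
# Two crossover pathways per homolog pair:
#   Class I  - interference-sensitive: one obligate CO per pair (when
#              enabled) plus an under-dispersed "extra" count whose
#              variance/mean ratio encodes the strength of interference;
#   Class II - interference-insensitive: Poisson(lambda2) per pair.
# A pair with >= 1 CO forms a bivalent; achiasmate pairs resolve as two
# univalents, each pair segregating in a balanced way with probability
# 1/2 independently. Lagging univalents at anaphase are Binomial.

#' Meiosis simulation parameters
#'
#' @param n_pairs homolog pair count (soybean: 20).
#' @param class1_enabled is the Class I (interference-sensitive) pathway
#'   active? FALSE reproduces an mlh1-type mutant.
#' @param class1_mean_extra mean non-obligate Class I COs per pair.
#' @param class1_dispersion variance/mean of the per-pair Class I CO
#'   count, in (0, 1]; values < 1 encode interference-driven
#'   under-dispersion, 1 gives Poisson counts.
#' @param class2_rate Poisson mean of Class II COs per pair (lambda2).
#' @param p_lag probability that a univalent lags at anaphase I.
#' @param obligate_co guarantee one Class I CO per pair when the pathway
#'   is enabled (wild-type soybean forms 20/20 bivalents without fail).
#' @return validated object of class `meiosis_params`.
#' @export
meiosis_params <- function(n_pairs = 20L, class1_enabled = TRUE,
                           class1_mean_extra = 0.925,
                           class1_dispersion = 1.41^2 / 38.50,
                           class2_rate = 0, p_lag = 0.5,
                           obligate_co = TRUE) {
  stopifnot(n_pairs >= 1, n_pairs == round(n_pairs),
            is.logical(class1_enabled), is.logical(obligate_co),
            class1_mean_extra >= 0, class2_rate >= 0,
            p_lag >= 0, p_lag <= 1)
  if (class1_dispersion <= 0 || class1_dispersion > 1)
    stop("class1_dispersion must lie in (0, 1]")
  p <- list(n_pairs = as.integer(n_pairs), class1_enabled = class1_enabled,
            class1_mean_extra = class1_mean_extra,
            class1_dispersion = class1_dispersion,
            class2_rate = class2_rate, p_lag = p_lag,
            obligate_co = obligate_co)
  if (class1_enabled) rcount_meanvar(0, class1_extra_mean(p), class1_extra_var(p))
  structure(p, class = "meiosis_params")
}

#' @export
print.meiosis_params <- function(x, ...) {
  cat("<meiosis_params>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

class1_extra_mean <- function(params) params$class1_mean_extra

# The dispersion parameter is defined on the *total* per-pair Class I
# count (obligate + extra); the extra draw must therefore carry variance
# d * (obligate + mean_extra). With no extras the count is degenerate
# and the dispersion parameter is moot.
class1_extra_var <- function(params) {
  if (params$class1_mean_extra == 0) return(0)
  base <- if (params$obligate_co) 1 else 0
  params$class1_dispersion * (base + params$class1_mean_extra)
}

# Integer draws with exact mean m and variance v <= m: a mixture of
# Poisson(m) (weight w) and the two-point lattice distribution on
# {floor(m), floor(m)+1} with mean m (weight 1 - w). Both components
# share the mean, so the mixture variance is w*m + (1-w)*f*(1-f) with
# f = frac(m); solving for w matches v exactly. v = m gives w = 1, i.e.
# exactly Poisson; v at the lattice minimum f*(1-f) gives the maximally
# regular integer draw.
rcount_meanvar <- function(n, m, v) {
  if (m == 0) {
    if (v > 1e-12) stop("variance must be 0 when the mean is 0")
    return(integer(n))
  }
  f <- m - floor(m)
  vmin <- f * (1 - f)
  if (v > m + 1e-12)
    stop(sprintf("requested variance %.4g exceeds the mean %.4g: ",
                 v, m),
         "over-dispersed Class I counts are not supported")
  if (v < vmin - 1e-12)
    stop(sprintf(
      "requested variance %.4g is below the integer-lattice minimum %.4g for mean %.4g",
      v, vmin, m))
  w <- if (m - vmin < 1e-12) 1 else min(1, max(0, (v - vmin) / (m - vmin)))
  if (n == 0) return(integer(0))
  pois <- stats::runif(n) < w
  out <- integer(n)
  out[pois] <- stats::rpois(sum(pois), m)
  out[!pois] <- floor(m) + (stats::runif(sum(!pois)) < f)
  out
}

# Matrix of per-pair CO counts (n_pairs x n_cells).
sim_pair_counts <- function(params, n_cells) {
  np <- params$n_pairs
  total <- np * n_cells
  counts <- matrix(0L, nrow = np, ncol = n_cells)
  if (params$class1_enabled) {
    extra <- rcount_meanvar(total, class1_extra_mean(params),
                            class1_extra_var(params))
    counts <- counts + matrix(extra, nrow = np) +
      (if (params$obligate_co) 1L else 0L)
  }
  if (params$class2_rate > 0)
    counts <- counts + matrix(stats::rpois(total, params$class2_rate),
                              nrow = np)
  counts
}

#' Simulate a single meiocyte
#'
#' @param params a [meiosis_params()] object.
#' @param seed optional integer seed.
#' @return list of class `simulated_meiocyte` with `per_pair_co_counts`,
#'   `n_bivalents`, `n_chiasmata`, `daughter_balanced` and `n_lagging`.
#' @export
simulate_meiocyte <- function(params, seed = NULL) {
  stopifnot(inherits(params, "meiosis_params"))
  with_seed_if(seed, {
    co <- as.integer(sim_pair_counts(params, 1L))
    u_pairs <- sum(co == 0L)
    balanced_pairs <- stats::rbinom(1L, u_pairs, 0.5)
    structure(list(
      per_pair_co_counts = co,
      n_bivalents = sum(co >= 1L),
      n_chiasmata = sum(co),
      daughter_balanced = balanced_pairs == u_pairs,
      n_lagging = stats::rbinom(1L, 2L * u_pairs, params$p_lag)
    ), class = "simulated_meiocyte")
  })
}

#' Simulate a cytology dataset of independent meiocytes
#'
#' Batch forward simulation; the result is a [chiasma_dataset()] carrying
#' `n_bivalents`, `n_chiasmata`, `n_lagging` and `daughter_balanced` per
#' cell, directly consumable by the chiasma statistics functions.
#' Deterministic under a fixed seed.
#'
#' @param params a [meiosis_params()] object.
#' @param n_cells number of meiocytes, >= 1.
#' @param seed optional integer seed.
#' @return a `chiasma_dataset` with simulation columns; the parameters
#'   and seed are attached as attributes `params` and `seed`.
#' @export
simulate_dataset <- function(params, n_cells, seed = NULL) {
  stopifnot(inherits(params, "meiosis_params"))
  if (n_cells < 1) stop("n_cells must be >= 1")
  n_cells <- as.integer(n_cells)
  df <- with_seed_if(seed, {
    co <- sim_pair_counts(params, n_cells)
    biv <- colSums(co >= 1L)
    u_pairs <- params$n_pairs - biv
    balanced <- stats::rbinom(n_cells, u_pairs, 0.5) == u_pairs
    data.frame(cell_id = sprintf("cell%04d", seq_len(n_cells)),
               n_bivalents = as.integer(biv),
               n_chiasmata = as.integer(colSums(co)),
               n_lagging = stats::rbinom(n_cells, 2L * u_pairs, params$p_lag),
               daughter_balanced = balanced)
  })
  out <- chiasma_dataset(df, n_pairs = params$n_pairs)
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  out
}

#' Calibrate the Class II crossover rate to an observed mean
#'
#' Inverts the interference-free (pure Class II) model: with per-pair
#' Poisson(lambda2) COs, the expected bivalent count is
#' `n_pairs * (1 - exp(-lambda2))` and the expected chiasma count is
#' `n_pairs * lambda2`; so
#' `lambda2 = -log(1 - value/n_pairs)` for a bivalent target and
#' `lambda2 = value/n_pairs` for a chiasma target.
#'
#' @param target `"mean_bivalents"` or `"mean_chiasmata"`.
#' @param value target mean; in (0, n_pairs) for bivalents, > 0 for
#'   chiasmata.
#' @param n_pairs homolog pair count.
#' @return the per-pair Class II rate lambda2.
#' @examples
#' calibrate_class2_rate("mean_bivalents", 6.40)  # -log(0.68) ~ 0.3857
#' calibrate_class2_rate("mean_chiasmata", 8.41)  # 0.4205
#' @export
calibrate_class2_rate <- function(target = c("mean_bivalents", "mean_chiasmata"),
                                  value, n_pairs = 20L) {
  target <- match.arg(target)
  if (target == "mean_bivalents") {
    if (value <= 0 || value >= n_pairs)
      stop("bivalent target must lie in (0, n_pairs)")
    -log(1 - value / n_pairs)
  } else {
    if (value <= 0) stop("chiasma target must be > 0")
    value / n_pairs
  }
}
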