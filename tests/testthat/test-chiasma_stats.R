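test_that("morphology scoring follows the ring=2 / rod=1 convention and is additive", {
  expect_equal(chiasmata_from_morphology(0, 0, 20), 0L)
  expect_equal(chiasmata_from_morphology(20, 0, 0), 40L)
  expect_equal(chiasmata_from_morphology(18, 2, 0), 38L)
  expect_error(chiasmata_from_morphology(-1, 0), "non-negative")
  expect_error(chiasmata_from_morphology(1.5, 0), "integer")

  set.seed(11)
  for (i in 1:25) {
    a <- sample(0:10, 1); b <- sample(0:10, 1)
    c_ <- sample(0:10, 1); d_ <- sample(0:10, 1)
    expect_equal(chiasmata_from_morphology(a + b, c_ + d_),
                 chiasmata_from_morphology(a, c_) +
                   chiasmata_from_morphology(b, d_))
  }
})

test_that("summary statistics use the sample SD and dispersion = variance/mean", {
  s <- chiasma_summary(c(8, 8, 8))
  expect_equal(s$mean, 8)
  expect_equal(s$sd, 0)
  expect_equal(s$dispersion_index, 0)

  s <- chiasma_summary(c(7, 9))
  expect_equal(s$mean, 8)
  expect_equal(s$sd, sqrt(2))
  expect_equal(s$dispersion_index, 0.25)

  # dispersion is sd^2/mean for arbitrary counts
  set.seed(3)
  x <- rpois(40, 6)
  s <- chiasma_summary(x)
  expect_equal(s$dispersion_index, var(x) / mean(x))

  expect_error(chiasma_summary(numeric(0)), "empty")
  expect_error(chiasma_summary(5), "2 cells")
})

test_that("a WT-like under-dispersed dataset has dispersion index near 0.052", {
  # moments as printed for the wild type: mean 38.50, SD 1.41
  d <- simulate_dataset(meiosis_preset("wildtype"), 2000, seed = 7)
  s <- chiasma_summary(d)
  expect_equal(s$mean, 38.50, tolerance = 0.01)
  expect_equal(s$dispersion_index, 1.41^2 / 38.50, tolerance = 0.15)
})

test_that("percent reduction reproduces the headline crossover/bivalent losses", {
  expect_equal(percent_reduction(38.50, 8.41), 78.16)
  expect_equal(percent_reduction(20, 6.40), 68.00)
  expect_equal(percent_reduction(12.3, 12.3), 0)
  expect_error(percent_reduction(0, 1), "> 0")
  expect_error(percent_reduction(-2, 1), "> 0")
})

test_that("predicted Poisson counts match the closed form and sum to n_cells", {
  e <- predicted_poisson_counts(1, 100)
  expect_equal(unname(e[1]), 100 * exp(-1), tolerance = 1e-10)
  expect_equal(sum(e), 100, tolerance = 1e-9)

  e <- predicted_poisson_counts(8.41, 158, support_max = 30)
  expect_equal(sum(e), 158, tolerance = 0.01)
  expect_true(all(e >= 0))
  # scaled by 1/n it is a pmf
  expect_equal(sum(e / 158), 1, tolerance = 1e-9)

  # without tail folding the truncation error is the tail mass
  e2 <- predicted_poisson_counts(8.41, 158, support_max = 30, fold_tail = FALSE)
  expect_equal(sum(e2), 158 * ppois(30, 8.41), tolerance = 1e-9)

  expect_error(predicted_poisson_counts(0, 10), "lam")
  expect_error(predicted_poisson_counts(-1, 10), "lam")
})

test_that("observed-vs-expected table lines up observed tallies with the model", {
  x <- c(0, 1, 1, 2, 4)
  tab <- poisson_expectation_table(x, lam = 1.6)
  expect_equal(tab$k[1:5], 0:4)
  expect_equal(tab$observed[1:5], c(1, 2, 1, 0, 1))
  expect_equal(tab$expected[2], length(x) * dpois(1, 1.6), tolerance = 1e-12)
})

test_that("KS D statistic equals the hand-computed value and a brute-force oracle", {
  # frozen example: counts 0,1,2 against Poisson(1), sup of CDF gaps
  k <- ks_poisson_test(c(0, 1, 2), lambda = 1, method = "asymptotic")
  expect_equal(unname(k$statistic),
               max(abs(c(1, 2, 3) / 3 - ppois(0:2, 1))), tolerance = 1e-12)
  expect_equal(unname(k$statistic), 0.0803, tolerance = 1e-4)

  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    x <- rpois(n, runif(1, 0.5, 20))
    lam <- mean(x)
    got <- ks_poisson_test(x, method = "asymptotic")
    expect_equal(unname(got$statistic), brute_force_ks_d(x, lam),
                 tolerance = 1e-12)
    lam_fix <- runif(1, 0.5, 20)
    got2 <- ks_poisson_test(x, lambda = lam_fix, method = "asymptotic")
    expect_equal(unname(got2$statistic), brute_force_ks_d(x, lam_fix),
                 tolerance = 1e-12)
  }
})

test_that("counts proportional to the model pmf give D near 0 and no rejection", {
  lam <- 2
  k <- 0:10
  counts <- rep(k, round(5000 * dpois(k, lam)))
  res <- ks_poisson_test(counts, lambda = lam, method = "asymptotic")
  expect_lt(unname(res$statistic), 0.01)
  expect_false(res$reject_at_alpha)
})

test_that("asymptotic p-value follows the Kolmogorov limiting distribution", {
  # Q(1.36) ~ 0.049: the classical 5% critical point
  x <- c(0, 1, 2, 3, 4)
  res <- ks_poisson_test(x, lambda = 2, method = "asymptotic")
  tt <- sqrt(5) * unname(res$statistic)
  j <- 1:100
  expect_equal(res$p.value, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * tt^2)),
               tolerance = 1e-10)
  expect_equal(meioscan:::kolmogorov_sf(1.358), 0.05, tolerance = 1e-3)
})

test_that("bootstrap p-values respect their bounds and the degenerate cases", {
  set.seed(5)
  x <- rpois(30, 4)
  res <- ks_poisson_test(x, n_boot = 199, seed = 1)
  expect_gte(res$p.value, 1 / 200)
  expect_lte(res$p.value, 1)
  # deterministic under a fixed seed and does not disturb the caller RNG
  before <- .Random.seed
  res2 <- ks_poisson_test(x, n_boot = 199, seed = 1)
  expect_identical(before, .Random.seed)
  expect_equal(res$p.value, res2$p.value)

  expect_error(ks_poisson_test(c(1, 2)), "5 cells")
  expect_warning(res0 <- ks_poisson_test(rep(0L, 10)), "degenerate")
  expect_equal(res0$p.value, 1)
})

test_that("cytology tables round-trip and morphology columns are validated", {
  df <- data.frame(cell_id = c("a", "b", "c"),
                   n_ring = c(18, 19, 17), n_rod = c(2, 1, 2),
                   n_lagging = c(0, 0, 1))
  path <- write_tmp_cytology(df)
  ds <- read_cytology(path)
  expect_s3_class(ds, "chiasma_dataset")
  expect_equal(ds$n_chiasmata, c(38L, 39L, 36L))
  expect_equal(ds$n_bivalents, c(20L, 20L, 19L))

  out <- tempfile(fileext = ".tsv")
  write_cytology(ds, out, header_lines = "simulated: no")
  ds2 <- read_cytology(out)
  expect_equal(ds2$n_chiasmata, ds$n_chiasmata)

  bad <- df; bad$n_chiasmata <- c(38, 39, 35)
  expect_error(chiasma_dataset(bad), "inconsistent")
  badbiv <- data.frame(n_chiasmata = c(10, 10), n_bivalents = c(21, 2))
  expect_error(chiasma_dataset(badbiv), "n_pairs")
  expect_error(chiasma_dataset(data.frame(n_chiasmata = c(3, 4),
                                          n_bivalents = c(4, 4))),
               ">= 1 chiasma")
})
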