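test_that("SNP index is the alt-read fraction with a depth floor", {
  expect_equal(snp_index(15, 15), 0.5)
  expect_equal(snp_index(0, 30), 1.0)
  expect_true(is.na(snp_index(2, 3)))          # depth 5 < 8
  expect_equal(snp_index(2, 3, min_depth = 5), 0.6)
  expect_true(is.na(snp_index(0, 0, min_depth = 0)))
  expect_error(snp_index(-1, 5), ">= 0")

  # bounded and symmetric
  set.seed(9)
  a <- rpois(50, 15); b <- rpois(50, 15)
  idx <- snp_index(a, b)
  expect_true(all(idx >= 0 & idx <= 1, na.rm = TRUE))
  expect_equal(snp_index(a, b), 1 - snp_index(b, a))
})

test_that("window layout: anchored at zero, full windows, 17 windows over 1 Mb", {
  pos <- seq(10000, 1000000, by = 10000)
  v <- data.frame(chrom = "chr1", pos = pos, snp_index = 0.5)
  w <- window_scan(v, min_variants = 1)
  expect_equal(nrow(w), 17)
  expect_equal(w$start, seq(0, 800000, by = 50000))
  expect_true(all(w$end - w$start == 200000))

  # an interior position is covered by exactly window/step = 4 windows
  covered <- sum(w$start <= 499999 & 499999 < w$end)
  expect_equal(covered, 4)

  # short chromosome still gets its single anchored window
  w1 <- window_scan(data.frame(chrom = "c", pos = 5000, snp_index = 1),
                    min_variants = 1)
  expect_equal(nrow(w1), 1)
  expect_equal(w1$start, 0)
})

test_that("window means average the usable indices and honour min_variants", {
  v <- data.frame(chrom = "chr1",
                  pos = c(1000, 2000, 3000),
                  snp_index = c(1.0, 0.8, 0.9))
  w <- window_scan(v, window_bp = 200000, step_bp = 50000, min_variants = 1)
  expect_equal(w$mean_index[w$start == 0], 0.9)
  expect_equal(w$n_variants[w$start == 0], 3L)

  w2 <- window_scan(v, min_variants = 10)
  expect_true(is.na(w2$mean_index[1]))

  # NA indices (low depth) are excluded from both count and mean
  v3 <- data.frame(chrom = "chr1", pos = c(1000, 2000, 3000),
                   ad_ref = c(0, 2, 5), ad_alt = c(30, 3, 5))
  w3 <- window_scan(v3, min_variants = 1)
  expect_equal(w3$n_variants[1], 2L)
  expect_equal(w3$mean_index[1], mean(c(1.0, 0.5)))
})

test_that("window scan validates ordering and step sizes", {
  v <- data.frame(chrom = "chr1", pos = c(5000, 1000), snp_index = 0.5)
  expect_error(window_scan(v), "sorted")
  v2 <- data.frame(chrom = "chr1", pos = c(1000, 5000), snp_index = 0.5)
  expect_error(window_scan(v2, step_bp = 0), "step_bp")
  expect_error(window_scan(v2, window_bp = 1000, step_bp = 5000), ">= step")
})

test_that("candidate regions merge overlapping above-threshold windows", {
  w <- data.frame(chrom = "chr1",
                  start = c(0, 50000, 400000),
                  end = c(200000, 250000, 600000),
                  n_variants = 20L,
                  mean_index = c(0.95, 0.92, 0.91))
  r <- call_candidate_regions(w)
  expect_equal(nrow(r), 2)
  expect_equal(r$start, c(0, 400000))
  expect_equal(r$end, c(250000, 600000))
  expect_equal(r$peak_index, c(0.95, 0.91))

  # threshold is strict; NA windows never call
  w$mean_index <- c(0.9, NA, 0.85)
  expect_equal(nrow(call_candidate_regions(w)), 0)

  # disjoint, sorted, idempotent under re-merging
  set.seed(14)
  wb <- data.frame(chrom = "chr2", start = seq(0, 950000, 50000))
  wb$end <- wb$start + 200000
  wb$n_variants <- 20L
  wb$mean_index <- runif(nrow(wb), 0.8, 1.0)
  r1 <- call_candidate_regions(wb)
  if (nrow(r1) > 1) {
    expect_true(all(diff(r1$start) > 0))
    expect_true(all(r1$start[-1] > r1$end[-nrow(r1)]))
  }
  r2 <- call_candidate_regions(
    data.frame(chrom = r1$chrom, start = r1$start, end = r1$end,
               n_variants = 1L, mean_index = r1$peak_index))
  expect_equal(r2$start, r1$start)
  expect_equal(r2$end, r1$end)
})

test_that("simulated bulk VCF round-trips through the reader without loss", {
  cfg <- bsa_sim_config(chrom_length_bp = 500000, marker_spacing_bp = 10000,
                        unlinked_length_bp = 100000)
  vars <- simulate_bsa_bulk(cfg, seed = 3)
  path <- tempfile(fileext = ".vcf")
  write_bsa_vcf(vars, path)
  back <- read_bulk_vcf(path)
  expect_equal(back$chrom, vars$chrom)
  expect_equal(back$pos, vars$pos)
  expect_equal(back$ad_ref, vars$ad_ref)
  expect_equal(back$ad_alt, vars$ad_alt)
  expect_true(file.exists(paste0(path, ".yml")))

  # serialize -> parse -> serialize identity on the fields used
  path2 <- tempfile(fileext = ".vcf")
  attr(back, "config") <- NULL
  write_bsa_vcf(back, path2, config_echo = FALSE)
  expect_identical(readLines(path)[-(1:5)], readLines(path2)[-(1:5)])

  expect_error(read_bulk_vcf(tempfile()), "no such file")
  expect_error(read_bulk_vcf(path, sample = "nope"), "sample not found")
})

test_that("BED output is 0-based half-open with a score column", {
  r <- data.frame(chrom = "chr4", start = 4800000, end = 5250000,
                  peak_index = 0.97)
  path <- tempfile(fileext = ".bed")
  write_bed(r, path)
  lines <- readLines(path)
  expect_length(lines, 1)
  f <- strsplit(lines, "\t")[[1]]
  expect_equal(f[1:3], c("chr4", "4800000", "5250000"))
  expect_equal(as.numeric(f[4]), 0.97)
})
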