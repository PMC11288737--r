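# Independent oracles used across test files.

# Brute-force discrete KS statistic: walk every integer of the support
# and compare the step CDFs directly.
brute_force_ks_d <- function(counts, lambda) {
  d <- 0
  for (k in 0:max(counts)) {
    fn <- mean(counts <= k)
    d <- max(d, abs(fn - stats::ppois(k, lambda)))
  }
  d
}

# A small cytology table on disk for reader tests.
write_tmp_cytology <- function(df, ext = ".csv") {
  path <- tempfile(fileext = ext)
  sep <- if (ext == ".csv") "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}
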