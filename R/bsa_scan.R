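# Bulked-segregant-analysis SNP-index scan: per-variant index from bulk
# allele depths, sliding-window averaging, candidate-region calling.
#
# Coordinate conventions: VCF positions are 1-based; windows, candidate
# regions and BED output are 0-based half-open.

#' Per-variant SNP index from bulk allele depths
#'
#' `ad_alt / (ad_ref + ad_alt)`, the fraction of reads carrying the
#' mutant (alt) allele in the bulk; `NA` when total depth is below
#' `min_depth` (low-depth sites are uninformative and excluded rather
#' than erroring). In a bulk of recessive homozygotes the index
#' approaches 1 at the causal locus and 0.5 at unlinked sites.
#'
#' @param ad_ref reference-allele read depth (vectorised).
#' @param ad_alt alternate-allele read depth.
#' @param min_depth minimum total depth for a usable index (default 8).
#' @return numeric vector in \[0, 1\] with `NA` at low-depth sites.
#' @examples
#' snp_index(15, 15)  # 0.5
#' snp_index(2, 3)    # NA under the default depth threshold
#' @export
snp_index <- function(ad_ref, ad_alt, min_depth = 8L) {
  if (any(ad_ref < 0, na.rm = TRUE) || any(ad_alt < 0, na.rm = TRUE))
    stop("allele depths must be >= 0")
  depth <- ad_ref + ad_alt
  ifelse(!is.na(depth) & depth >= min_depth & depth > 0,
         ad_alt / depth, NA_real_)
}

#' Read bulk allele depths from a VCF
#'
#' Extracts CHROM/POS/REF/ALT and the per-sample AD (allele depth) field
#' for one sample, yielding the variant table consumed by
#' [window_scan()]. Multi-allelic records use the first ALT allele's
#' depth.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param sample sample name or 1-based index (default: first sample).
#' @return data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `ad_ref`, `ad_alt`.
#' @export
read_bulk_vcf <- function(path, sample = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || ncol(ad) == 0L) stop("VCF has no per-sample AD field")
  col <- if (is.character(sample)) {
    if (!sample %in% colnames(ad)) stop("sample not found in VCF: ", sample)
    sample
  } else colnames(ad)[sample]
  parts <- strsplit(ad[, col], ",", fixed = TRUE)
  ad_ref <- vapply(parts, function(p) suppressWarnings(as.integer(p[1])), 1L)
  ad_alt <- vapply(parts, function(p) suppressWarnings(as.integer(p[2])), 1L)
  fix <- vcfR::getFIX(v)
  data.frame(chrom = fix[, "CHROM"],
             pos = as.integer(fix[, "POS"]),
             ref = fix[, "REF"],
             alt = fix[, "ALT"],
             ad_ref = ad_ref, ad_alt = ad_alt,
             stringsAsFactors = FALSE)
}

#' Sliding-window SNP-index scan
#'
#' Averages per-variant SNP indices in sliding windows anchored at
#' position 0 on each chromosome (defaults: 200-kb windows advancing by
#' 50 kb). Only full-size windows are emitted, the last one being the
#' furthest full window still containing the last variant; windows with
#' fewer than `min_variants` usable (non-missing-index) variants get a
#' missing mean. Chromosomes with no variants yield no windows.
#'
#' @param variants data frame as from [read_bulk_vcf()] (or from
#'   [simulate_bsa_bulk()]), sorted by chromosome then position. An
#'   existing `snp_index` column is used as-is; otherwise indices are
#'   computed from `ad_ref`/`ad_alt` with `min_depth`.
#' @param window_bp window size in bp (default 200000).
#' @param step_bp step size in bp (default 50000), must satisfy
#'   `window_bp >= step_bp > 0`.
#' @param min_variants minimum usable variants per window (default 10).
#' @param min_depth depth threshold passed to [snp_index()].
#' @return data frame of class `bsa_windows`: `chrom`, `start`, `end`
#'   (0-based half-open), `n_variants`, `mean_index`.
#' @export
window_scan <- function(variants, window_bp = 200000L, step_bp = 50000L,
                        min_variants = 10L, min_depth = 8L) {
  stopifnot(is.data.frame(variants))
  if (step_bp <= 0) stop("step_bp must be > 0")
  if (window_bp < step_bp) stop("window_bp must be >= step_bp")
  if (!"snp_index" %in% names(variants))
    variants$snp_index <- snp_index(variants$ad_ref, variants$ad_alt, min_depth)

  pieces <- lapply(split(variants, variants$chrom), function(vc) {
    if (nrow(vc) == 0L) return(NULL)
    if (is.unsorted(vc$pos, strictly = FALSE))
      stop("variants must be sorted by position within each chromosome")
    pos0 <- vc$pos - 1L                     # 0-based
    last <- pos0[length(pos0)]
    k_last <- max(0L, as.integer(floor((last + 1 - window_bp) / step_bp)))
    starts <- as.numeric(0:k_last) * step_bp
    ends <- starts + window_bp
    ok <- !is.na(vc$snp_index)
    cnt_ok <- cumsum(ok)
    sum_ok <- cumsum(ifelse(ok, vc$snp_index, 0))
    # variants with start <= pos0 < end, counted via cumulative sums
    hi <- findInterval(ends - 0.5, pos0)    # pos0 <= end - 1
    lo <- findInterval(starts - 0.5, pos0)  # pos0 <= start - 1
    at <- function(cs, i) ifelse(i >= 1L, cs[pmax(i, 1L)], 0)
    nv <- at(cnt_ok, hi) - at(cnt_ok, lo)
    sv <- at(sum_ok, hi) - at(sum_ok, lo)
    data.frame(chrom = vc$chrom[1], start = starts, end = ends,
               n_variants = as.integer(nv),
               mean_index = ifelse(nv >= min_variants, sv / nv, NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  structure(out, class = c("bsa_windows", "data.frame"),
            window_bp = window_bp, step_bp = step_bp)
}

#' Call candidate regions from window SNP indices
#'
#' Windows whose mean SNP index strictly exceeds `threshold` (default
#' 0.9, the calling rule for a selected recessive bulk) are merged when
#' overlapping or book-ended; each merged region reports the maximum
#' member-window mean as `peak_index`.
#'
#' @param windows output of [window_scan()].
#' @param threshold SNP-index calling threshold (strict, default 0.9).
#' @return data frame of class `bsa_regions`: `chrom`, `start`, `end`
#'   (0-based half-open), `peak_index`; disjoint and sorted.
#' @export
call_candidate_regions <- function(windows, threshold = 0.9) {
  stopifnot(is.data.frame(windows),
            all(c("chrom", "start", "end", "mean_index") %in% names(windows)))
  hit <- !is.na(windows$mean_index) & windows$mean_index > threshold
  hits <- windows[hit, , drop = FALSE]
  out <- data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0), peak_index = numeric(0))
  for (ch in unique(hits$chrom)) {
    hc <- hits[hits$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = hc$start + 1L, end = hc$end)  # 1-based closed
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    peak <- tapply(hc$mean_index[S4Vectors::from(ov)],
                   S4Vectors::to(ov), max)
    out <- rbind(out, data.frame(
      chrom = ch,
      start = IRanges::start(red) - 1L,
      end = IRanges::end(red),
      peak_index = as.numeric(peak)))
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("bsa_regions", "data.frame"),
            threshold = threshold)
}

#' Write a window table as delimited text
#'
#' @param windows output of [window_scan()].
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_window_table <- function(windows, path) {
  utils::write.table(as.data.frame(windows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write candidate regions as BED3+score
#'
#' Emits `chrom`, `start`, `end`, `peak_index` with 0-based half-open
#' coordinates and no header, loadable in any genome browser.
#'
#' @param regions output of [call_candidate_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  df <- as.data.frame(regions)[, c("chrom", "start", "end", "peak_index")]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
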