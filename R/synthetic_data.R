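# Synthetic-data generators: F2 phenotype counts, a BSA bulk VCF with a
# planted recessive locus, and meiosis-simulator presets. Everything is
# bit-reproducible under a fixed seed, so the whole pipeline is testable
# without any sequencing deposit.

#' Simulate F2 phenotype segregation counts
#'
#' Draws the sterile (recessive homozygote) count as
#' Binomial(n_plants, p_mutant); the remainder is fertile. The default
#' `p_mutant = 1/4` is the F2 expectation for a single recessive
#' mutation.
#'
#' @param n_plants F2 population size (default 181, a typical mapping
#'   population).
#' @param p_mutant probability a plant is a recessive homozygote.
#' @param seed optional integer seed.
#' @return list with `fertile`, `sterile`, `n_plants` and
#'   `expected_ratio` (`c(3, 1)` scaled from `p_mutant`).
#' @export
simulate_f2_counts <- function(n_plants = 181L, p_mutant = 0.25, seed = NULL) {
  if (n_plants < 1) stop("n_plants must be >= 1")
  if (p_mutant < 0 || p_mutant > 1) stop("p_mutant must lie in [0, 1]")
  sterile <- with_seed_if(seed, stats::rbinom(1L, n_plants, p_mutant))
  list(fertile = n_plants - sterile, sterile = sterile,
       n_plants = as.integer(n_plants),
       expected_ratio = c(fertile = 1 - p_mutant, sterile = p_mutant) /
         min(p_mutant, 1 - p_mutant))
}

#' Configuration for the synthetic BSA bulk
#'
#' Defaults emulate the study design of a sterile F2 bulk: 39 recessive
#' homozygotes sequenced to ~30x. The genetic model places the causal
#' locus on one chromosome and links each marker to it through Haldane's
#' map function `r = (1 - exp(-2*d_Morgan)) / 2` with physical-to-genetic
#' scaling `kb_per_cM` (default 400 kb/cM, a genome-wide soybean-scale
#' figure; the true local rate is configuration, not inference). An
#' optional second, unlinked chromosome (r = 1/2 everywhere) provides a
#' genome-background control.
#'
#' @param n_plants bulk size (default 39).
#' @param mean_depth mean sequencing depth per marker (default 30).
#' @param chrom_length_bp carrier chromosome length (default 10 Mb).
#' @param marker_spacing_bp marker spacing (default 400 bp, matching the
#'   2-3 variants/kb typical of divergent-parent resequencing bulks).
#' @param locus_pos 1-based causal-locus position (default mid-chromosome).
#' @param kb_per_cM physical-to-genetic scaling (default 400).
#' @param unlinked_length_bp length of the unlinked control chromosome;
#'   0 suppresses it (default 2 Mb).
#' @param seed optional integer seed.
#' @return validated list of class `bsa_sim_config`.
#' @export
bsa_sim_config <- function(n_plants = 39L, mean_depth = 30,
                           chrom_length_bp = 10e6, marker_spacing_bp = 400L,
                           locus_pos = NULL, kb_per_cM = 400,
                           unlinked_length_bp = 2e6, seed = NULL) {
  locus_pos <- locus_pos %||% (chrom_length_bp / 2)
  stopifnot(n_plants >= 1, mean_depth > 0, marker_spacing_bp > 0,
            chrom_length_bp >= marker_spacing_bp, kb_per_cM > 0,
            unlinked_length_bp >= 0)
  if (locus_pos < 1 || locus_pos > chrom_length_bp)
    stop("locus_pos must lie within the chromosome")
  structure(list(n_plants = as.integer(n_plants), mean_depth = mean_depth,
                 chrom_length_bp = chrom_length_bp,
                 marker_spacing_bp = marker_spacing_bp,
                 locus_pos = locus_pos, kb_per_cM = kb_per_cM,
                 unlinked_length_bp = unlinked_length_bp, seed = seed),
            class = "bsa_sim_config")
}

# Haldane map function: bp distance -> recombination fraction.
haldane_r <- function(distance_bp, kb_per_cM) {
  d_morgan <- (distance_bp / (kb_per_cM * 1000)) / 100
  (1 - exp(-2 * d_morgan)) / 2
}

#' Expected bulk SNP index at a given distance from the causal locus
#'
#' In a bulk of recessive homozygotes every selected gamete carries the
#' mutant allele at the locus; a marker at recombination fraction `r`
#' carries it with probability `1 - r`. This analytic expectation (1 at
#' the locus, decaying monotonically to 0.5 when unlinked) is the
#' quantity the simulated index fluctuates around.
#'
#' @param distance_bp physical distance from the causal locus (vectorised).
#' @param kb_per_cM physical-to-genetic scaling.
#' @return expected SNP index in \[0.5, 1\].
#' @export
expected_snp_index <- function(distance_bp, kb_per_cM = 400) {
  1 - haldane_r(abs(distance_bp), kb_per_cM)
}

# Mutant-allele carrier states of n_gam gamete haplotypes at sorted
# marker positions, as a Markov walk along the chromosome: between
# consecutive markers the state flips with the Haldane recombination
# fraction of the interval. Haldane fractions compose (no interference),
# so the marginal law at any marker at distance d from the anchor is
# exactly Bernoulli(1 - r(d)) while nearby markers stay linked, as on a
# real haplotype. `anchor_pos = NULL` simulates an unlinked chromosome:
# each haplotype starts from a fair coin at one end.
sim_haplotype_freq <- function(pos, anchor_pos, kb_per_cM, n_gam) {
  walk <- function(dist_steps, init_carry) {
    # dist_steps: bp lengths of successive intervals (first: from anchor)
    r_step <- haldane_r(dist_steps, kb_per_cM)
    flips <- matrix(stats::runif(n_gam * length(r_step)) <
                      rep(r_step, each = n_gam), nrow = n_gam)
    cum <- flips
    if (ncol(cum) > 1L) cum <- t(apply(flips, 1L, cumsum))
    carry <- (cum + !init_carry) %% 2 == 0
    colMeans(carry)
  }
  freq <- numeric(length(pos))
  if (is.null(anchor_pos)) {
    init <- stats::runif(n_gam) < 0.5
    freq[] <- walk(diff(c(pos[1], pos)) + c(1e-9, numeric(length(pos) - 1L)),
                   init)
    # (first interval has length ~0: the coin itself anchors the walk)
  } else {
    left <- which(pos < anchor_pos)
    right <- which(pos >= anchor_pos)
    if (length(right))
      freq[right] <- walk(diff(c(anchor_pos, pos[right])), TRUE)
    if (length(left)) {
      lp <- rev(pos[left])  # outward from the locus
      freq[rev(left)] <- walk(-diff(c(anchor_pos, lp)), TRUE)
    }
  }
  freq
}

#' Simulate a sterile-bulk marker table with a planted locus
#'
#' Plant-by-plant simulation of the selected bulk: each of the
#' `n_plants` sterile plants is homozygous mutant at the causal locus,
#' so all `2 * n_plants` of its gametes carry the mutant allele there.
#' Each gamete's haplotype is extended outward from the locus as a
#' Markov recombination walk (Haldane, no interference), so a marker at
#' distance `d` carries the mutant allele with probability `1 - r(d)`
#' and neighbouring markers are linked as on a real chromosome. The bulk
#' allele frequency at a marker is the mean over the gametes — so
#' finite-bulk noise is realistic — and read support is Poisson depth
#' with Binomial allele sampling.
#'
#' @param config a [bsa_sim_config()].
#' @param seed optional integer seed (overrides `config$seed`).
#' @return data frame of variant records (`chrom`, `pos`, `ref`, `alt`,
#'   `ad_ref`, `ad_alt`) sorted by chromosome and position, with the
#'   config attached as attribute `config`. Serialise with
#'   [write_bsa_vcf()].
#' @export
simulate_bsa_bulk <- function(config = bsa_sim_config(), seed = NULL) {
  stopifnot(inherits(config, "bsa_sim_config"))
  seed <- seed %||% config$seed
  with_seed_if(seed, {
    sp <- config$marker_spacing_bp
    n_gametes <- 2L * config$n_plants
    pos <- seq.int(sp, config$chrom_length_bp, by = sp)
    freq <- sim_haplotype_freq(pos, config$locus_pos, config$kb_per_cM,
                               n_gametes)
    chrom <- rep("chr04", length(pos))
    if (config$unlinked_length_bp >= sp) {
      posu <- seq.int(sp, config$unlinked_length_bp, by = sp)
      freq <- c(freq, sim_haplotype_freq(posu, NULL, config$kb_per_cM,
                                         n_gametes))
      pos <- c(pos, posu)
      chrom <- c(chrom, rep("chrUn", length(posu)))
    }
    depth <- stats::rpois(length(pos), config$mean_depth)
    ad_alt <- stats::rbinom(length(pos), depth, freq)
    out <- data.frame(chrom = chrom, pos = as.integer(pos),
                      ref = "A", alt = "T",
                      ad_ref = as.integer(depth - ad_alt),
                      ad_alt = as.integer(ad_alt),
                      stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$pos), ]
    rownames(out) <- NULL
    attr(out, "config") <- config
    out
  })
}

#' Write a simulated bulk as a minimal VCF
#'
#' Emits a valid VCFv4.2 file with one sample and a `GT:AD` FORMAT so
#' the table round-trips through [read_bulk_vcf()]. A YAML companion
#' file (`<path>.yml`) echoes the generating configuration and seed when
#' available.
#'
#' @param variants data frame from [simulate_bsa_bulk()] (any data frame
#'   with `chrom`, `pos`, `ref`, `alt`, `ad_ref`, `ad_alt` works).
#' @param path output `.vcf` path.
#' @param sample_name bulk sample name in the VCF header.
#' @param config_echo write the YAML companion (default TRUE when a
#'   config attribute is present).
#' @return `path`, invisibly.
#' @export
write_bsa_vcf <- function(variants, path, sample_name = "sterile_bulk",
                          config_echo = TRUE) {
  cfg <- attr(variants, "config")
  contigs <- vapply(split(variants$pos, variants$chrom), max, 1)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=meioscan.simulate_bsa_bulk",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs),
            as.integer(contigs + 1000)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele read depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_name))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD\t./.:%d,%d",
                  variants$chrom, variants$pos, variants$ref, variants$alt,
                  variants$ad_ref, variants$ad_alt)
  writeLines(c(hdr, body), path)
  if (config_echo && !is.null(cfg))
    writeLines(yaml::as.yaml(unclass(cfg)), paste0(path, ".yml"))
  invisible(path)
}

#' Meiosis-simulator presets for the two study regimes
#'
#' * `wildtype`: Class I pathway on with an obligate crossover per pair,
#'   calibrated so per-cell chiasma counts have mean 38.50 and SD 1.41
#'   (dispersion index ~0.052, strongly under-dispersed) over a 20-pair
#'   karyotype; every cell forms 20 bivalents.
#' * `mlh1_mutant`: Class I off; Class II Poisson rate 0.4205 per pair,
#'   i.e. mean 8.41 chiasmata per cell with Poisson (dispersion 1)
#'   cell-to-cell variation.
#'
#' @param name `"wildtype"` or `"mlh1_mutant"`.
#' @return a [meiosis_params()] object.
#' @examples
#' p <- meiosis_preset("mlh1_mutant")
#' d <- simulate_dataset(p, 158, seed = 1)
#' chiasma_summary(d)$mean  # ~8.41
#' @export
meiosis_preset <- function(name = c("wildtype", "mlh1_mutant")) {
  name <- match.arg(name)
  switch(name,
    wildtype = meiosis_params(
      n_pairs = 20L, class1_enabled = TRUE, obligate_co = TRUE,
      class1_mean_extra = 38.50 / 20 - 1,
      class1_dispersion = 1.41^2 / 38.50,
      class2_rate = 0),
    mlh1_mutant = meiosis_params(
      n_pairs = 20L, class1_enabled = FALSE,
      class2_rate = calibrate_class2_rate("mean_chiasmata", 8.41)))
}
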