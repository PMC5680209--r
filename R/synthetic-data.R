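#' Simulation configuration for panel pileups
#'
#' Bundles the parameters of the pileup generator: site count, the
#' negative-binomial depth model, the per-base sequencing error rate,
#' tumor purity and subclone structure, per-site copy states, and the
#' fraction of nominal depth surviving duplicate removal (FFPE libraries
#' lose a substantial share of reads to deduplication).
#'
#' @param n_sites number of panel positions to simulate.
#' @param depth_mean mean nominal (pre-deduplication) depth.
#' @param depth_dispersion negative-binomial size parameter; smaller
#'   values give more uneven coverage across the panel.
#' @param base_error_rate per-base sequencing error rate \eqn{\epsilon};
#'   an erroneous base is one of the three non-reference bases with
#'   equal probability, so a specific alternative base accumulates
#'   errors at rate \eqn{\epsilon/3}.
#' @param purity fraction of cells in the specimen that are tumor cells.
#' @param clone_fractions cancer-cell fraction of the clone carrying
#'   each variant; recycled across sites.
#' @param copy_states data.frame with columns `total` and `variant`:
#'   copies of the locus and of the variant allele in tumor cells;
#'   recycled across sites. `variant = 0` marks a non-variant site.
#' @param dedup_fraction fraction of nominal depth surviving duplicate
#'   removal (around 0.8 for FFPE panels targeted at ~1000x).
#' @param read_length read length in bp used for variant read offsets.
#' @param seed optional integer seed recorded in the config.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_sites = 200L,
                              depth_mean = 1000,
                              depth_dispersion = 10,
                              base_error_rate = 0.001,
                              purity = 1,
                              clone_fractions = 1,
                              copy_states = data.frame(total = 2L, variant = 1L),
                              dedup_fraction = 0.8,
                              read_length = 100L,
                              seed = NULL) {
  stopifnot(is.data.frame(copy_states),
            all(c("total", "variant") %in% names(copy_states)))
  cfg <- list(n_sites = as.integer(n_sites), depth_mean = depth_mean,
              depth_dispersion = depth_dispersion,
              base_error_rate = base_error_rate, purity = purity,
              clone_fractions = clone_fractions, copy_states = copy_states,
              dedup_fraction = dedup_fraction,
              read_length = as.integer(read_length), seed = seed)
  num_ok <- function(x) length(x) >= 1L && all(is.finite(x))
  if (!num_ok(cfg$depth_mean) || cfg$depth_mean <= 0)
    stop("depth_mean must be a positive finite number")
  if (!num_ok(cfg$purity) || cfg$purity < 0 || cfg$purity > 1)
    stop("purity must lie in [0, 1]")
  if (!num_ok(cfg$base_error_rate) ||
      cfg$base_error_rate <= 0 || cfg$base_error_rate >= 0.1)
    stop("base_error_rate must lie in (0, 0.1)")
  if (!num_ok(cfg$dedup_fraction) ||
      cfg$dedup_fraction <= 0 || cfg$dedup_fraction > 1)
    stop("dedup_fraction must lie in (0, 1]")
  if (!num_ok(cfg$clone_fractions) ||
      any(cfg$clone_fractions <= 0) || any(cfg$clone_fractions > 1))
    stop("clone_fractions must lie in (0, 1]")
  if (!num_ok(cfg$depth_dispersion) || cfg$depth_dispersion <= 0)
    stop("depth_dispersion must be positive")
  if (any(copy_states$total < 1L) || any(copy_states$variant < 0L) ||
      any(copy_states$variant > copy_states$total))
    stop("copy_states must satisfy 0 <= variant <= total, total >= 1")
  class(cfg) <- "simulation_config"
  cfg
}

#' @method print simulation_config
#' @export
print.simulation_config <- function(x, ...) {
  cat("Panel pileup simulation config\n")
  cat(sprintf("  sites: %d  depth: NB(mu = %g, size = %g) x dedup %g\n",
              x$n_sites, x$depth_mean, x$depth_dispersion, x$dedup_fraction))
  cat(sprintf("  error rate: %g  purity: %g\n", x$base_error_rate, x$purity))
  invisible(x)
}

.BASES <- c("A", "C", "G", "T")

## Expected somatic VAF given purity P, clone fraction c and tumor copy
## state (X total, Y variant): variant alleles come only from tumor cells
## of the mutated clone; normal cells and non-mutated tumor cells
## contribute reference alleles.
.expected_somatic_vaf <- function(purity, clone_fraction, total, variant) {
  num <- purity * clone_fraction * variant
  den <- purity * clone_fraction * total +
    purity * (1 - clone_fraction) * 2 + 2 * (1 - purity)
  ifelse(den > 0, num / den, 0)
}

.new_pileup <- function(chrom, pos, ref_base, alt_base, depth, alt_count,
                        alt_fwd, ref_fwd, alt_read_offsets, true_vaf = NA_real_) {
  data.frame(chrom = chrom, pos = as.integer(pos),
             ref_base = ref_base, alt_base = alt_base,
             depth = as.integer(depth), alt_count = as.integer(alt_count),
             alt_fwd = as.integer(alt_fwd),
             alt_rev = as.integer(alt_count - alt_fwd),
             ref_fwd = as.integer(ref_fwd),
             ref_rev = as.integer(depth - alt_count - ref_fwd),
             alt_read_offsets = I(alt_read_offsets),
             true_vaf = true_vaf,
             stringsAsFactors = FALSE)
}

#' Simulate deduplicated tumor panel pileups
#'
#' Draws per-site depths from a negative-binomial model, thins them by
#' the deduplication fraction, and samples variant-supporting read
#' counts binomially at the expected VAF implied by purity, clone
#' fraction and copy state. Sequencing errors convert reference reads to
#' the designated alternative base at rate \eqn{\epsilon/3}. Strand
#' assignment is unbiased and variant read offsets are uniform over the
#' read.
#'
#' @param config a [simulation_config()].
#' @return a data.frame of pileup sites with one row per position:
#'   `chrom`, `pos`, `ref_base`, `alt_base`, `depth`, `alt_count`,
#'   stranded counts `alt_fwd`/`alt_rev`/`ref_fwd`/`ref_rev`, a
#'   list-column `alt_read_offsets` of 0-based variant base offsets,
#'   and the simulation truth `true_vaf` (expected VAF before error).
#' @export
simulate_tumor_pileups <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_sites
  idx <- function(v) rep_len(seq_along(v), n)
  cf <- rep_len(config$clone_fractions, n)
  cs <- config$copy_states[rep_len(seq_len(nrow(config$copy_states)), n), ,
                           drop = FALSE]
  true_vaf <- .expected_somatic_vaf(config$purity, cf, cs$total, cs$variant)
  nominal <- stats::rnbinom(n, size = config$depth_dispersion,
                            mu = config$depth_mean)
  depth <- stats::rbinom(n, nominal, config$dedup_fraction)
  eps3 <- config$base_error_rate / 3
  p_alt <- true_vaf + (1 - true_vaf) * eps3
  alt <- stats::rbinom(n, depth, p_alt)
  alt_fwd <- stats::rbinom(n, alt, 0.5)
  ref_fwd <- stats::rbinom(n, depth - alt, 0.5)
  ref <- sample(.BASES, n, replace = TRUE)
  alt_base <- vapply(ref, function(b) sample(setdiff(.BASES, b), 1L), "")
  offs <- lapply(alt, function(k)
    if (k > 0) sample.int(config$read_length, k, replace = TRUE) - 1L
    else integer(0))
  .new_pileup(chrom = "chr1", pos = 1000000L + (seq_len(n) - 1L) * 500L,
              ref_base = ref, alt_base = alt_base, depth = depth,
              alt_count = alt, alt_fwd = alt_fwd, ref_fwd = ref_fwd,
              alt_read_offsets = offs, true_vaf = true_vaf)
}

#' Check pileup count identities
#'
#' @param sites a pileup data.frame.
#' @return `TRUE` invisibly; stops if any identity is violated.
#' @keywords internal
#' @export
validate_pileups <- function(sites) {
  with(sites, {
    stopifnot(all(alt_count >= 0), all(depth >= 0),
              all(alt_count <= depth),
              all(alt_fwd + alt_rev == alt_count),
              all(ref_fwd + ref_rev == depth - alt_count),
              all(alt_fwd >= 0), all(alt_rev >= 0),
              all(ref_fwd >= 0), all(ref_rev >= 0))
  })
  invisible(TRUE)
}

#' Dilute pileups in silico to a target VAF
#'
#' Emulates the in silico dilution assay: each variant-supporting read
#' is independently converted to a reference read with probability
#' `1 - target_vaf / observed_vaf`, where the *observed* (realized) VAF
#' of the site is the denominator. Depth is unchanged; converted reads
#' keep their strand, so strand counts move from the alt to the ref
#' category consistently.
#'
#' @param sites pileup data.frame; every site must have observed VAF at
#'   least `target_vaf`.
#' @param target_vaf the VAF to dilute to.
#' @param seed optional integer seed.
#' @return the diluted pileup data.frame with an extra `realized_vaf`
#'   column.
#' @export
dilute_in_silico <- function(sites, target_vaf, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(target_vaf > 0, target_vaf <= 1)
  obs <- sites$alt_count / pmax(sites$depth, 1L)
  if (any(obs < target_vaf))
    stop("target_vaf exceeds the observed VAF at ",
         sum(obs < target_vaf), " site(s)")
  keep_p <- target_vaf / obs
  kept_fwd <- stats::rbinom(nrow(sites), sites$alt_fwd, keep_p)
  kept_rev <- stats::rbinom(nrow(sites), sites$alt_rev, keep_p)
  kept <- kept_fwd + kept_rev
  out <- sites
  out$alt_fwd <- kept_fwd
  out$alt_rev <- kept_rev
  out$ref_fwd <- sites$ref_fwd + (sites$alt_fwd - kept_fwd)
  out$ref_rev <- sites$ref_rev + (sites$alt_rev - kept_rev)
  out$alt_count <- kept
  if (!is.null(sites$alt_read_offsets)) {
    out$alt_read_offsets <- I(mapply(function(o, k) {
      if (k == 0L || length(o) == 0L) integer(0)
      else sort(sample(o, min(k, length(o))))
    }, sites$alt_read_offsets, kept, SIMPLIFY = FALSE))
  }
  out$realized_vaf <- out$alt_count / pmax(out$depth, 1L)
  out
}

#' Downsample one pileup site to a fixed depth
#'
#' Draws `target_depth` reads without replacement from the site's reads
#' (hypergeometric on the alt/ref split, then on strands within each
#' class), so `E[alt'] = alt_count * target_depth / depth`.
#'
#' @param site a single-row pileup data.frame.
#' @param target_depth number of reads to keep; at most `site$depth`.
#' @param seed optional integer seed.
#' @return the downsampled single-row pileup data.frame.
#' @export
downsample_site <- function(site, target_depth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(site) == 1L)
  target_depth <- as.integer(target_depth)
  if (target_depth > site$depth)
    stop("target_depth exceeds site depth (", site$depth, ")")
  if (target_depth == site$depth) return(site)
  alt2 <- stats::rhyper(1L, site$alt_count, site$depth - site$alt_count,
                        target_depth)
  alt_fwd2 <- if (alt2 > 0)
    stats::rhyper(1L, site$alt_fwd, site$alt_rev, alt2) else 0L
  ref2 <- target_depth - alt2
  ref_fwd2 <- if (ref2 > 0)
    stats::rhyper(1L, site$ref_fwd, site$ref_rev, ref2) else 0L
  out <- site
  out$depth <- target_depth
  out$alt_count <- as.integer(alt2)
  out$alt_fwd <- as.integer(alt_fwd2)
  out$alt_rev <- as.integer(alt2 - alt_fwd2)
  out$ref_fwd <- as.integer(ref_fwd2)
  out$ref_rev <- as.integer(ref2 - ref_fwd2)
  if (!is.null(site$alt_read_offsets)) {
    o <- site$alt_read_offsets[[1L]]
    out$alt_read_offsets <- I(list(
      if (alt2 > 0 && length(o) > 0) sort(sample(o, min(alt2, length(o))))
      else integer(0)))
  }
  out
}

#' Pool-level downsampling by binomial thinning
#'
#' Emulates down-sampling a sequencing pool at a fraction: every read at
#' every site is kept independently with probability `fraction`, so
#' realized depths vary binomially around `fraction * depth`.
#'
#' @param sites pileup data.frame.
#' @param fraction keep probability in (0, 1].
#' @param seed optional integer seed.
#' @return the thinned pileup data.frame.
#' @export
pool_downsample <- function(sites, fraction, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(fraction > 0, fraction <= 1)
  n <- nrow(sites)
  out <- sites
  out$alt_fwd <- stats::rbinom(n, sites$alt_fwd, fraction)
  out$alt_rev <- stats::rbinom(n, sites$alt_rev, fraction)
  out$ref_fwd <- stats::rbinom(n, sites$ref_fwd, fraction)
  out$ref_rev <- stats::rbinom(n, sites$ref_rev, fraction)
  out$alt_count <- out$alt_fwd + out$alt_rev
  out$depth <- out$alt_count + out$ref_fwd + out$ref_rev
  if (!is.null(sites$alt_read_offsets)) {
    out$alt_read_offsets <- I(mapply(function(o, k) {
      if (k == 0L || length(o) == 0L) integer(0)
      else sort(sample(o, min(k, length(o))))
    }, sites$alt_read_offsets, out$alt_count, SIMPLIFY = FALSE))
  }
  out
}

#' Simulate a panel-of-normals cohort
#'
#' Draws per-sample allele dosages at the supplied germline sites under
#' Hardy-Weinberg sampling (dosage ~ Binomial(2, population AF)) and
#' records the realized cohort allele frequency at each site.
#'
#' @param n_samples cohort size (the filtering panel targets > 400).
#' @param germline_sites data.frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `pop_af`.
#' @param seed optional integer seed.
#' @return an object of class `normal_cohort`: list with `n_samples`,
#'   `sites` (the input plus realized `cohort_af`), and the
#'   sample-by-site `genotypes` dosage matrix.
#' @export
simulate_normal_cohort <- function(n_samples = 400L, germline_sites,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_samples <- as.integer(n_samples)
  stopifnot(n_samples >= 2L)
  if (is.null(germline_sites) || nrow(germline_sites) == 0L)
    stop("germline_sites must contain at least one site")
  stopifnot(all(c("chrom", "pos", "pop_af") %in% names(germline_sites)),
            all(germline_sites$pop_af >= 0),
            all(germline_sites$pop_af <= 1))
  m <- nrow(germline_sites)
  geno <- matrix(stats::rbinom(n_samples * m, 2L,
                               rep(germline_sites$pop_af, each = n_samples)),
                 nrow = n_samples, ncol = m)
  sites <- germline_sites
  sites$cohort_af <- colSums(geno) / (2 * n_samples)
  structure(list(n_samples = n_samples, sites = sites, genotypes = geno),
            class = "normal_cohort")
}

#' @method print normal_cohort
#' @export
print.normal_cohort <- function(x, ...) {
  cat(sprintf("Panel-of-normals cohort: %d samples, %d sites\n",
              x$n_samples, nrow(x$sites)))
  invisible(x)
}

#' Expected VAFs of a multi-line equal-mixture dilution pool
#'
#' For a pool of cell lines mixed at given proportions, the expected VAF
#' of each SNP is the proportion-weighted mean of dosage/2 across lines.
#' A SNP heterozygous in exactly one line of a 10-line equal mix has an
#' expected VAF of 5%.
#'
#' @param genotype_matrix lines-by-SNP matrix of allele dosages in
#'   \{0, 1, 2\}.
#' @param proportions mixing proportions, one per line, summing to 1.
#' @return numeric vector of expected VAFs, one per SNP.
#' @export
simulate_mixture_vafs <- function(genotype_matrix, proportions) {
  genotype_matrix <- as.matrix(genotype_matrix)
  if (!all(genotype_matrix %in% c(0, 1, 2)))
    stop("genotype dosages must be 0, 1, or 2")
  stopifnot(length(proportions) == nrow(genotype_matrix))
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must sum to 1 (tolerance 1e-9)")
  as.vector(proportions %*% (genotype_matrix / 2))
}

#' Simulate an exon-level depth matrix with copy number truth
#'
#' Inverse model of the read-depth CNV caller: a gene at tumor copy
#' number C in a sample of purity P has expected depth ratio
#' `R = (P*C + 2*(1-P)) / 2` against a diploid baseline, with
#' multiplicative log-normal noise of the configured coefficient of
#' variation. Normal reference samples are generated at C = 2.
#'
#' @param cnv_truth data.frame with columns `gene` and `copies`.
#' @param purity tumor purity of the simulated sample.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_exons exons per gene.
#' @param n_normals number of normal reference samples.
#' @param depth_per_exon baseline diploid depth per exon.
#' @param seed optional integer seed.
#' @return list with `exons` (gene/exon data.frame), `tumor` (named
#'   depth vector) and `normals` (exon-by-sample depth matrix).
#' @export
simulate_exon_depth_matrix <- function(cnv_truth, purity = 1,
                                       noise_cv = 0.05, n_exons = 8L,
                                       n_normals = 8L,
                                       depth_per_exon = 500,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(cnv_truth$copies >= 0), purity >= 0, purity <= 1)
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  exons <- data.frame(
    gene = rep(cnv_truth$gene, each = n_exons),
    exon = paste0(rep(cnv_truth$gene, each = n_exons), "_e",
                  rep(seq_len(n_exons), times = nrow(cnv_truth))),
    copies = rep(cnv_truth$copies, each = n_exons),
    stringsAsFactors = FALSE)
  m <- nrow(exons)
  sdlog <- sqrt(log(1 + noise_cv^2))
  noise <- function(k) stats::rlnorm(k, -sdlog^2 / 2, sdlog)
  r_tumor <- (purity * exons$copies + 2 * (1 - purity)) / 2
  tumor <- depth_per_exon * r_tumor * noise(m)
  normals <- matrix(depth_per_exon * noise(m * n_normals), nrow = m)
  rownames(normals) <- exons$exon
  names(tumor) <- exons$exon
  list(exons = exons, tumor = tumor, normals = normals)
}

#' Simulate split-read records supporting fusions
#'
#' Emits one record per supporting read for each breakpoint pair in the
#' truth table, with the configured left/right side split, mapping
#' quality, primary/secondary flags, strands, and matched segment
#' lengths.
#'
#' @param fusion_truth data.frame with columns `fusion_id`, `gene_a`,
#'   `chrom_a`, `pos_a`, `strand_a`, `gene_b`, `chrom_b`, `pos_b`,
#'   `strand_b`, `n_left`, `n_right`, and optionally `n_secondary`
#'   (number of the supporting reads flagged secondary), `mapq`,
#'   `matched_len`.
#' @param seed optional integer seed (used only when optional jitter is
#'   requested).
#' @param pos_jitter integer; maximum +/- jitter applied to breakpoint
#'   positions per read (0 = exact).
#' @return data.frame of split reads: `read_id`, `fusion_id`, `side`,
#'   segment A and B coordinates/strands, `mapq`, `secondary`,
#'   `matched_len`, and pass-through gene names.
#' @export
simulate_split_reads <- function(fusion_truth, seed = NULL, pos_jitter = 0L) {
  if (!is.null(seed)) set.seed(seed)
  need <- c("fusion_id", "chrom_a", "pos_a", "strand_a",
            "chrom_b", "pos_b", "strand_b", "n_left", "n_right")
  if (!all(need %in% names(fusion_truth)))
    stop("fusion_truth is missing columns: ",
         paste(setdiff(need, names(fusion_truth)), collapse = ", "))
  if (any(fusion_truth$n_left < 0) || any(fusion_truth$n_right < 0))
    stop("support counts must be >= 0")
  rows <- lapply(seq_len(nrow(fusion_truth)), function(i) {
    tr <- fusion_truth[i, ]
    n <- tr$n_left + tr$n_right
    if (n == 0L) return(NULL)
    n_sec <- if (!is.null(tr$n_secondary)) min(tr$n_secondary, n) else 0L
    jit <- function(k) if (pos_jitter > 0)
      sample(seq(-pos_jitter, pos_jitter), k, replace = TRUE) else integer(k)
    data.frame(
      read_id = sprintf("%s_r%02d", tr$fusion_id, seq_len(n)),
      fusion_id = tr$fusion_id,
      side = rep(c("left", "right"), c(tr$n_left, tr$n_right)),
      gene_a = if (!is.null(tr$gene_a)) tr$gene_a else NA_character_,
      chrom_a = tr$chrom_a, pos_a = tr$pos_a + jit(n),
      strand_a = tr$strand_a,
      gene_b = if (!is.null(tr$gene_b)) tr$gene_b else NA_character_,
      chrom_b = tr$chrom_b, pos_b = tr$pos_b + jit(n),
      strand_b = tr$strand_b,
      mapq = if (!is.null(tr$mapq)) tr$mapq else 60L,
      secondary = seq_len(n) > (n - n_sec),
      matched_len = if (!is.null(tr$matched_len)) tr$matched_len else 50L,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(read_id = character(0), fusion_id = character(0),
                      side = character(0), gene_a = character(0),
                      chrom_a = character(0), pos_a = integer(0),
                      strand_a = character(0), gene_b = character(0),
                      chrom_b = character(0), pos_b = integer(0),
                      strand_b = character(0), mapq = integer(0),
                      secondary = logical(0), matched_len = integer(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate germline SNP pileups under purity and copy state
#'
#' Substrate for tumor purity inference: heterozygous germline SNPs laid
#' across panel segments with per-segment tumor copy states. The
#' expected alternative allele frequency follows the clone-proportion
#' model (see [expected_aaf()]) and coverage scales with total copy
#' number relative to the diploid baseline. The alternative allele of a
#' germline het SNP sits on a random haplotype, so within a segment each
#' SNP is assigned the stated (X, Y) or its mirror (X, X - Y) with equal
#' probability.
#'
#' @param purity tumor purity in [0, 1].
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `total_copies`, `alt_copies`, `n_snps`.
#' @param depth_neutral mean depth of a copy-neutral diploid segment.
#' @param depth_dispersion negative-binomial size for coverage noise.
#' @param base_error_rate per-base error rate.
#' @param seed optional integer seed.
#' @return pileup data.frame with extra columns `segment`,
#'   `true_total_copies`, `true_alt_copies`.
#' @export
simulate_snp_pileups <- function(purity, segments, depth_neutral = 1000,
                                 depth_dispersion = 50,
                                 base_error_rate = 0.001, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(purity >= 0, purity <= 1,
            all(c("chrom", "start", "end", "total_copies", "alt_copies",
                  "n_snps") %in% names(segments)))
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    sg <- segments[i, ]
    k <- sg$n_snps
    X <- sg$total_copies
    # random haplotype: mirror Y -> X - Y with probability 1/2 per SNP
    mirror <- stats::rbinom(k, 1L, 0.5) == 1L
    Y <- ifelse(mirror, X - sg$alt_copies, sg$alt_copies)
    aaf <- expected_aaf(purity, X, Y)
    ratio <- (purity * X + 2 * (1 - purity)) / 2
    depth <- stats::rnbinom(k, size = depth_dispersion,
                            mu = depth_neutral * ratio)
    p <- aaf + (1 - aaf) * base_error_rate / 3
    alt <- stats::rbinom(k, depth, p)
    pos <- as.integer(round(seq(sg$start, sg$end, length.out = k)))
    ref <- sample(.BASES, k, replace = TRUE)
    altb <- vapply(ref, function(b) sample(setdiff(.BASES, b), 1L), "")
    cbind(.new_pileup(chrom = sg$chrom, pos = pos, ref_base = ref,
                      alt_base = altb, depth = depth, alt_count = alt,
                      alt_fwd = stats::rbinom(k, alt, 0.5),
                      ref_fwd = stats::rbinom(k, depth - alt, 0.5),
                      alt_read_offsets = lapply(alt, function(a)
                        if (a > 0) sample.int(100L, a, replace = TRUE) - 1L
                        else integer(0)),
                      true_vaf = aaf),
          data.frame(segment = i, true_total_copies = X,
                     true_alt_copies = Y))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
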