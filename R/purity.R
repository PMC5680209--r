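#' Expected alternative allele frequency under the clone-proportion model
#'
#' For a germline heterozygous SNP in a specimen where the tumor clone
#' (proportion `P` of cells) carries `Y` alternative alleles out of `X`
#' total copies at the locus, the expected alternative allele frequency
#' is `(P*Y + (1-P)) / (P*X + 2*(1-P))`: normal cells contribute one
#' alternative and two total alleles. At (X, Y) = (2, 1) this is 0.5
#' for every P, which is why copy-neutral heterozygous SNPs carry no
#' purity information.
#'
#' @param P tumor clone proportion in [0, 1].
#' @param X total allele copies in tumor cells (>= 1).
#' @param Y alternative allele copies in tumor cells (0 <= Y <= X).
#' @return expected alternative allele frequency.
#' @export
expected_aaf <- function(P, X, Y) {
  stopifnot(all(P >= 0), all(P <= 1), all(X >= 1), all(Y >= 0),
            all(Y <= X))
  den <- P * X + 2 * (1 - P)
  if (any(den == 0)) stop("degenerate denominator (P = 1 with X = 0)")
  (P * Y + (1 - P)) / den
}

#' Solve the clone-proportion model for purity
#'
#' Closed-form inversion of [expected_aaf()]:
#' `P = (2A - 1) / (Y - 1 - A*(X - 2))` with `A` the observed AAF,
#' clipped to [0, 1]. Degenerate configurations where the denominator
#' vanishes -- e.g. (X, Y) = (2, 1), where any P fits, or A = Y/X by
#' symmetry -- return `NA` so the cluster can be skipped.
#'
#' @param observed_aaf observed alternative allele frequency `A`.
#' @param X total allele copies in tumor cells.
#' @param Y alternative allele copies in tumor cells.
#' @return clone proportion in [0, 1], or `NA` for uninformative
#'   configurations.
#' @export
solve_purity <- function(observed_aaf, X, Y) {
  stopifnot(all(observed_aaf >= 0), all(observed_aaf <= 1))
  den <- Y - 1 - observed_aaf * (X - 2)
  P <- ifelse(abs(den) < 1e-9, NA_real_, (2 * observed_aaf - 1) / den)
  pmin(pmax(P, 0), 1)
}

#' Delineate copy-neutral, gain and loss regions from SNP pileups
#'
#' Copy-neutral regions are identified from SNPs with near-balanced
#' minor allele fractions: their read depths form the most prominent
#' peak of the coverage density (pure 4N-everywhere polyploid tumors
#' being rare, the dominant coverage mode is taken as diploid).
#' Contiguous panel segments are then labeled gain or loss by their
#' mean coverage relative to that neutral mode.
#'
#' @param snp_sites SNP pileup data.frame (`chrom`, `pos`, `depth`,
#'   `alt_count`).
#' @param min_snps minimum number of usable balanced SNPs (default 20).
#' @param balanced_band AAF band regarded as balanced.
#' @param gain_ratio,loss_ratio coverage ratios beyond which a segment
#'   is labeled gain or loss.
#' @param segment_gap bp gap starting a new panel segment.
#' @param min_peak_prominence required ratio of the density peak to the
#'   mean density; a flat density declines estimation.
#' @return data.frame of clusters: `segment`, `chrom`, `start`, `end`,
#'   `n_snps`, `depth_ratio`, `folded_aaf` (depth-weighted pooled
#'   max(A, 1-A)), `copy_state_label`; the neutral depth is attached as
#'   attribute `neutral_depth`.
#' @export
find_copy_state_regions <- function(snp_sites, min_snps = 20L,
                                    balanced_band = c(0.4, 0.6),
                                    gain_ratio = 1.15, loss_ratio = 0.85,
                                    segment_gap = 1e5,
                                    min_peak_prominence = 1.2) {
  aaf <- snp_sites$alt_count / pmax(snp_sites$depth, 1L)
  balanced <- aaf >= balanced_band[1] & aaf <= balanced_band[2]
  if (sum(balanced) < min_snps)
    stop("purity estimation declined: fewer than ", min_snps,
         " balanced SNPs available")
  dens <- stats::density(snp_sites$depth[balanced])
  if (max(dens$y) / mean(dens$y) < min_peak_prominence)
    stop("purity estimation declined: no prominent coverage peak")
  neutral_depth <- dens$x[which.max(dens$y)]
  o <- order(snp_sites$chrom, snp_sites$pos)
  s <- snp_sites[o, ]
  new_seg <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)] |
                 diff(s$pos) > segment_gap)
  seg <- cumsum(new_seg)
  folded_alt <- pmax(s$alt_count, s$depth - s$alt_count)
  out <- do.call(rbind, lapply(split(seq_len(nrow(s)), seg), function(i) {
    ratio <- mean(s$depth[i]) / neutral_depth
    data.frame(segment = seg[i[1]], chrom = s$chrom[i[1]],
               start = min(s$pos[i]), end = max(s$pos[i]),
               n_snps = length(i), depth_ratio = ratio,
               folded_aaf = sum(folded_alt[i]) / sum(s$depth[i]),
               copy_state_label = if (ratio > gain_ratio) "gain"
                 else if (ratio < loss_ratio) "loss" else "neutral",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "neutral_depth") <- neutral_depth
  out
}

## (X, Y) hypotheses enumerated per copy-state label. Clusters pool
## *folded* AAFs (max(A, 1-A) per SNP), so mirror-image hypotheses
## (X, X-Y) are redundant: the lower branch solves to P < 0 or a large
## residual and is screened out.
.XY_HYPOTHESES <- list(
  loss = rbind(c(1L, 0L), c(1L, 1L)),
  neutral = rbind(c(2L, 2L)),
  gain = rbind(c(3L, 1L), c(3L, 2L), c(4L, 1L), c(4L, 3L)))

#' Estimate tumor purity from copy-state clusters
#'
#' For each cluster, candidate (X, Y) copy states matching its
#' gain/loss/neutral label are enumerated; each yields a closed-form
#' clone proportion via [solve_purity()]. Solutions whose model AAF
#' misses the observed pooled AAF by more than `residual_tol` are
#' discarded, and among the survivors the hypothesis whose implied
#' coverage ratio `(P*X + 2*(1-P))/2` best matches the cluster's
#' observed depth ratio is kept. Tumor purity is the maximum of the
#' per-cluster clone proportions (the largest clone best represents
#' purity). Estimates below 30% are flagged unreliable and should not
#' be annotated.
#'
#' @param clusters output of [find_copy_state_regions()].
#' @param residual_tol maximum absolute AAF residual (default 0.05).
#' @param reliability_floor purity below which the estimate is flagged
#'   unreliable (default 0.30).
#' @return object of class `purity_estimate`: `P`, `reliable`, and the
#'   per-cluster solutions.
#' @export
estimate_purity <- function(clusters, residual_tol = 0.05,
                            reliability_floor = 0.30) {
  sols <- lapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    hyp <- .XY_HYPOTHESES[[cl$copy_state_label]]
    cand <- do.call(rbind, lapply(seq_len(nrow(hyp)), function(h) {
      X <- hyp[h, 1]; Y <- hyp[h, 2]
      P <- solve_purity(cl$folded_aaf, X, Y)
      if (is.na(P)) return(NULL)
      resid <- abs(expected_aaf(P, X, Y) - cl$folded_aaf)
      if (resid > residual_tol) return(NULL)
      data.frame(segment = cl$segment, X = X, Y = Y, P = P,
                 resid = resid,
                 ratio_err = abs((P * X + 2 * (1 - P)) / 2 -
                                   cl$depth_ratio))
    }))
    if (is.null(cand)) return(NULL)
    cand[which.min(cand$ratio_err), , drop = FALSE]
  })
  sols <- do.call(rbind, sols)
  if (is.null(sols) || nrow(sols) == 0L)
    stop("purity estimation declined: no informative clusters")
  P <- max(sols$P)
  structure(list(P = P, reliable = P >= reliability_floor,
                 clusters = sols),
            class = "purity_estimate")
}

#' @method print purity_estimate
#' @export
print.purity_estimate <- function(x, ...) {
  if (x$reliable)
    cat(sprintf("Estimated tumor purity: %.3f (%d informative clusters)\n",
                x$P, nrow(x$clusters)))
  else
    cat(sprintf(
      "Tumor purity below the 30%% reliability floor (%.3f); not annotated\n",
      x$P))
  invisible(x)
}

#' Purity estimation from SNP pileups in one step
#'
#' Convenience wrapper: [find_copy_state_regions()] followed by
#' [estimate_purity()].
#'
#' @param snp_sites SNP pileup data.frame.
#' @param ... passed on to [find_copy_state_regions()].
#' @return a `purity_estimate`.
#' @export
estimate_purity_from_snps <- function(snp_sites, ...) {
  estimate_purity(find_copy_state_regions(snp_sites, ...))
}
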