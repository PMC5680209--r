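# Fixture builders shared across the suite. Everything is generated in
# code; no binary data.

# A pileup data.frame with exact counts (no sampling noise).
make_pileup <- function(depth, alt, chrom = "chr1",
                        pos = seq(1e6, by = 1000, length.out = length(depth)),
                        alt_fwd = NULL, ref_fwd = NULL, offsets = NULL) {
  n <- length(depth)
  alt <- rep_len(alt, n)
  if (is.null(alt_fwd)) alt_fwd <- alt %/% 2L
  if (is.null(ref_fwd)) ref_fwd <- (depth - alt) %/% 2L
  if (is.null(offsets))
    offsets <- lapply(alt, function(k)
      if (k > 0) as.integer(round(seq(5, 95, length.out = k))) else integer(0))
  data.frame(chrom = chrom, pos = as.integer(pos),
             ref_base = "A", alt_base = "T",
             depth = as.integer(depth), alt_count = as.integer(alt),
             alt_fwd = as.integer(alt_fwd),
             alt_rev = as.integer(alt - alt_fwd),
             ref_fwd = as.integer(ref_fwd),
             ref_rev = as.integer(depth - alt - ref_fwd),
             alt_read_offsets = I(offsets),
             true_vaf = alt / pmax(depth, 1L),
             stringsAsFactors = FALSE)
}

# n exactly heterozygous substrate sites at a fixed depth.
exact_het_sites <- function(n, depth) {
  make_pileup(depth = rep(depth, n), alt = rep(depth %/% 2L, n))
}

# Independent brute-force two-sided Fisher exact p for the 2x2 table
# [[ref_fwd, ref_rev], [alt_fwd, alt_rev]]: enumerate every table with
# the observed margins and sum the probabilities of tables no more
# likely than the observed one (with the same relative tolerance
# fisher.test uses).
fisher_p_bruteforce <- function(ref_fwd, ref_rev, alt_fwd, alt_rev) {
  r1 <- ref_fwd + ref_rev   # ref row margin
  r2 <- alt_fwd + alt_rev   # alt row margin
  c1 <- ref_fwd + alt_fwd   # fwd column margin
  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  a <- lo:hi
  probs <- exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1))
  p_obs <- probs[a == ref_fwd]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Sensitivity records simulated directly from a probit curve
# Phi(a + b log10 d) -- independent of the dilution machinery.
probit_records <- function(a, b, depths, n_per_depth, vaf_bin = 0.05) {
  sens <- pnorm(a + b * log10(depths))
  data.frame(vaf_bin = vaf_bin, depth_bin = depths,
             n_trials = n_per_depth,
             n_detected = rbinom(length(depths), n_per_depth, sens))
}

# Probit models whose 95%-sensitivity depths are exactly `d95`,
# for lod_at_depth tests.
models_with_d95 <- function(vafs, d95, b = 3) {
  mapply(function(v, d) probit_model(a = qnorm(0.95) - b * log10(d), b = b,
                                     vaf_bin = v),
         vafs, d95, SIMPLIFY = FALSE)
}

# Smallest depth at which P(Binom(d, f) >= k) reaches the target
# sensitivity: the exact LOD oracle for the error-free "alt >= k" rule.
exact_binomial_d95 <- function(k, f, target = 0.95) {
  d <- k
  while (pbinom(k - 1, d, f, lower.tail = FALSE) < target) d <- d + 1L
  d
}
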