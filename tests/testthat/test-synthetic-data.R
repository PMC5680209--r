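test_that("simulated pileups satisfy count identities and are reproducible", {
  cfg <- simulation_config(n_sites = 500, depth_mean = 1000, seed = 7)
  sites <- simulate_tumor_pileups(cfg)
  expect_true(validate_pileups(sites))
  expect_identical(sites, simulate_tumor_pileups(cfg))
  expect_true(all(lengths(sites$alt_read_offsets) == sites$alt_count))
  # offsets stay within the read
  offs <- unlist(sites$alt_read_offsets)
  expect_true(all(offs >= 0 & offs <= 99))
})

test_that("expected VAF follows the purity/clone/copy-state accounting", {
  het <- data.frame(total = 2L, variant = 1L)
  # pure tumor, clonal het variant
  cfg1 <- simulation_config(n_sites = 2000, purity = 1, copy_states = het,
                            seed = 1)
  s1 <- simulate_tumor_pileups(cfg1)
  expect_equal(unique(s1$true_vaf), 0.5)
  # half purity halves the expectation
  cfg2 <- simulation_config(n_sites = 2000, purity = 0.5, copy_states = het,
                            seed = 2)
  s2 <- simulate_tumor_pileups(cfg2)
  expect_equal(unique(s2$true_vaf), 0.25)
  # purity 0: only error reads
  cfg0 <- simulation_config(n_sites = 2000, purity = 0, copy_states = het,
                            seed = 3)
  s0 <- simulate_tumor_pileups(cfg0)
  expect_equal(unique(s0$true_vaf), 0)
  expect_lt(mean(s0$alt_count / pmax(s0$depth, 1)), 0.002)
  # realized VAF tracks the expectation (3 Monte Carlo s.e.)
  for (s in list(s1, s2)) {
    v <- s$alt_count / s$depth
    se <- sd(v) / sqrt(nrow(s))
    expect_lt(abs(mean(v) - unique(s$true_vaf)), 3 * se + 1e-3)
  }
  # subclonal variant: c = 0.5 at purity 1 gives VAF 0.25
  cfg_sub <- simulation_config(n_sites = 10, purity = 1,
                               clone_fractions = 0.5, copy_states = het)
  expect_equal(unique(simulate_tumor_pileups(cfg_sub)$true_vaf), 0.25)
})

test_that("config validation rejects out-of-range values", {
  expect_error(simulation_config(purity = 1.2), "purity")
  expect_error(simulation_config(base_error_rate = 0.5), "base_error_rate")
  expect_error(simulation_config(dedup_fraction = 0), "dedup_fraction")
  expect_error(simulation_config(depth_mean = -5), "depth_mean")
  expect_error(simulation_config(purity = NaN), "purity")
  expect_error(simulation_config(
    copy_states = data.frame(total = 2L, variant = 3L)), "copy_states")
})

test_that("in silico dilution hits the target VAF in expectation", {
  sites <- exact_het_sites(1200, depth = 1500)
  dil <- dilute_in_silico(sites, target_vaf = 0.02, seed = 5)
  expect_true(validate_pileups(dil))
  expect_true(all(dil$depth == sites$depth))
  # mean realized VAF within 3 MC s.e. of the target
  se <- sd(dil$realized_vaf) / sqrt(nrow(dil))
  expect_lt(abs(mean(dil$realized_vaf) - 0.02), 3 * se)
  # offsets track surviving variant reads
  expect_true(all(lengths(dil$alt_read_offsets) == dil$alt_count))
  # converted reads moved to the reference strand categories
  expect_true(all(dil$ref_fwd + dil$ref_rev + dil$alt_count == dil$depth))
})

test_that("dilution at the observed VAF leaves sites unchanged and cannot concentrate", {
  sites <- exact_het_sites(5, depth = 1000)
  same <- dilute_in_silico(sites, target_vaf = 0.5, seed = 1)
  expect_equal(same$alt_count, sites$alt_count)
  expect_equal(same$alt_fwd, sites$alt_fwd)
  expect_error(dilute_in_silico(sites, target_vaf = 0.6), "observed VAF")
})

test_that("downsampling preserves the hypergeometric expectation", {
  # depth 1500, 52 variant reads (a low-VAF hotspot profile), target 100:
  # E[alt'] = 52 * 100 / 1500 = 3.4667
  site <- make_pileup(depth = 1500, alt = 52)
  n_rep <- 10000
  alt_seen <- vapply(seq_len(n_rep), function(i)
    downsample_site(site, 100)$alt_count, integer(1))
  expected <- 52 * 100 / 1500
  se <- sd(alt_seen) / sqrt(n_rep)
  expect_lt(abs(mean(alt_seen) - expected), 3 * se)
  expect_true(all(alt_seen <= 52))
  # identity at full depth; zero alt stays zero
  expect_identical(downsample_site(site, 1500), site)
  none <- make_pileup(depth = 500, alt = 0)
  expect_equal(downsample_site(none, 50)$alt_count, 0L)
  expect_error(downsample_site(site, 2000), "exceeds")
})

test_that("pool downsampling thins every read class binomially", {
  sites <- exact_het_sites(800, depth = 1000)
  thin <- pool_downsample(sites, fraction = 0.1, seed = 3)
  expect_true(validate_pileups(thin))
  se <- sd(thin$depth) / sqrt(nrow(thin))
  expect_lt(abs(mean(thin$depth) - 100), 3 * se)
  se_a <- sd(thin$alt_count) / sqrt(nrow(thin))
  expect_lt(abs(mean(thin$alt_count) - 50), 3 * se_a)
})

test_that("normal cohort allele frequencies match the injected population AFs", {
  gs <- data.frame(chrom = "chr1", pos = c(100, 200, 300),
                   ref = "A", alt = "G", pop_af = c(0.5, 0.05, 0))
  coh <- simulate_normal_cohort(400, gs, seed = 9)
  expect_equal(dim(coh$genotypes), c(400L, 3L))
  expect_true(all(coh$genotypes %in% 0:2))
  # allele frequency identity
  expect_equal(coh$sites$cohort_af, colSums(coh$genotypes) / 800)
  # 3 s.e. around each injected AF
  for (j in 1:2) {
    p <- gs$pop_af[j]
    se <- sqrt(p * (1 - p) / 800)
    expect_lt(abs(coh$sites$cohort_af[j] - p), 3 * se)
  }
  expect_equal(coh$sites$cohort_af[3], 0)
  expect_error(simulate_normal_cohort(400, gs[0, ]), "at least one site")
  expect_error(simulate_normal_cohort(1, gs), "n_samples")
})

test_that("mixture VAFs follow proportion-weighted dosages", {
  # 10-line equal mix
  geno <- matrix(0, nrow = 10, ncol = 3)
  geno[1, 1] <- 1   # het in one line -> 5%
  geno[1, 2] <- 2   # hom in one line -> 10%
  geno[, 3] <- 1    # het in all lines -> 50%
  v <- simulate_mixture_vafs(geno, rep(0.1, 10))
  expect_equal(v, c(0.05, 0.10, 0.50))
  expect_error(simulate_mixture_vafs(matrix(3, 1, 1), 1), "dosages")
  expect_error(simulate_mixture_vafs(geno, rep(0.2, 10)), "sum to 1")
})

test_that("exon depth matrices encode the purity-scaled copy ratio", {
  truth <- data.frame(gene = c("NEUT", "AMP", "DEL"), copies = c(2, 6, 0))
  sim <- simulate_exon_depth_matrix(truth, purity = 0.5, noise_cv = 0.02,
                                    n_exons = 50, depth_per_exon = 1000,
                                    seed = 4)
  by_gene <- tapply(sim$tumor, sim$exons$gene, mean) / 1000
  # R = (P*C + 2*(1-P)) / 2
  expect_equal(unname(by_gene["NEUT"]), 1, tolerance = 0.02)
  expect_equal(unname(by_gene["AMP"]), 2, tolerance = 0.02)
  expect_equal(unname(by_gene["DEL"]), 0.5, tolerance = 0.02)
  # homozygous deletion in a pure tumor leaves no coverage at all
  pure <- simulate_exon_depth_matrix(data.frame(gene = "G", copies = 0),
                                     purity = 1, noise_cv = 0.05, seed = 1)
  expect_true(all(pure$tumor == 0))
  expect_error(simulate_exon_depth_matrix(truth, noise_cv = -1), "noise_cv")
})

test_that("split-read generator reproduces the support truth table", {
  truth <- data.frame(fusion_id = c("F1", "F2"),
                      gene_a = "ALK", chrom_a = "chr2",
                      pos_a = c(29446394L, 29447000L), strand_a = "+",
                      gene_b = "EML4", chrom_b = "chr2",
                      pos_b = c(42492091L, 42493000L), strand_b = "-",
                      n_left = c(3L, 0L), n_right = c(2L, 0L),
                      n_secondary = c(2L, 0L))
  reads <- simulate_split_reads(truth)
  expect_equal(nrow(reads), 5L)
  expect_equal(sum(reads$side == "left"), 3L)
  expect_equal(sum(reads$side == "right"), 2L)
  expect_equal(sum(reads$secondary), 2L)
  # zero-support truth emits nothing
  expect_equal(nrow(simulate_split_reads(truth[2, ])), 0L)
  expect_error(simulate_split_reads(data.frame(fusion_id = "X")), "missing")
  bad <- truth; bad$n_left[1] <- -1L
  expect_error(simulate_split_reads(bad), ">= 0")
})

test_that("SNP pileup generator reflects copy state in AAF and coverage", {
  segs <- data.frame(chrom = "chr1", start = 1e6, end = 2e6,
                     total_copies = 3, alt_copies = 2, n_snps = 400)
  snps <- simulate_snp_pileups(0.6, segs, depth_neutral = 1000, seed = 2)
  expect_true(validate_pileups(snps))
  # coverage scales with (P*X + 2*(1-P))/2 = 1.3
  expect_equal(mean(snps$depth) / 1000, 1.3, tolerance = 0.02)
  # folded AAF matches the upper branch (1+P)/(2+P)
  folded <- pmax(snps$alt_count, snps$depth - snps$alt_count) / snps$depth
  expect_equal(mean(folded), (1 + 0.6) / (2 + 0.6), tolerance = 0.01)
})
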