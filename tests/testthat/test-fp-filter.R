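test_that("strand bias equals a brute-force hypergeometric enumeration", {
  # balanced table: p = 1, score 0
  bal <- make_pileup(120, 20, alt_fwd = 10, ref_fwd = 50)
  expect_equal(compute_fp_features(bal)$strand_bias_score, 0)
  # fully one-sided alt reads
  onesided <- make_pileup(110, 10, alt_fwd = 10, ref_fwd = 50)
  got <- compute_fp_features(onesided)$strand_bias_score
  want <- -log10(fisher_p_bruteforce(50, 50, 10, 0))
  expect_equal(got, want, tolerance = 1e-9)
  # random tables with margins <= 30 agree with the enumeration oracle
  set.seed(42)
  for (i in 1:25) {
    rf <- sample(0:15, 1); rr <- sample(0:15, 1)
    af <- sample(0:15, 1); ar <- sample(0:15, 1)
    if ((rf + rr) == 0 || (af + ar) == 0) next
    site <- make_pileup(rf + rr + af + ar, af + ar,
                        alt_fwd = af, ref_fwd = rf)
    got <- compute_fp_features(site)$strand_bias_score
    want <- max(0, -log10(fisher_p_bruteforce(rf, rr, af, ar)))
    expect_equal(got, want, tolerance = 1e-6,
                 info = sprintf("table %d/%d/%d/%d", rf, rr, af, ar))
  }
})

test_that("context features count indels and neighborhood candidates in their windows", {
  sites <- make_pileup(depth = c(1000, 1000, 1000), alt = 20,
                       pos = c(1000L, 1030L, 5000L))
  f0 <- compute_fp_features(sites)
  # no indels supplied, neighbor within 50 bp only for the first pair
  expect_equal(f0$indel_proximity, c(0L, 0L, 0L))
  expect_equal(f0$neighborhood_mutation_count, c(1L, 1L, 0L))
  indels <- data.frame(chrom = "chr1", pos = 1020L)
  f1 <- compute_fp_features(sites, indel_positions = indels)
  expect_equal(f1$indel_proximity, c(1L, 1L, 0L))  # both within 25 bp
})

test_that("read-position clustering contrasts piled-up against dispersed offsets", {
  spread <- make_pileup(1000, 20)
  tight <- make_pileup(1000, 20,
                       offsets = list(rep(c(47L, 48L), 10)))
  f <- compute_fp_features(rbind(spread, tight))
  expect_lt(f$read_position_clustering[1], 0.2)
  expect_gt(f$read_position_clustering[2], 0.9)
  # a single supporting read carries no clustering evidence
  single <- make_pileup(1000, 1)
  expect_equal(compute_fp_features(single)$read_position_clustering, 0)
})

test_that("training recovers separable data, chance labels, and weight signs", {
  set.seed(11)
  n <- 400
  feats <- data.frame(
    indel_proximity = rbinom(n, 1, 0.3),
    neighborhood_mutation_count = rpois(n, 0.5),
    strand_bias_score = rexp(n, 1),
    read_position_clustering = runif(n))
  # (a) linearly separable labels with a clean margin -> AUC 1 and a
  # flagged regularized fit (unpenalized weights would diverge)
  sep <- data.frame(
    indel_proximity = 0, neighborhood_mutation_count = 0,
    strand_bias_score = c(runif(n / 2, 0, 0.8), runif(n / 2, 1.2, 3)),
    read_position_clustering = 0,
    label = rep(0:1, each = n / 2))
  m_sep <- train_fp_filter(sep, seed = 1)
  expect_equal(m_sep$auc, 1)
  expect_true(m_sep$regularized)
  # (b) permuted labels -> cross-validated AUC ~ 0.5 within 3 s.e.
  # over repetitions (the in-sample AUC is optimistically biased)
  aucs <- vapply(1:15, function(i) {
    perm <- feats
    perm$label <- sample(rep(0:1, n / 2))
    train_fp_filter(perm, seed = i)$auc_cv
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(length(aucs)) + 0.02)
  # (c) only strand bias informative: recovered weight sign is positive
  gen <- feats
  eta <- -2 + 2.5 * gen$strand_bias_score
  gen$label <- rbinom(n, 1, plogis(eta))
  if (length(unique(gen$label)) < 2) gen$label[1:2] <- 0:1
  m_gen <- train_fp_filter(gen, seed = 3)
  expect_gt(unname(m_gen$coef["strand_bias_score"]), 0)
  expect_gt(m_gen$auc_cv, 0.7)
  # single-class input is rejected
  one <- feats; one$label <- 1L
  expect_error(train_fp_filter(one), "both classes")
})

test_that("predictions and thresholds are usable downstream", {
  set.seed(2)
  n <- 200
  feats <- data.frame(
    indel_proximity = rbinom(n, 1, 0.5),
    neighborhood_mutation_count = rpois(n, 1),
    strand_bias_score = rexp(n, 1),
    read_position_clustering = runif(n))
  feats$label <- rbinom(n, 1, plogis(-1 + feats$strand_bias_score))
  m <- train_fp_filter(feats, seed = 4)
  p <- predict(m, feats)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(m$threshold > 0 && m$threshold < 1)
})
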