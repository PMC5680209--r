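test_that("dilution-grid sensitivity matches the single-read closed form", {
  # error-free "alt >= 1" rule at VAF 5%, depth 100: sensitivity is
  # about 1 - 0.95^100 = 0.9941 (pool thinning adds slight depth spread)
  sites <- exact_het_sites(300, depth = 10000)
  m <- detection_model(min_alt_reads = 1, alpha = NULL)
  rec <- run_dilution_grid(sites, vafs = 0.05, depths = 100, model = m,
                           reps = 5, seed = 31)
  expect_true(all(rec$n_detected <= rec$n_trials))
  expect_equal(rec$n_detected / rec$n_trials, 1 - 0.95^100,
               tolerance = 0.01)
})

test_that("dilution-grid input contracts are enforced", {
  sites <- exact_het_sites(10, depth = 1000)
  expect_error(run_dilution_grid(sites, 0.05, 100, reps = 0), "reps")
  expect_error(run_dilution_grid(sites[0, ], 0.05, 100), "nonempty")
  expect_error(run_dilution_grid(sites, vafs = 0.6, depths = 100),
               "observed VAF")
})

test_that("probit fits recover known parameters within their confidence intervals", {
  set.seed(13)
  depths <- round(10^seq(1.2, 2.6, length.out = 6))
  rec <- probit_records(a = -5, b = 3, depths = depths, n_per_depth = 2000)
  fit <- fit_probit(rec)
  expect_false(fit$separation)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$a - (-5)), 1.96 * se[1])
  expect_lt(abs(fit$b - 3), 1.96 * se[2])
  # slope positive on monotone-increasing data
  expect_gt(fit$b, 0)
})

test_that("complete separation is flagged and still yields a usable fit", {
  rec <- data.frame(vaf_bin = 0.2, depth_bin = c(50, 100, 200, 400),
                    n_trials = 50L, n_detected = c(0L, 0L, 50L, 50L))
  fit <- fit_probit(rec)
  expect_true(fit$separation)
  expect_true(is.finite(fit$a) && is.finite(fit$b) && fit$b > 0)
  expect_error(fit_probit(rec[1, ]), "depth bins")
  two <- rbind(rec, transform(rec, vaf_bin = 0.4))
  expect_error(fit_probit(two), "single VAF")
})

test_that("the sensitivity curve inverts in closed form", {
  m <- probit_model(a = -5, b = 3)
  expect_equal(depth_for_sensitivity(m, 0.95), 164.040547073,
               tolerance = 1e-9)
  # round trip: predicted sensitivity at that depth is exactly 95%
  expect_equal(predict(m, depth_for_sensitivity(m)), 0.95)
  expect_error(depth_for_sensitivity(probit_model(1, -2)), "positive")
})

test_that("probit-derived 95% depths match the exact binomial oracle", {
  # error-free "alt >= k" rule: the LOD has a closed form, the smallest
  # depth with P(Binom(d, f) >= k) >= 0.95; the full dilution + probit
  # machinery must agree within 10% relative depth
  for (k in c(1L, 4L)) {
    sites <- exact_het_sites(250, depth = 20000)
    model <- detection_model(min_alt_reads = k, alpha = NULL)
    for (f in c(0.02, 0.05, 0.1, 0.2, 0.4)) {
      d_star <- exact_binomial_d95(k, f)
      depths <- unique(pmax(k, round(
        d_star * c(0.5, 0.65, 0.8, 0.9, 1, 1.15, 1.35, 1.6))))
      rec <- run_dilution_grid(sites, vafs = f, depths = depths,
                               model = model, reps = 12,
                               seed = 1000 + k * 10 + round(100 * f),
                               thinning = "fixed")
      est <- depth_for_sensitivity(fit_probit(rec))
      expect_lt(abs(est - d_star) / d_star, 0.10,
                label = sprintf("k=%d f=%.2f est=%.1f exact=%d",
                                k, f, est, d_star))
    }
  }
})

test_that("95% depths fall and LOD-at-depth steps as calibrated", {
  vafs <- c(0.02, 0.05, 0.10, 0.20, 0.40)
  d95 <- c(1085, 294, 94, 40, 18)
  models <- models_with_d95(vafs, d95)
  # strictly decreasing in VAF
  expect_true(all(diff(vapply(models, depth_for_sensitivity,
                              numeric(1))) < 0))
  # the published grid read-outs
  expect_equal(lod_at_depth(models, 94)$lod, 0.10)
  expect_equal(lod_at_depth(models, 1085)$lod, 0.02)
  expect_equal(lod_at_depth(models, 294)$lod, 0.05)
  # above the calibrated range: smallest VAF, flagged
  high <- lod_at_depth(models, 5000)
  expect_equal(high$lod, 0.02)
  expect_equal(high$flag, "above_range")
  # below the calibrated range: no LOD
  low <- lod_at_depth(models, 5)
  expect_true(is.na(low$lod))
  expect_equal(low$flag, "below_range")
  # monotone: shallower depth never has a smaller LOD
  qd <- c(10, 20, 45, 90, 100, 300, 500, 1100, 2000)
  lods <- vapply(qd, function(d) {
    l <- lod_at_depth(models, d)$lod
    if (is.na(l)) 1 else l
  }, numeric(1))
  expect_true(all(diff(lods) <= 0))
})

test_that("downsampling detection rates behave at the boundaries", {
  # full-depth downsampling is the identity: rate 1 for detected sites
  sites <- make_pileup(depth = rep(1500L, 10), alt = 52L)
  r_full <- detection_rate_by_downsampling(sites, 1500, n_iter = 3,
                                           seed = 2)
  expect_equal(r_full$rate, 1)
  # a balanced het at 50x under "alt >= 4" is essentially always seen
  het <- make_pileup(depth = 5000L, alt = 2500L)
  r50 <- detection_rate_by_downsampling(het, 50, n_iter = 200, seed = 3)
  expect_gt(r50$rate, 0.99)
  # shallower sites are skipped with a warning
  mix <- make_pileup(depth = c(1500L, 80L), alt = c(52L, 10L))
  expect_warning(
    r <- detection_rate_by_downsampling(mix, 100, n_iter = 2, seed = 4),
    "skipped")
  expect_equal(r$n_sites, 1L)
})

test_that("LOD reports annotate every panel position", {
  models <- models_with_d95(c(0.02, 0.05, 0.10, 0.20, 0.40),
                            c(1085, 294, 94, 40, 18))
  pos <- data.frame(chrom = "chr7", pos = c(55249071L, 55242465L, 1L),
                    depth = c(1085, 10, 0))
  rep_tab <- lod_report(pos, models)
  expect_equal(nrow(rep_tab), 3L)
  expect_equal(rep_tab$lod[1], 0.02)
  # 10x is below even the 40% VAF calibration; 0 depth has no power
  expect_equal(rep_tab$status, c("ok", "insufficient power", "no power"))
  # the ceiling downgrades positions whose LOD is attainable but poor
  mid <- lod_report(data.frame(chrom = "chr7", pos = 1L, depth = 30),
                    models, lod_ceiling = 0.2)
  expect_equal(mid$status, "insufficient power")
  tf <- tempfile(fileext = ".tsv")
  lod_report(pos, models, path = tf)
  expect_true(file.exists(tf))
})
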