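test_that("generation is deterministic under the world seed", {
  w <- WorldTruth(seed = 99, depth = 2e4, n_taxa = 80)
  g1 <- generateSamples(w, 4)
  g2 <- generateSamples(w, 4)
  expect_identical(sampleMetadata(g1), sampleMetadata(g2))
  expect_identical(sampleTruth(g1), sampleTruth(g2))
  expect_identical(lapply(sampleProfiles(g1), taxonCounts),
                   lapply(sampleProfiles(g2), taxonCounts))
  expect_equal(length(g1), 4L)
  # a different seed changes the draws
  g3 <- generateSamples(WorldTruth(seed = 100, depth = 2e4, n_taxa = 80), 4)
  expect_false(identical(sampleMetadata(g1)$extracted_rna_ng,
                         sampleMetadata(g3)$extracted_rna_ng))
  expect_error(WorldTruth(retention = 0), "retention")
  expect_error(WorldTruth(imaginary = 1), "unknown")
})

test_that("generated metadata obeys the extraction mass bookkeeping", {
  w <- WorldTruth(seed = 7, depth = 2e4, n_taxa = 60, retention = 0.3,
                  spike_retention = 0.8)
  g <- generateSamples(w, 5)
  md <- sampleMetadata(g)
  tr <- sampleTruth(g)
  soil_dw <- md$soil_fresh_g * md$dry_matter_fraction
  expect_equal(md$extracted_rna_ng,
               tr$true_total_rna_ng_per_g_dw * soil_dw * 0.3 + 30 * 0.8)
  expect_equal(tr$spike_retention, rep(0.8, 5))
  # per-gram identity: extracted RNA scaled per g DW matches the truth table
  expect_equal(perGramDW(tr$community_extracted_ng, md$soil_fresh_g,
                         md$dry_matter_fraction),
               tr$true_total_rna_ng_per_g_dw * 0.3)
})

test_that("spike abundance converges to its expectation at high depth", {
  w <- WorldTruth(seed = 17, depth = 1e6, n_taxa = 100, rna_cv = 1e-9,
                  retention = 1, spike_retention = 1)
  g <- generateSamples(w, 3)
  md <- sampleMetadata(g)
  tr <- sampleTruth(g)
  obs <- vapply(sampleProfiles(g),
                function(p) spikeAbundance(splitSpike(p)), 0)
  # observed read share within 3 binomial SEs of the recorded expectation
  se <- sqrt(tr$expected_spike_pct / 100 *
               (1 - tr$expected_spike_pct / 100) / w@depth) * 100
  expect_true(all(abs(obs - tr$expected_spike_pct) <= 3 * se))
  # with full retention the expectation is close to the mass-ratio
  # prediction; the small gap is the 18S length weighting
  mass_expect <- expectedSpikeAbundance(md$spike_ng, md$extracted_rna_ng)
  expect_equal(tr$expected_spike_pct, mass_expect, tolerance = 0.02)
})

test_that("AMP libraries shift spike abundance by the configured bias", {
  w <- WorldTruth(seed = 23, depth = 1e6, n_taxa = 100, rna_cv = 1e-9)
  nonamp <- generateSamples(w, 3, protocol = "nonAMP")
  amp <- generateSamples(w, 3, protocol = "AMP")
  shift <- sampleTruth(amp)$expected_spike_pct -
    sampleTruth(nonamp)$expected_spike_pct
  expect_equal(shift, rep(0.4, 3), tolerance = 1e-9)
  obs_shift <- mean(
    vapply(sampleProfiles(amp), function(p) spikeAbundance(splitSpike(p)), 0) -
    vapply(sampleProfiles(nonamp), function(p) spikeAbundance(splitSpike(p)), 0))
  expect_equal(obs_shift, 0.4, tolerance = 0.05)
  # eukaryote reads are enriched in the AMP variant
  euk_share <- function(g) mean(vapply(sampleProfiles(g), function(p) {
    dom <- relativeAbundance(profileWithoutSpike(splitSpike(p)), "domain")
    sum(dom[names(dom) == "Eukaryota"])
  }, 0))
  expect_gt(euk_share(amp), 1.5 * euk_share(nonamp))
})

test_that("the spike-in estimator recovers true totals while qMeTra tracks retention", {
  rec <- recoveryExperiment(WorldTruth(), retentions = c(0.1, 0.4, 1),
                            n_samples = 5, seed = 271)
  # spike-in estimate: unbiased for the true (pre-retention) RNA content
  expect_lt(median(abs(rec$naestd_rel_error)), 0.05)
  # qMeTra estimate divided by truth equals the retention fraction
  by_r <- split(rec$qmetra_truth_ratio, rec$retention)
  for (r in names(by_r))
    expect_equal(mean(by_r[[r]]), as.numeric(r), tolerance = 0.02)
  # at r = 1 both methods agree within sampling error
  full <- rec[rec$retention == 1, ]
  expect_equal(full$naestd_total_rna_ng_per_g_dw /
                 full$true_total_rna_ng_per_g_dw,
               rep(1, nrow(full)), tolerance = 0.05)
  expect_equal(full$qmetra_truth_ratio, rep(1, nrow(full)), tolerance = 0.05)
})

test_that("generated profiles satisfy conservation and the configured level", {
  w <- WorldTruth(seed = 37, depth = 1e5, n_taxa = 120)
  g <- generateSamples(w, 4)
  tr <- sampleTruth(g)
  for (i in 1:4) {
    prof <- sampleProfiles(g)[[i]]
    acc <- splitSpike(prof)
    expect_equal(spikeReads(acc) + totalReads(profileWithoutSpike(acc)),
                 totalReads(prof))
    p <- tr$expected_spike_pct[i] / 100
    sd3 <- 3 * sqrt(p * (1 - p) / w@depth)
    expect_lt(abs(spikeReads(acc) / totalReads(prof) - p), sd3 + 1e-12)
  }
})
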