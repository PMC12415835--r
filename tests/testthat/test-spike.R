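test_that("splitSpike removes the standard's clades and conserves counts", {
  prof <- TaxonProfile(
    c(9, 991),
    lineages = c(SPIKE_LINEAGE, "Bacteria;Bacillota;Bacilli;Bacillales;Bacillaceae;Bacillus"),
    sample_id = "d2")
  acc <- splitSpike(prof)
  expect_equal(spikeReads(acc), 9)
  expect_equal(spikeAbundance(acc), 0.9)
  expect_equal(totalReads(profileWithoutSpike(acc)), 991)

  # no spike lineages -> zero; all spike -> 100% and empty remainder
  clean <- TaxonProfile(c("Bacteria;X;Y;Z" = 10))
  expect_equal(spikeAbundance(splitSpike(clean)), 0)
  allspike <- TaxonProfile(structure(7, names = SPIKE_LINEAGE))
  acc2 <- splitSpike(allspike)
  expect_equal(spikeAbundance(acc2), 100)
  expect_equal(totalReads(profileWithoutSpike(acc2)), 0)

  # Enterobacteriaceae (the vector trace) is removed too, and deeper
  # assignments under a removed clade match by their rank position
  mixed <- fixtureProfile()
  acc3 <- splitSpike(mixed)
  expect_equal(spikeReads(acc3), 21 + 9)
  # matching is exact at the rank: a genus merely named like the family is kept
  trap <- TaxonProfile(c("Bacteria;P;C;O;NotEnterobacteriaceaeX;G" = 5))
  expect_equal(spikeReads(splitSpike(trap)), 0)
})

test_that("spike splitting conserves counts taxon-by-taxon and is idempotent", {
  set.seed(21)
  for (i in 1:25) {
    prof <- randomProfile(15)
    # randomly graft spike taxa into some profiles
    if (i %% 2 == 0) {
      cnt <- c(taxonCounts(prof), structure(i, names = SPIKE_LINEAGE))
      prof <- TaxonProfile(cnt, sample_id = sampleId(prof))
    }
    acc <- splitSpike(prof)
    kept <- taxonCounts(profileWithoutSpike(acc))
    orig <- taxonCounts(prof)
    # taxon-by-taxon: kept counts match the input on every kept taxon,
    # and removed mass equals the difference
    expect_identical(orig[names(kept)], kept)
    expect_equal(sum(orig) - sum(kept), spikeReads(acc))
    # idempotence
    again <- splitSpike(profileWithoutSpike(acc))
    expect_equal(spikeReads(again), 0)
    expect_identical(taxonCounts(profileWithoutSpike(again)), kept)
  }
})

test_that("non-rRNA profiles use the phylum-level rule set", {
  nr <- TaxonProfile(
    c(999, 1, 500),
    lineages = c("Archaea;Crenarchaeota;Thermoprotei;Sulfolobales",
                 "Viruses;Taleaviricota;SSV1",
                 "Bacteria;Pseudomonadota;Gammaproteobacteria"),
    fraction = "nonrRNA")
  acc <- splitSpike(nr)
  expect_equal(spikeReads(acc), 1000)
  # the same lineages in an SSU profile fall under the SSU rules instead:
  # Thermoprotei still matches (class rank) but Taleaviricota does not
  ssu <- TaxonProfile(taxonCounts(nr), fraction = "SSU")
  expect_equal(spikeReads(splitSpike(ssu)), 999)
})

test_that("expected spike abundance follows the mass ratio convention", {
  expect_equal(expectedSpikeAbundance(30, 839), 100 * 30 / 839)
  expect_equal(round(expectedSpikeAbundance(30, 839), 1), 3.6)
  expect_equal(expectedSpikeAbundance(0, 839), 0)
  expect_equal(expectedSpikeAbundance(30, 30), 100)
  expect_error(expectedSpikeAbundance(30, 0), "positive")
  # monotone decreasing in the extract mass
  ext <- seq(100, 2000, by = 100)
  expect_true(all(diff(expectedSpikeAbundance(30, ext)) < 0))
})

test_that("outlier flagging finds aberrant spike abundances iteratively", {
  # cohort shaped like a 48-sample dataset: ~0.9 +/- 0.7 plus 50% and 5%
  set.seed(4)
  pct <- c(pmax(rnorm(46, 0.9, 0.7), 0.05), 50, 5)
  names(pct) <- sprintf("s%02d", seq_along(pct))
  flags <- flagSpikeOutliers(pct)
  expect_identical(sort(flags$sample_id[flags$flagged]), c("s47", "s48"))
  expect_equal(sum(flags$flagged), 2L)

  # all equal -> none flagged
  none <- flagSpikeOutliers(structure(rep(1, 5), names = letters[1:5]))
  expect_false(any(none$flagged))

  # fixed threshold overrides the iterative rule
  fixed <- flagSpikeOutliers(structure(c(1, 1, 1, 1, 10), names = letters[1:5]),
                             high_pct = 5)
  expect_equal(sum(fixed$flagged), 1L)
  expect_true(fixed$flagged[5])
  expect_error(flagSpikeOutliers(structure(1, names = "x")), "at least 2")

  # accepts a list of accountings
  profs <- list(
    TaxonProfile(c(structure(1, names = SPIKE_LINEAGE), "Bacteria;X" = 99)),
    TaxonProfile(c(structure(2, names = SPIKE_LINEAGE), "Bacteria;X" = 98),
                 sample_id = "b"))
  fl <- flagSpikeOutliers(lapply(profs, splitSpike))
  expect_equal(fl$spike_abundance_pct, c(1, 2))
})
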