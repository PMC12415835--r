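test_that("profile reading sums counts, merges duplicates and validates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("lineage\tcount",
               "Bacteria;Bacillota;Bacilli;Bacillales;Bacillaceae\t10",
               "Archaea;Crenarchaeota;Thermoprotei;Sulfolobales\t5"), path)
  p <- readTaxonProfile(path, sample_id = "a")
  expect_s4_class(p, "TaxonProfile")
  expect_equal(totalReads(p), 15)
  expect_equal(length(taxonCounts(p)), 2L)

  # duplicate lineages merge with a warning
  writeLines(c("lineage,count", "Bacteria;X,3", "Bacteria;X,4"), path)
  expect_warning(p2 <- readTaxonProfile(path), "duplicate")
  expect_equal(unname(taxonCounts(p2)), 7)

  # empty table is a valid zero-read profile
  writeLines("lineage\tcount", path)
  p3 <- readTaxonProfile(path)
  expect_equal(totalReads(p3), 0)
  expect_equal(length(taxonCounts(p3)), 0L)

  # malformed inputs fail loudly
  writeLines(c("taxon\tn", "x\t1"), path)
  expect_error(readTaxonProfile(path), "lineage")
  writeLines(c("lineage\tcount", "Bacteria;X\t-2"), path)
  expect_error(readTaxonProfile(path), "row 1")
  writeLines(c("lineage\tcount", "Bacteria;X\t2.5"), path)
  expect_error(readTaxonProfile(path), "invalid count")
})

test_that("results tables round-trip bit-exactly with NA convention", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(
    sample_id = c("a", "b"), method = c("NAEstd", "MBC"),
    transcripts_per_g_dw = c(1.63e13, NA),
    biomass_ug_per_g_dw = c(580.123456789012, 1 / 3))
  writeResultsTable(tab, path)
  lines <- readLines(path)
  expect_length(lines, 3L)            # header + 2 data rows
  expect_match(lines[3], "NA")
  back <- readResultsTable(path)
  expect_identical(back$sample_id, tab$sample_id)
  expect_identical(back$transcripts_per_g_dw, tab$transcripts_per_g_dw)
  expect_identical(back$biomass_ug_per_g_dw, tab$biomass_ug_per_g_dw)
  expect_error(writeResultsTable(NULL, path), "NULL")

  # TaxonProfile round trip preserves integer counts exactly
  prof <- fixtureProfile()
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeTaxonProfile(prof, p2)
  expect_identical(taxonCounts(readTaxonProfile(p2)), taxonCounts(prof))
})

test_that("relative abundances sum to one at any rank and pool correctly", {
  p <- TaxonProfile(c("Bacteria;F1;C;O;FamA;A" = 1, "Bacteria;F1;C;O;FamB;B" = 3),
                    sample_id = "x")
  ab <- relativeAbundance(p)
  expect_equal(unname(ab), c(0.25, 0.75))

  single <- TaxonProfile(c("Bacteria;X" = 5))
  expect_equal(unname(relativeAbundance(single)), 1.0)

  # pooling at family level; a lineage lacking the rank goes to unclassified
  p2 <- TaxonProfile(c("Bacteria;F1;C;O;FamA;A" = 2, "Bacteria;F1;C;O;FamA;B" = 2,
                       "Bacteria;F1" = 4), sample_id = "y")
  fam <- relativeAbundance(p2, "family")
  expect_equal(fam[["FamA"]], 0.5)
  expect_equal(fam[["unclassified"]], 0.5)

  # property: sums to 1 at every rank for fuzzed profiles
  set.seed(11)
  for (i in 1:20) {
    rp <- randomProfile(sample.int(30, 1) + 1)
    for (rk in c(NULL, "domain", "phylum", "family", "genus"))
      expect_equal(sum(relativeAbundance(rp, rk)), 1, tolerance = 1e-12)
  }
  empty <- TaxonProfile(numeric(0), lineages = character(0))
  expect_error(relativeAbundance(empty), "undefined")
})

test_that("lineage rank extraction is positional and case-sensitive", {
  expect_identical(rankLabel("Bacteria;Firmicutes;Bacilli", "class"), "Bacilli")
  expect_identical(rankLabel("Bacteria;Firmicutes", "family"), NA_character_)
  expect_identical(rankLabel("bacteria;x", "domain"), "bacteria")
  expect_error(rankLabel("Bacteria", "species"))
})

test_that("metadata reading enforces required columns and ranges", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\textracted_rna_ng\tspike_ng\tsoil_fresh_g\tdry_matter_fraction",
    "s1\t839\t30\t0.5\t0.4"), path)
  m <- readSampleMetadata(path)
  expect_equal(m$dilution_factor, 100)   # default fills in
  writeLines(c("sample_id\tspike_ng", "s1\t30"), path)
  expect_error(readSampleMetadata(path), "extracted_rna_ng")
  bad <- data.frame(sample_id = "s", extracted_rna_ng = 10, spike_ng = 30,
                    soil_fresh_g = 0.5, dry_matter_fraction = 1.4,
                    dilution_factor = 100)
  expect_error(validateSampleMetadata(bad), "dry_matter_fraction")
})

test_that("constants validate and can be overridden from file", {
  k <- defaultConstants()
  expect_equal(k@f_mrna + k@f_rrna, 1)
  expect_equal(molarMass16S(k), 480909)
  expect_equal(molarMass16S(ConstantsSet(molar_mass_16s_da = 4.5e5)), 4.5e5)
  expect_error(ConstantsSet(f_mrna = 0.1), "f_mrna \\+ f_rrna")
  expect_error(ConstantsSet(nonsense = 2), "unknown")

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("ribosomes_per_cell: 10000", "cell_mass_g: 2.0e-13"), yml)
  k2 <- readConstants(yml)
  expect_equal(k2@ribosomes_per_cell, 10000)
  expect_equal(k2@cell_mass_g, 2e-13)

  flat <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "len_16s_nt = 1600"), flat)
  expect_equal(readConstants(flat)@len_16s_nt, 1600)
})
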