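#' @import methods
NULL

## Rank vocabulary used for SILVA-style semicolon-delimited lineages.
## Positional: "Bacteria;Firmicutes;Bacilli;Bacillales;Bacillaceae;Bacillus"
.LINEAGE_RANKS <- c(domain = 1L, phylum = 2L, class = 3L, order = 4L,
                    family = 5L, genus = 6L)

.PROTOCOLS <- c("AMP", "nonAMP", "unknown")
.FRACTIONS <- c("SSU", "nonrRNA")

#' ConstantsSet: molecular and biomass conversion constants
#'
#' Houses every fixed number the quantification chains rely on: the mass
#' composition of total RNA (mRNA:rRNA ratio, SSU share of rRNA), transcript
#' lengths and per-nucleotide masses, the Avogadro constant, per-cell ribosome
#' content and cell dry mass, fumigation-extraction correction factors and the
#' elemental composition of microbial biomass. All values can be overridden at
#' construction or from a config file ([readConstants()]), so each assumption
#' is visible and auditable in one place.
#'
#' The 16S molar mass is computed from length and per-nucleotide mass
#' (1500 x 320.5 Da + 159 Da for the 5' triphosphate = 480,909 Da) unless
#' `molar_mass_16s_da` is set explicitly.
#'
#' @slot f_mrna mass fraction of total RNA that is mRNA (default 0.04)
#' @slot f_rrna mass fraction of total RNA that is rRNA (default 0.96)
#' @slot f_ssu_of_rrna SSU share of rRNA mass (default 1/3)
#' @slot len_16s_nt,len_18s_nt,len_lsu_nt assumed transcript lengths (nt)
#' @slot mass_per_nt_da average nucleotide mass within an RNA chain (Da)
#' @slot mass_triphosphate_da additional mass of the 5' triphosphate (Da)
#' @slot molar_mass_16s_da 16S molar mass (Da); `NA` means compute from length
#' @slot avogadro Avogadro constant (mol^-1)
#' @slot ribosomes_per_cell assumed ribosome count of an active prokaryote
#' @slot cell_mass_g dry mass of one prokaryotic cell (g)
#' @slot k_extraction_c,k_extraction_n fumigation extractability corrections
#' @slot c_fraction,n_fraction carbon / nitrogen share of cell dry mass
#' @slot qpcr_mass_per_nt_da per-nucleotide mass used in qPCR copy arithmetic
#' @seealso [defaultConstants()], [transcriptsPerNg()], [ssuMassFraction()]
#' @export
setClass("ConstantsSet",
  representation(
    f_mrna = "numeric", f_rrna = "numeric", f_ssu_of_rrna = "numeric",
    len_16s_nt = "numeric", len_18s_nt = "numeric", len_lsu_nt = "numeric",
    mass_per_nt_da = "numeric", mass_triphosphate_da = "numeric",
    molar_mass_16s_da = "numeric", avogadro = "numeric",
    ribosomes_per_cell = "numeric", cell_mass_g = "numeric",
    k_extraction_c = "numeric", k_extraction_n = "numeric",
    c_fraction = "numeric", n_fraction = "numeric",
    qpcr_mass_per_nt_da = "numeric"
  ),
  prototype(
    f_mrna = 0.04, f_rrna = 0.96, f_ssu_of_rrna = 1 / 3,
    len_16s_nt = 1500, len_18s_nt = 1700, len_lsu_nt = 2900,
    mass_per_nt_da = 320.5, mass_triphosphate_da = 159,
    molar_mass_16s_da = NA_real_, avogadro = 6.02214076e23,
    ribosomes_per_cell = 20000, cell_mass_g = 3e-13,
    k_extraction_c = 0.45, k_extraction_n = 0.40,
    c_fraction = 0.50, n_fraction = 0.14,
    qpcr_mass_per_nt_da = 340
  )
)

setValidity("ConstantsSet", function(object) {
  msg <- character()
  slots <- slotNames(object)
  for (s in slots) {
    v <- slot(object, s)
    if (length(v) != 1L)
      msg <- c(msg, sprintf("slot '%s' must be a single number", s))
    else if (s != "molar_mass_16s_da" && (!is.finite(v) || v <= 0))
      msg <- c(msg, sprintf("slot '%s' must be strictly positive", s))
  }
  mm <- object@molar_mass_16s_da
  if (length(mm) == 1L && !is.na(mm) && mm <= 0)
    msg <- c(msg, "molar_mass_16s_da must be positive when set")
  if (length(object@f_mrna) == 1L && length(object@f_rrna) == 1L &&
      is.finite(object@f_mrna) && is.finite(object@f_rrna) &&
      abs(object@f_mrna + object@f_rrna - 1) > 1e-12)
    msg <- c(msg, "f_mrna + f_rrna must equal 1")
  if (length(msg)) msg else TRUE
})

#' TaxonProfile: per-sample taxon count table
#'
#' A validated container for the SSU rRNA (or non-rRNA) read counts of one
#' sequencing library, keyed by SILVA-style semicolon-delimited lineage
#' strings. Counts are whole and non-negative, duplicate lineages are merged
#' at construction, and `total_reads` always equals the sum of counts.
#'
#' @slot sample_id sample identifier
#' @slot protocol library protocol, one of `"AMP"`, `"nonAMP"`, `"unknown"`
#' @slot fraction `"SSU"` or `"nonrRNA"`
#' @slot lineages character vector of lineage strings
#' @slot counts numeric vector of whole non-negative read counts
#' @slot total_reads sum of `counts`
#' @seealso [readTaxonProfile()], [relativeAbundance()], [splitSpike()]
#' @export
setClass("TaxonProfile",
  representation(
    sample_id = "character", protocol = "character", fraction = "character",
    lineages = "character", counts = "numeric", total_reads = "numeric"
  )
)

setValidity("TaxonProfile", function(object) {
  msg <- character()
  if (length(object@sample_id) != 1L) msg <- c(msg, "sample_id must be scalar")
  if (!object@protocol %in% .PROTOCOLS)
    msg <- c(msg, sprintf("protocol must be one of %s",
                          paste(.PROTOCOLS, collapse = ", ")))
  if (!object@fraction %in% .FRACTIONS)
    msg <- c(msg, sprintf("fraction must be one of %s",
                          paste(.FRACTIONS, collapse = ", ")))
  if (length(object@lineages) != length(object@counts))
    msg <- c(msg, "lineages and counts must have equal length")
  if (any(!nzchar(object@lineages)))
    msg <- c(msg, "empty lineage strings are not allowed")
  if (anyDuplicated(object@lineages))
    msg <- c(msg, "duplicate lineages must be merged before construction")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be whole and non-negative")
  if (length(object@total_reads) != 1L ||
      abs(object@total_reads - sum(object@counts)) > 1e-6)
    msg <- c(msg, "total_reads must equal sum(counts)")
  if (length(msg)) msg else TRUE
})

#' SpikeDefinition: taxon-removal rules identifying the internal standard
#'
#' Reads from the RNA extraction standard (total RNA of a hyperthermophilic
#' Sulfolobales archaeon foreign to temperate soils) are recognised in
#' classified profiles by exact rank-label matching. The defaults remove, in
#' the SSU fraction, everything assigned to the archaeal class Thermoprotei
#' (the standard itself) plus the bacterial family Enterobacteriaceae (the
#' E. coli cloning vector carried by the culture), and in the non-rRNA
#' fraction the phyla Crenarchaeota and Taleaviricota (the culture's virus).
#'
#' @slot ssu_rules data.frame with columns `rank`, `label` for SSU profiles
#' @slot nonrrna_rules data.frame with the same columns for non-rRNA profiles
#' @seealso [splitSpike()], [defaultSpikeDefinition()]
#' @export
setClass("SpikeDefinition",
  representation(ssu_rules = "data.frame", nonrrna_rules = "data.frame")
)

.validRules <- function(df, what) {
  msg <- character()
  if (!all(c("rank", "label") %in% names(df)))
    return(sprintf("%s must have columns 'rank' and 'label'", what))
  if (nrow(df) == 0L)
    msg <- c(msg, sprintf("%s must contain at least one rule", what))
  if (!all(df$rank %in% names(.LINEAGE_RANKS)))
    msg <- c(msg, sprintf("%s ranks must be among: %s", what,
                          paste(names(.LINEAGE_RANKS), collapse = ", ")))
  if (anyDuplicated(paste(df$rank, df$label)))
    msg <- c(msg, sprintf("%s labels must be unique per rank", what))
  msg
}

setValidity("SpikeDefinition", function(object) {
  msg <- c(.validRules(object@ssu_rules, "ssu_rules"),
           .validRules(object@nonrrna_rules, "nonrrna_rules"))
  if (length(msg)) msg else TRUE
})

#' SpikeAccounting: spike-read bookkeeping for one profile
#'
#' Result of [splitSpike()]: how many reads matched the spike-removal rules,
#' the spike's relative abundance (percent of total reads), and the cleaned
#' profile. Counts are conserved: spike reads plus the cleaned profile's
#' total equal the input total.
#'
#' @slot sample_id sample identifier
#' @slot spike_reads reads matching the removal rules
#' @slot total_reads input profile total
#' @slot spike_abundance_pct `100 * spike_reads / total_reads` (0 if empty)
#' @slot profile the profile with spike taxa removed
#' @export
setClass("SpikeAccounting",
  representation(
    sample_id = "character", spike_reads = "numeric", total_reads = "numeric",
    spike_abundance_pct = "numeric", profile = "TaxonProfile"
  )
)

setValidity("SpikeAccounting", function(object) {
  msg <- character()
  if (object@spike_reads > object@total_reads)
    msg <- c(msg, "spike_reads cannot exceed total_reads")
  expected <- if (object@total_reads > 0)
    100 * object@spike_reads / object@total_reads else 0
  if (abs(object@spike_abundance_pct - expected) > 1e-9)
    msg <- c(msg, "spike_abundance_pct inconsistent with counts")
  if (abs(object@profile@total_reads -
          (object@total_reads - object@spike_reads)) > 1e-6)
    msg <- c(msg, "cleaned profile total must equal total - spike reads")
  if (length(msg)) msg else TRUE
})

#' QpcrStandard: fitted qRT-PCR standard curve
#'
#' A dilution series of in-vitro transcripts with known copy numbers, fitted
#' as Cq = slope * log10(copies) + intercept. The amplification efficiency is
#' `10^(-1/slope) - 1` (1.0 means perfect per-cycle doubling). A curve is
#' accepted for quantification only when R-squared lies in \[0.98, 1\] and
#' efficiency in \[0.9, 1.10\].
#'
#' @slot points data.frame with columns `copies_per_ul`, `cq`
#' @slot slope,intercept least-squares fit coefficients
#' @slot r_squared coefficient of determination of the fit
#' @slot efficiency amplification efficiency derived from the slope
#' @slot accepted logical acceptance flag
#' @seealso [fitStandardCurve()], [sampleTranscriptsPerGram()]
#' @export
setClass("QpcrStandard",
  representation(
    points = "data.frame", slope = "numeric", intercept = "numeric",
    r_squared = "numeric", efficiency = "numeric", accepted = "logical"
  )
)

setValidity("QpcrStandard", function(object) {
  msg <- character()
  if (!all(c("copies_per_ul", "cq") %in% names(object@points)))
    msg <- c(msg, "points must have columns copies_per_ul and cq")
  if (nrow(object@points) < 3L)
    msg <- c(msg, "a standard curve needs at least 3 points")
  if (length(msg)) msg else TRUE
})

#' MockDesign: layout of an in-silico mock-community experiment
#'
#' Mock samples mix reads subsampled from labelled community and spike pools
#' at fixed spike proportions, plus unspiked controls. The default design
#' (8 sources x 3 spiking levels + 8 controls = 32 mocks) mirrors a
#' classification-validation experiment at levels 10%, 1% and 0.1%.
#'
#' @slot n_sources number of source datasets
#' @slot spike_levels spike read proportions, each in (0, 1)
#' @slot include_controls add one unspiked control per source
#' @slot reads_per_mock reads per mock sample
#' @slot subsample_per_source reads drawn per source pool before mixing
#' @slot seed RNG seed for the subsampling
#' @seealso [buildMocks()], [nMocks()]
#' @export
setClass("MockDesign",
  representation(
    n_sources = "numeric", spike_levels = "numeric",
    include_controls = "logical", reads_per_mock = "numeric",
    subsample_per_source = "numeric", seed = "numeric"
  ),
  prototype(
    n_sources = 8, spike_levels = c(0.10, 0.01, 0.001),
    include_controls = TRUE, reads_per_mock = 5e6,
    subsample_per_source = 2e5, seed = 1
  )
)

setValidity("MockDesign", function(object) {
  msg <- character()
  if (object@n_sources < 1) msg <- c(msg, "n_sources must be >= 1")
  if (length(object@spike_levels) == 0L ||
      any(object@spike_levels <= 0 | object@spike_levels >= 1))
    msg <- c(msg, "spike_levels must lie strictly in (0, 1)")
  if (object@reads_per_mock < 1) msg <- c(msg, "reads_per_mock must be >= 1")
  if (length(msg)) msg else TRUE
})

#' MockExperiment: labelled mock samples ready for recovery evaluation
#'
#' Each mock is a data.frame of (lineage, origin, count) rows where `origin`
#' is the ground-truth source ("spike" or "community"); the assigned lineage
#' may later be perturbed by a confusion-model classifier before spike
#' removal is evaluated.
#'
#' @slot design the [MockDesign-class] that produced the samples
#' @slot samples list of per-mock data.frames
#' @slot mock_id identifiers, parallel to `samples`
#' @slot spike_level nominal spike proportion per mock (0 for controls)
#' @export
setClass("MockExperiment",
  representation(
    design = "MockDesign", samples = "list",
    mock_id = "character", spike_level = "numeric"
  )
)

#' WorldTruth: ground-truth parameters of the synthetic soil world
#'
#' Defines the data-generating process the synthetic module emulates: a
#' lognormal soil community split into pro- and eukaryotes, a true total RNA
#' content per gram dry soil, an extraction retention fraction (the share of
#' community RNA that survives adsorption to soil particles and ends up in
#' the extract), an internal RNA standard added to the slurry before lysis,
#' multinomial SSU read sampling with 1/length molecule weighting, an
#' optional mRNA-amplification library bias, and a qRT-PCR detection
#' efficiency.
#'
#' `spike_retention = NA` (the default) couples the spike's extraction
#' retention to the community's, i.e. the standard is exposed to the same
#' soil chemistry as the released community RNA; a numeric value fixes it
#' independently (1.0 = idealised full recovery).
#'
#' @slot n_taxa number of community taxa
#' @slot euk_taxa_fraction fraction of taxa that are eukaryotic
#' @slot log_sd SD of the lognormal community mass abundances (log scale)
#' @slot true_total_rna_ng_per_g_dw true community RNA content (ng / g DW)
#' @slot retention community RNA extraction retention fraction, in (0, 1]
#' @slot prok_mass_fraction prokaryotic share of community SSU mass
#' @slot spike_ng RNA standard added per sample (ng)
#' @slot spike_retention spike extraction retention; `NA` couples it to
#'   `retention`
#' @slot soil_fresh_g fresh soil mass extracted per sample (g)
#' @slot dry_matter_fraction dry matter per gram fresh soil, in (0, 1]
#' @slot rna_cv between-sample coefficient of variation of true RNA content
#' @slot depth sequencing depth (SSU reads per sample)
#' @slot amp_bias_pp additive shift of spike abundance in AMP libraries
#'   (percentage points)
#' @slot amp_euk_enrichment multiplicative eukaryote read enrichment in AMP
#'   libraries
#' @slot qpcr_detection_efficiency fraction of extracted 16S detected by qPCR
#' @slot seed RNG seed making generation deterministic
#' @seealso [generateSamples()], [recoveryExperiment()]
#' @export
setClass("WorldTruth",
  representation(
    n_taxa = "numeric", euk_taxa_fraction = "numeric", log_sd = "numeric",
    true_total_rna_ng_per_g_dw = "numeric", retention = "numeric",
    prok_mass_fraction = "numeric", spike_ng = "numeric",
    spike_retention = "numeric", soil_fresh_g = "numeric",
    dry_matter_fraction = "numeric", rna_cv = "numeric", depth = "numeric",
    amp_bias_pp = "numeric", amp_euk_enrichment = "numeric",
    qpcr_detection_efficiency = "numeric", seed = "numeric"
  ),
  prototype(
    n_taxa = 300, euk_taxa_fraction = 0.2, log_sd = 2,
    true_total_rna_ng_per_g_dw = 20000, retention = 0.2,
    prok_mass_fraction = 0.95, spike_ng = 30,
    spike_retention = NA_real_, soil_fresh_g = 0.5,
    dry_matter_fraction = 0.4, rna_cv = 0.4, depth = 2e5,
    amp_bias_pp = 0.4, amp_euk_enrichment = 2,
    qpcr_detection_efficiency = 0.02, seed = 1
  )
)

setValidity("WorldTruth", function(object) {
  msg <- character()
  frac_in <- function(x, lo, hi) is.finite(x) && x > lo && x <= hi
  if (object@n_taxa < 2) msg <- c(msg, "n_taxa must be >= 2")
  if (!frac_in(object@retention, 0, 1))
    msg <- c(msg, "retention must lie in (0, 1]")
  if (!frac_in(object@dry_matter_fraction, 0, 1))
    msg <- c(msg, "dry_matter_fraction must lie in (0, 1]")
  if (!frac_in(object@prok_mass_fraction, 0, 1))
    msg <- c(msg, "prok_mass_fraction must lie in (0, 1]")
  if (!is.na(object@spike_retention) &&
      !frac_in(object@spike_retention, 0, 1))
    msg <- c(msg, "spike_retention must be NA (coupled) or in (0, 1]")
  if (!frac_in(object@qpcr_detection_efficiency, 0, 1))
    msg <- c(msg, "qpcr_detection_efficiency must lie in (0, 1]")
  if (object@true_total_rna_ng_per_g_dw <= 0)
    msg <- c(msg, "true_total_rna_ng_per_g_dw must be positive")
  if (object@euk_taxa_fraction < 0 || object@euk_taxa_fraction >= 1)
    msg <- c(msg, "euk_taxa_fraction must lie in [0, 1)")
  if (object@depth < 1) msg <- c(msg, "depth must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SyntheticCommunity: generated samples with recorded ground truth
#'
#' @slot world the generating [WorldTruth-class]
#' @slot profiles list of [TaxonProfile-class] objects, one per sample
#' @slot metadata data.frame of [sample metadata][readSampleMetadata] columns
#'   plus synthetic qPCR Cq values
#' @slot truth data.frame of per-sample true quantities (total RNA, extracted
#'   RNA, expected spike abundance, true transcript numbers) for oracle
#'   comparison
#' @export
setClass("SyntheticCommunity",
  representation(
    world = "WorldTruth", profiles = "list",
    metadata = "data.frame", truth = "data.frame"
  )
)
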