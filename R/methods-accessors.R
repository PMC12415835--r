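#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("sampleId", "TaxonProfile", function(object, ...) object@sample_id)

#' @rdname accessors
setMethod("sampleId", "SpikeAccounting",
          function(object, ...) object@sample_id)

#' @rdname accessors
setMethod("totalReads", "TaxonProfile",
          function(object, ...) object@total_reads)

#' @rdname accessors
setMethod("taxonCounts", "TaxonProfile", function(object, ...) {
  structure(object@counts, names = object@lineages)
})

#' @rdname accessors
setMethod("libraryProtocol", "TaxonProfile",
          function(object, ...) object@protocol)

#' @rdname accessors
setMethod("rnaFraction", "TaxonProfile", function(object, ...) object@fraction)

#' @rdname accessors
setMethod("spikeReads", "SpikeAccounting",
          function(object, ...) object@spike_reads)

#' @rdname accessors
setMethod("totalReads", "SpikeAccounting",
          function(object, ...) object@total_reads)

#' @rdname accessors
setMethod("spikeAbundance", "SpikeAccounting",
          function(object, ...) object@spike_abundance_pct)

#' @rdname accessors
setMethod("profileWithoutSpike", "SpikeAccounting",
          function(object, ...) object@profile)

#' @rdname accessors
setMethod("curveAccepted", "QpcrStandard", function(object, ...) object@accepted)

#' @rdname accessors
setMethod("curveEfficiency", "QpcrStandard",
          function(object, ...) object@efficiency)

#' @rdname accessors
setMethod("nMocks", "MockDesign", function(object, ...) {
  object@n_sources * length(object@spike_levels) +
    if (object@include_controls) object@n_sources else 0
})

#' @rdname accessors
setMethod("nMocks", "MockExperiment",
          function(object, ...) length(object@samples))

#' @rdname accessors
setMethod("worldTruth", "SyntheticCommunity", function(object, ...) object@world)

#' @rdname accessors
setMethod("sampleMetadata", "SyntheticCommunity",
          function(object, ...) object@metadata)

#' @rdname accessors
setMethod("sampleTruth", "SyntheticCommunity",
          function(object, ...) object@truth)

#' @rdname accessors
setMethod("sampleProfiles", "SyntheticCommunity",
          function(object, ...) object@profiles)

setMethod("length", "SyntheticCommunity", function(x) length(x@profiles))

setMethod("show", "TaxonProfile", function(object) {
  cat(sprintf(
    "TaxonProfile '%s' [%s, %s]: %d taxa, %s reads\n",
    object@sample_id, object@protocol, object@fraction,
    length(object@lineages), format(object@total_reads, big.mark = ",")
  ))
})

setMethod("show", "SpikeAccounting", function(object) {
  cat(sprintf(
    "SpikeAccounting '%s': %s / %s reads spike (%.3g%%)\n",
    object@sample_id, format(object@spike_reads, big.mark = ","),
    format(object@total_reads, big.mark = ","), object@spike_abundance_pct
  ))
})

setMethod("show", "ConstantsSet", function(object) {
  cat("ConstantsSet\n")
  for (s in slotNames(object))
    cat(sprintf("  %-22s %g\n", s, slot(object, s)))
  cat(sprintf("  (effective 16S molar mass: %g Da)\n", molarMass16S(object)))
})

setMethod("show", "QpcrStandard", function(object) {
  cat(sprintf(
    paste0("QpcrStandard: %d points, slope %.4f, intercept %.3f, ",
           "R^2 %.4f, efficiency %.3f [%s]\n"),
    nrow(object@points), object@slope, object@intercept,
    object@r_squared, object@efficiency,
    if (object@accepted) "accepted" else "rejected"
  ))
})

setMethod("show", "MockDesign", function(object) {
  cat(sprintf(
    "MockDesign: %d sources x levels {%s}%s -> %d mocks of %s reads\n",
    object@n_sources, paste(object@spike_levels, collapse = ", "),
    if (object@include_controls) " + controls" else "",
    nMocks(object), format(object@reads_per_mock, big.mark = ",")
  ))
})

setMethod("show", "MockExperiment", function(object) {
  cat(sprintf("MockExperiment: %d mock samples (levels: %s)\n",
              nMocks(object),
              paste(sort(unique(object@spike_level)), collapse = ", ")))
})

setMethod("show", "WorldTruth", function(object) {
  cat(sprintf(
    paste0("WorldTruth: %d taxa, true RNA %g ng/g DW, retention %.2f, ",
           "spike %g ng (%s), depth %s, seed %d\n"),
    object@n_taxa, object@true_total_rna_ng_per_g_dw, object@retention,
    object@spike_ng,
    if (is.na(object@spike_retention)) "coupled retention"
    else sprintf("retention %.2f", object@spike_retention),
    format(object@depth, big.mark = ","), as.integer(object@seed)
  ))
})

setMethod("show", "SyntheticCommunity", function(object) {
  cat(sprintf("SyntheticCommunity: %d samples from ", length(object@profiles)))
  show(object@world)
})

setMethod("show", "SpikeDefinition", function(object) {
  fmt <- function(df) paste(sprintf("%s=%s", df$rank, df$label),
                            collapse = ", ")
  cat("SpikeDefinition\n")
  cat("  SSU:      ", fmt(object@ssu_rules), "\n")
  cat("  non-rRNA: ", fmt(object@nonrrna_rules), "\n")
})
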