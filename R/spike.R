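#' @include AllGenerics.R profiles-io.R
NULL

#' Construct spike-removal rule sets
#'
#' `defaultSpikeDefinition()` returns the standard rules: SSU reads assigned
#' to the archaeal class Thermoprotei or the bacterial family
#' Enterobacteriaceae are treated as internal standard, and non-rRNA reads
#' assigned to the phyla Crenarchaeota or Taleaviricota. Matching is by
#' exact label at the stated rank position, so any lineage classified to
#' that clade *or deeper* is removed, while unrelated taxa whose names merely
#' contain the label are not.
#'
#' @param ssu_rules data.frame with columns `rank`, `label`
#' @param nonrrna_rules data.frame with columns `rank`, `label`
#' @return a [SpikeDefinition-class]
#' @export
SpikeDefinition <- function(ssu_rules, nonrrna_rules) {
  new("SpikeDefinition",
      ssu_rules = as.data.frame(ssu_rules, stringsAsFactors = FALSE),
      nonrrna_rules = as.data.frame(nonrrna_rules, stringsAsFactors = FALSE))
}

#' @rdname SpikeDefinition
#' @export
defaultSpikeDefinition <- function() {
  SpikeDefinition(
    ssu_rules = data.frame(
      rank = c("class", "family"),
      label = c("Thermoprotei", "Enterobacteriaceae"),
      stringsAsFactors = FALSE),
    nonrrna_rules = data.frame(
      rank = c("phylum", "phylum"),
      label = c("Crenarchaeota", "Taleaviricota"),
      stringsAsFactors = FALSE))
}

## logical vector: which lineages match any rule of the given rule set
.matchRules <- function(lineages, rules) {
  hit <- rep(FALSE, length(lineages))
  for (i in seq_len(nrow(rules)))
    hit <- hit | (!is.na(l <- rankLabel(lineages, rules$rank[i])) &
                    l == rules$label[i])
  hit
}

#' @rdname splitSpike
setMethod("splitSpike", "TaxonProfile",
          function(profile, spikedef = defaultSpikeDefinition()) {
  stopifnot(is(spikedef, "SpikeDefinition"))
  rules <- if (profile@fraction == "SSU") spikedef@ssu_rules
           else spikedef@nonrrna_rules
  hit <- .matchRules(profile@lineages, rules)
  spike_reads <- sum(profile@counts[hit])
  kept <- new("TaxonProfile", sample_id = profile@sample_id,
              protocol = profile@protocol, fraction = profile@fraction,
              lineages = profile@lineages[!hit],
              counts = profile@counts[!hit],
              total_reads = sum(profile@counts[!hit]))
  pct <- if (profile@total_reads > 0)
    100 * spike_reads / profile@total_reads else 0
  new("SpikeAccounting", sample_id = profile@sample_id,
      spike_reads = spike_reads, total_reads = profile@total_reads,
      spike_abundance_pct = pct, profile = kept)
})

#' Expected spike relative abundance from masses
#'
#' The expected percentage of spike reads when the full spike mass ends up
#' in the extract: `100 * spike_ng / extracted_ng`, with the total extracted
#' RNA (which already contains the spike) as denominator. With the study's
#' values, 30 ng spike in an 839 ng extract gives ca. 3.6%.
#'
#' @param spike_ng RNA standard added (ng)
#' @param extracted_ng total RNA recovered from the extraction (ng)
#' @return expected abundance in percent
#' @examples
#' expectedSpikeAbundance(30, 839) # ~3.6
#' @export
expectedSpikeAbundance <- function(spike_ng, extracted_ng) {
  stopifnot(spike_ng >= 0)
  if (any(extracted_ng <= 0))
    stop("extracted_ng must be positive")
  100 * spike_ng / extracted_ng
}

#' Flag samples with aberrant spike abundance
#'
#' Technical outliers (e.g. failed extractions) show up as spike relative
#' abundances far from the cohort. The default upper threshold is
#' mean + 3 SD of the currently unflagged samples, re-estimated iteratively
#' until no new sample is flagged; the lower threshold is 0 (disabled)
#' unless given. Flags are reported, never silently dropped.
#'
#' @param accountings list of [SpikeAccounting-class] objects (or a numeric
#'   vector of spike abundances named by sample)
#' @param low_pct fixed lower threshold in percent (default 0 = disabled)
#' @param high_pct fixed upper threshold in percent; `NULL` (default) uses
#'   the iterative mean + 3 SD rule
#' @return data.frame with columns `sample_id`, `spike_abundance_pct`,
#'   `flagged`, `reason`
#' @export
flagSpikeOutliers <- function(accountings, low_pct = 0, high_pct = NULL) {
  if (is.list(accountings)) {
    pct <- vapply(accountings, spikeAbundance, numeric(1))
    ids <- vapply(accountings, sampleId, "")
  } else {
    pct <- as.numeric(accountings)
    ids <- if (!is.null(names(accountings))) names(accountings)
           else sprintf("sample_%d", seq_along(pct))
  }
  if (length(pct) < 2L) stop("outlier flagging needs at least 2 samples")
  if (is.null(high_pct)) {
    keep <- rep(TRUE, length(pct))
    repeat {
      thr <- mean(pct[keep]) + 3 * stats::sd(pct[keep])
      newkeep <- keep & (pct <= thr)
      if (identical(newkeep, keep) || sum(newkeep) < 2L) break
      keep <- newkeep
    }
    high <- thr
  } else {
    high <- high_pct
  }
  flagged <- pct > high | pct < low_pct
  reason <- ifelse(pct > high, sprintf("above %.4g%%", high),
                   ifelse(pct < low_pct, sprintf("below %.4g%%", low_pct), ""))
  data.frame(sample_id = ids, spike_abundance_pct = pct,
             flagged = flagged, reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}
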