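#' @include constants.R spike.R
NULL

#' Total sample RNA from the spike-in standard
#'
#' Scales the known spiked-in RNA mass back by its observed relative read
#' abundance to estimate what a 100% extraction of the sample would have
#' yielded, excluding the standard itself:
#' `spike_ng / spike_abundance_pct * 100 - spike_ng`.
#'
#' Because the standard is added to the soil-buffer slurry before lysis and
#' is exposed to the same soil chemistry as the community RNA, its read
#' abundance reflects the pre-retention RNA pool, not just what the
#' extraction recovered.
#'
#' @param spike_ng RNA standard added (ng), > 0
#' @param spike_abundance_pct observed spike relative abundance in percent,
#'   in (0, 100]
#' @return estimated total sample RNA in ng (spike excluded)
#' @examples
#' naestdTotalRNA(30, 0.9) # 3303.33 ng
#' @export
naestdTotalRNA <- function(spike_ng, spike_abundance_pct) {
  if (any(spike_ng <= 0)) stop("spike_ng must be positive")
  if (any(spike_abundance_pct <= 0 | spike_abundance_pct > 100))
    stop("spike_abundance_pct must lie in (0, 100]")
  spike_ng / spike_abundance_pct * 100 - spike_ng
}

#' Convert a per-sample quantity to per gram dry soil
#'
#' @param quantity_per_sample any per-sample amount (ng RNA, transcripts, ...)
#' @param soil_fresh_g fresh soil mass extracted (g)
#' @param dry_matter_fraction dry matter per g fresh soil, in (0, 1]
#' @return the quantity per g dry-weight soil
#' @export
perGramDW <- function(quantity_per_sample, soil_fresh_g, dry_matter_fraction) {
  if (any(soil_fresh_g <= 0) || any(dry_matter_fraction <= 0))
    stop("soil_fresh_g and dry_matter_fraction must be positive")
  quantity_per_sample / (soil_fresh_g * dry_matter_fraction)
}

#' SSU share of total RNA mass
#'
#' rRNA is taken to be 96% of total RNA by mass (4:96 mRNA:rRNA) and the
#' small subunit one third of the rRNA (SSU ~1500 nt vs LSU ~2900 nt), so
#' with default constants 32% of the total RNA mass is SSU rRNA.
#'
#' @param constants a [ConstantsSet-class]
#' @return fraction of total RNA mass that is SSU rRNA
#' @examples
#' ssuMassFraction() # 0.32
#' @export
ssuMassFraction <- function(constants = defaultConstants()) {
  stopifnot(is(constants, "ConstantsSet"))
  constants@f_rrna * constants@f_ssu_of_rrna
}

#' Convert a prokaryote read-count share to a mass share
#'
#' Reads count molecules; mass weights them by length. With 16S at 1500 nt
#' and 18S at 1700 nt, a prokaryote read fraction p corresponds to the SSU
#' mass fraction `p*1500 / (p*1500 + (1-p)*1700)`.
#'
#' @param prok_count_fraction prokaryotic fraction of SSU reads, in \[0, 1\]
#' @param constants a [ConstantsSet-class]
#' @return prokaryotic fraction of SSU rRNA mass
#' @examples
#' prokMassShare(0.5) # 0.46875
#' @export
prokMassShare <- function(prok_count_fraction,
                          constants = defaultConstants()) {
  if (any(prok_count_fraction < 0 | prok_count_fraction > 1))
    stop("prok_count_fraction must lie in [0, 1]")
  p <- prok_count_fraction
  l16 <- constants@len_16s_nt
  l18 <- constants@len_18s_nt
  p * l16 / (p * l16 + (1 - p) * l18)
}

#' 16S transcripts per nanogram of 16S rRNA
#'
#' `avogadro / molar_mass / 1e9`. Three rate conventions are selectable,
#' because the exact molar mass (480,909 Da -> 1.252e9 / ng), the commonly
#' used rounded mass (4.5e5 Da -> 1.338e9 / ng) and the frequently quoted
#' rate of 1.22e9 / ng are mutually inconsistent; `"exact"` is the default
#' for auditability, and results scale linearly with whichever is chosen.
#'
#' @param constants a [ConstantsSet-class]
#' @param rate `"exact"` (computed molar mass), `"rounded"` (4.5e5 Da) or
#'   `"printed"` (fixed 1.22e9 per ng)
#' @return transcripts per ng
#' @examples
#' transcriptsPerNg()                  # 1.2523e9
#' transcriptsPerNg(rate = "rounded")  # 1.3383e9
#' @export
transcriptsPerNg <- function(constants = defaultConstants(),
                             rate = c("exact", "rounded", "printed")) {
  rate <- match.arg(rate)
  switch(rate,
    exact = constants@avogadro / molarMass16S(constants) / 1e9,
    rounded = constants@avogadro / 4.5e5 / 1e9,
    printed = 1.22e9)
}

## shared tail of the qMeTra / NAE_std chains:
## total RNA (ng per g DW) -> SSU mass -> prokaryote 16S mass -> transcripts
.transcriptChain <- function(sample_id, method, total_rna_ng_per_g,
                             prok_count_fraction, constants, rate) {
  ssu_frac <- ssuMassFraction(constants)
  share <- prokMassShare(prok_count_fraction, constants)
  per_ng <- transcriptsPerNg(constants, rate)
  ssu_ng <- total_rna_ng_per_g * ssu_frac
  transcripts <- ssu_ng * share * per_ng
  data.frame(
    sample_id = sample_id, method = method,
    transcripts_per_g_dw = transcripts,
    total_rna_ng_per_g = total_rna_ng_per_g,
    ssu_ng_per_g = ssu_ng,
    prok_count_fraction = prok_count_fraction,
    prok_mass_share = share,
    transcripts_per_ng = per_ng,
    stringsAsFactors = FALSE)
}

#' qMeTra: 16S transcripts per gram dry soil from extracted RNA mass
#'
#' The quantitative-metatranscriptomics chain: total extracted RNA per g DW
#' soil x SSU mass fraction (32%) x prokaryotic mass share x transcripts
#' per ng. All intermediates are returned for audit. When the extract
#' contains an internal standard, pass its mass in `spike_ng_in_extract` so
#' it is excluded from the community RNA.
#'
#' @param extracted_rna_ng total RNA recovered per sample (ng)
#' @param soil_fresh_g,dry_matter_fraction soil amounts (see [perGramDW()])
#' @param prok_count_fraction prokaryotic fraction of (spike-free) SSU reads
#' @param constants a [ConstantsSet-class]
#' @param rate transcripts-per-ng convention, see [transcriptsPerNg()]
#' @param sample_id identifier carried into the result
#' @param spike_ng_in_extract spike RNA mass contained in
#'   `extracted_rna_ng`, subtracted before scaling (default 0)
#' @return one-row data.frame: `sample_id`, `method`,
#'   `transcripts_per_g_dw` and the audit intermediates
#' @export
qmetraTranscripts <- function(extracted_rna_ng, soil_fresh_g,
                              dry_matter_fraction, prok_count_fraction,
                              constants = defaultConstants(),
                              rate = c("exact", "rounded", "printed"),
                              sample_id = "sample",
                              spike_ng_in_extract = 0) {
  if (extracted_rna_ng < 0) stop("extracted_rna_ng must be >= 0")
  community_ng <- max(extracted_rna_ng - spike_ng_in_extract, 0)
  total_per_g <- perGramDW(community_ng, soil_fresh_g, dry_matter_fraction)
  .transcriptChain(sample_id, "qMeTra", total_per_g, prok_count_fraction,
                   constants, match.arg(rate))
}

#' NAE_std: 16S transcripts per gram dry soil from the spike-in standard
#'
#' Estimates the true (pre-retention) total RNA content with
#' [naestdTotalRNA()], scales it per gram dry soil and applies the same
#' SSU-mass / prokaryote-share / transcripts-per-ng chain as
#' [qmetraTranscripts()].
#'
#' @param spike_ng RNA standard added (ng)
#' @param spike_abundance_pct observed spike read abundance (percent, > 0)
#' @inheritParams qmetraTranscripts
#' @return one-row data.frame as for [qmetraTranscripts()], method
#'   `"NAEstd"`
#' @export
naestdTranscripts <- function(spike_ng, spike_abundance_pct, soil_fresh_g,
                              dry_matter_fraction, prok_count_fraction,
                              constants = defaultConstants(),
                              rate = c("exact", "rounded", "printed"),
                              sample_id = "sample") {
  total_ng <- naestdTotalRNA(spike_ng, spike_abundance_pct)
  total_per_g <- perGramDW(total_ng, soil_fresh_g, dry_matter_fraction)
  .transcriptChain(sample_id, "NAEstd", total_per_g, prok_count_fraction,
                   constants, match.arg(rate))
}

#' Cells from ribosome (16S transcript) numbers
#'
#' Assumes every active prokaryote carries `ribosomes_per_cell` ribosomes
#' (default 20,000), i.e. cells = transcripts / 20,000.
#'
#' @param transcripts_per_g 16S transcripts per g DW soil
#' @param constants a [ConstantsSet-class]
#' @return cells per g DW soil
#' @examples
#' cellsFromTranscripts(2.73e10) # 1.365e6
#' @export
cellsFromTranscripts <- function(transcripts_per_g,
                                 constants = defaultConstants()) {
  if (any(transcripts_per_g < 0)) stop("transcripts must be >= 0")
  transcripts_per_g / constants@ribosomes_per_cell
}

#' Biomass from cell numbers
#'
#' One prokaryotic cell is assumed to weigh `cell_mass_g` (default
#' 3e-13 g DW); the result is reported in micrograms.
#'
#' @param cells_per_g cells per g DW soil
#' @param constants a [ConstantsSet-class]
#' @return biomass in ug DW per g DW soil
#' @export
biomassFromCells <- function(cells_per_g, constants = defaultConstants()) {
  if (any(cells_per_g < 0)) stop("cells must be >= 0")
  cells_per_g * constants@cell_mass_g * 1e6
}

#' Microbial biomass from chloroform fumigation extraction
#'
#' MB(C/N) is the fumigated-minus-unfumigated difference in dissolved
#' organic carbon (or total dissolved nitrogen), corrected for incomplete
#' extraction (k = 0.45 for C, 0.40 for N). The element mass converts to
#' total dry biomass via the assumed elemental composition of a cell:
#' carbon 50% of dry mass (biomass = 2 x MBC), nitrogen 14%
#' (biomass = MBN / 0.14). A negative difference is clipped to zero with a
#' warning (field-data noise, not an error).
#'
#' @param fumigated concentration in the fumigated extract (ug element / g)
#' @param unfumigated concentration in the unfumigated extract
#' @param element `"C"` or `"N"`
#' @param constants a [ConstantsSet-class]
#' @return list with `mb` (corrected MBC or MBN, ug element / g DW) and
#'   `biomass_ug_per_g_dw`
#' @examples
#' microbialBiomass(100, 10, "C") # MBC 200, biomass 400
#' @export
microbialBiomass <- function(fumigated, unfumigated, element = c("C", "N"),
                             constants = defaultConstants()) {
  element <- match.arg(element)
  diff <- fumigated - unfumigated
  if (any(diff < 0)) {
    warning("fumigated < unfumigated; microbial biomass clipped to 0",
            call. = FALSE)
    diff <- pmax(diff, 0)
  }
  k <- if (element == "C") constants@k_extraction_c else constants@k_extraction_n
  frac <- if (element == "C") constants@c_fraction else constants@n_fraction
  mb <- diff / k
  list(mb = mb, biomass_ug_per_g_dw = mb / frac)
}

#' Assemble a per-sample, per-method biomass table
#'
#' Combines transcript estimates (rows from [qmetraTranscripts()],
#' [naestdTranscripts()] or the qPCR module) into a long table with the
#' derived cell and biomass columns; optional MBC/MBN rows are appended on
#' the same biomass scale with `NA` transcript and cell columns.
#'
#' @param estimates data.frame with columns `sample_id`, `method`,
#'   `transcripts_per_g_dw`
#' @param mb optional data.frame with columns `sample_id`, `method`
#'   (`"MBC"`/`"MBN"`), `biomass_ug_per_g_dw`
#' @param constants a [ConstantsSet-class]
#' @return data.frame with columns `sample_id`, `method`,
#'   `transcripts_per_g_dw`, `cells_per_g_dw`, `biomass_ug_per_g_dw`
#' @export
biomassTable <- function(estimates, mb = NULL,
                         constants = defaultConstants()) {
  stopifnot(all(c("sample_id", "method", "transcripts_per_g_dw") %in%
                  names(estimates)))
  cells <- cellsFromTranscripts(estimates$transcripts_per_g_dw, constants)
  out <- data.frame(
    sample_id = estimates$sample_id, method = estimates$method,
    transcripts_per_g_dw = estimates$transcripts_per_g_dw,
    cells_per_g_dw = cells,
    biomass_ug_per_g_dw = biomassFromCells(cells, constants),
    stringsAsFactors = FALSE)
  if (!is.null(mb)) {
    stopifnot(all(c("sample_id", "method", "biomass_ug_per_g_dw") %in%
                    names(mb)))
    out <- rbind(out, data.frame(
      sample_id = mb$sample_id, method = mb$method,
      transcripts_per_g_dw = NA_real_, cells_per_g_dw = NA_real_,
      biomass_ug_per_g_dw = mb$biomass_ug_per_g_dw,
      stringsAsFactors = FALSE))
  }
  out
}
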