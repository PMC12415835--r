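#' @include quantify.R qpcr.R
NULL

## lineage of the spike organism: an archaeon of the class Thermoprotei,
## matching the default SSU removal rules
.SPIKE_LINEAGE <-
  "Archaea;Crenarchaeota;Thermoprotei;Sulfolobales;Sulfolobaceae;Saccharolobus"

## canonical in-silico qRT-PCR standard curve (perfect doubling)
.QPCR_SLOPE <- -1 / log10(2)
.QPCR_INTERCEPT <- 38
.QPCR_EXTRACT_VOLUME_UL <- 50
.QPCR_DILUTION <- 100

#' Construct a WorldTruth
#'
#' See [WorldTruth-class] for the meaning of every parameter; arguments
#' override the defaults, which describe a temperate volcanic grassland
#' soil: ca. 20 ug true RNA per g dry soil of which a fifth survives
#' extraction, 0.5 g fresh soil at 40% dry matter per sample, a 30 ng RNA
#' standard spiked before lysis, a 95% prokaryotic community by SSU mass,
#' and 200,000 SSU reads per library.
#'
#' @param ... named slot overrides, e.g. `retention = 0.5`
#' @return a validated [WorldTruth-class]
#' @export
WorldTruth <- function(...) {
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), slotNames("WorldTruth"))
    if (length(unknown))
      stop("unknown world parameters: ", paste(unknown, collapse = ", "))
  }
  do.call(new, c(list("WorldTruth"), overrides))
}

## fixed community layout for a world: lineages and mass shares
.communityLayout <- function(world) {
  n <- round(world@n_taxa)
  n_euk <- round(world@euk_taxa_fraction * n)
  n_prok <- n - n_euk
  lineages <- c(
    if (n_prok > 0) sprintf(
      "Bacteria;Phylum%02d;Class%02d;Order%03d;Family%03d;Genus%04d",
      (seq_len(n_prok) - 1) %% 12 + 1, (seq_len(n_prok) - 1) %% 25 + 1,
      (seq_len(n_prok) - 1) %% 60 + 1, (seq_len(n_prok) - 1) %/% 3 + 1,
      seq_len(n_prok)),
    if (n_euk > 0) sprintf(
      "Eukaryota;EukPhylum%02d;EukClass%02d;EukOrder%02d;EukFamily%03d;EukGenus%04d",
      (seq_len(n_euk) - 1) %% 8 + 1, (seq_len(n_euk) - 1) %% 15 + 1,
      (seq_len(n_euk) - 1) %% 30 + 1, (seq_len(n_euk) - 1) %/% 3 + 1,
      seq_len(n_euk)))
  is_euk <- c(rep(FALSE, n_prok), rep(TRUE, n_euk))
  mass <- stats::rlnorm(n, meanlog = 0, sdlog = world@log_sd)
  pmf <- if (n_euk == 0) 1 else world@prok_mass_fraction
  share <- numeric(n)
  if (n_prok > 0)
    share[!is_euk] <- mass[!is_euk] / sum(mass[!is_euk]) * pmf
  if (n_euk > 0)
    share[is_euk] <- mass[is_euk] / sum(mass[is_euk]) * (1 - pmf)
  list(lineages = lineages, is_euk = is_euk, mass_share = share, pmf = pmf)
}

#' Generate synthetic soil metatranscriptome samples
#'
#' Simulates the full measurement process with known ground truth. Per
#' sample: the true community RNA content varies lognormally around the
#' world mean (`rna_cv`); extraction retains fraction `retention` of the
#' community RNA and `spike_retention` of the standard (coupled to
#' `retention` when `NA`); SSU reads are drawn multinomially over the spike
#' taxon and the community taxa with probabilities proportional to
#' extracted SSU mass / transcript length (16S 1500 nt, 18S 1700 nt); AMP
#' libraries additionally enrich eukaryote reads and shift the spike
#' abundance by `amp_bias_pp` percentage points. A synthetic qRT-PCR Cq per
#' sample is derived from the extracted community 16S transcripts times the
#' detection efficiency, read off a perfect-doubling standard curve.
#'
#' Deterministic under the world's seed.
#'
#' @param world a [WorldTruth-class]
#' @param n_samples number of samples to generate
#' @param protocol library protocol for all samples (`"nonAMP"` or `"AMP"`)
#' @param constants a [ConstantsSet-class] used for the truth bookkeeping
#' @return a [SyntheticCommunity-class]
#' @export
generateSamples <- function(world, n_samples, protocol = c("nonAMP", "AMP"),
                            constants = defaultConstants()) {
  stopifnot(is(world, "WorldTruth"))
  validObject(world)
  protocol <- match.arg(protocol)
  if (n_samples < 1) stop("n_samples must be >= 1")
  set.seed(world@seed)
  layout <- .communityLayout(world)

  l16 <- constants@len_16s_nt
  l18 <- constants@len_18s_nt
  ssu_frac <- ssuMassFraction(constants)
  rate <- transcriptsPerNg(constants, "exact")
  soil_dw <- world@soil_fresh_g * world@dry_matter_fraction
  s_ret <- if (is.na(world@spike_retention)) world@retention
           else world@spike_retention
  sdlog <- sqrt(log(1 + world@rna_cv^2))

  profiles <- vector("list", n_samples)
  meta <- truth <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    id <- sprintf("synth_%03d", i)
    true_total <- world@true_total_rna_ng_per_g_dw *
      stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    comm_true_ng <- true_total * soil_dw
    comm_ext <- comm_true_ng * world@retention
    spike_ext <- world@spike_ng * s_ret
    extracted <- comm_ext + spike_ext

    ## molecule (read) weights: extracted SSU mass / length per taxon
    len <- ifelse(layout$is_euk, l18, l16)
    w_comm <- comm_ext * layout$mass_share / len
    w_spike <- spike_ext / l16
    prob <- c(w_spike, w_comm) / (w_spike + sum(w_comm))

    if (protocol == "AMP") {
      ## spike shift is defined relative to the nonAMP expectation, so it is
      ## applied to the pre-enrichment spike probability
      p_new <- min(prob[1] + world@amp_bias_pp / 100, 0.999)
      comm_p <- prob[-1]
      comm_p[layout$is_euk] <- comm_p[layout$is_euk] * world@amp_euk_enrichment
      prob <- c(p_new, comm_p / sum(comm_p) * (1 - p_new))
    }
    expected_spike_pct <- 100 * prob[1]

    counts <- stats::rmultinom(1, world@depth, prob)[, 1]
    keep <- counts > 0
    profiles[[i]] <- new("TaxonProfile", sample_id = id, protocol = protocol,
                         fraction = "SSU",
                         lineages = c(.SPIKE_LINEAGE, layout$lineages)[keep],
                         counts = counts[keep],
                         total_reads = sum(counts))

    ## synthetic qRT-PCR on the extract (community 16S only; the < 1% spike
    ## contribution to the 16S pool is neglected)
    ext_16s_ng <- comm_ext * ssu_frac * layout$pmf
    detected <- ext_16s_ng * rate * world@qpcr_detection_efficiency
    copies_template <- detected / (.QPCR_EXTRACT_VOLUME_UL * .QPCR_DILUTION)
    cq <- .QPCR_INTERCEPT + .QPCR_SLOPE * log10(copies_template)

    meta[[i]] <- data.frame(
      sample_id = id, extracted_rna_ng = extracted,
      spike_ng = world@spike_ng, soil_fresh_g = world@soil_fresh_g,
      dry_matter_fraction = world@dry_matter_fraction,
      dilution_factor = .QPCR_DILUTION,
      extract_volume_ul = .QPCR_EXTRACT_VOLUME_UL,
      protocol = protocol, cq = cq, stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      sample_id = id,
      true_total_rna_ng_per_g_dw = true_total,
      extracted_rna_ng = extracted,
      community_extracted_ng = comm_ext,
      spike_extracted_ng = spike_ext,
      retention = world@retention,
      spike_retention = s_ret,
      prok_mass_fraction = layout$pmf,
      expected_spike_pct = expected_spike_pct,
      true_transcripts_per_g_dw = true_total * ssu_frac * layout$pmf * rate,
      qpcr_true_transcripts_per_g_dw = detected / soil_dw,
      stringsAsFactors = FALSE)
  }
  new("SyntheticCommunity", world = world, profiles = profiles,
      metadata = do.call(rbind, meta), truth = do.call(rbind, truth))
}

#' Estimator recovery across a grid of retention fractions
#'
#' The central parameter-recovery experiment: for each retention fraction,
#' generate samples, run the spike-in (NAE_std) and extracted-mass (qMeTra)
#' estimators through [splitSpike()], [naestdTotalRNA()] and
#' [qmetraTranscripts()], and report each estimate against the recorded
#' ground truth. With spike retention coupled to community retention, the
#' spike-in estimate of the true total RNA is invariant in the retention
#' fraction, while the qMeTra estimate is proportional to it.
#'
#' @param world a [WorldTruth-class] template (its `retention` is replaced
#'   by the grid values; per-grid-point seeds are derived from `seed`)
#' @param retentions retention fractions to scan
#' @param n_samples samples per retention
#' @param seed base seed for the experiment
#' @param constants a [ConstantsSet-class]
#' @return data.frame with one row per sample: `retention`, `sample_id`,
#'   the spike-in total-RNA estimate and its relative error, and the qMeTra
#'   transcript estimate with its ratio to truth
#' @export
recoveryExperiment <- function(world = WorldTruth(),
                               retentions = seq(0.1, 1, by = 0.1),
                               n_samples = 6, seed = world@seed,
                               constants = defaultConstants()) {
  if (!length(retentions)) stop("retention grid must be non-empty")
  rows <- list()
  for (k in seq_along(retentions)) {
    r <- retentions[k]
    w <- world
    w@retention <- r
    w@seed <- (seed * 131 + k) %% .Machine$integer.max
    gen <- generateSamples(w, n_samples, constants = constants)
    est <- estimateFromSynthetic(gen, constants = constants)
    est$retention <- r
    rows[[k]] <- est
  }
  out <- do.call(rbind, rows)
  out[, c("retention", setdiff(names(out), "retention"))]
}

#' Run the spike-in and extracted-mass estimators on generated samples
#'
#' @param community a [SyntheticCommunity-class]
#' @param constants a [ConstantsSet-class]
#' @return data.frame with per-sample estimates and truth columns
#' @export
estimateFromSynthetic <- function(community,
                                  constants = defaultConstants()) {
  stopifnot(is(community, "SyntheticCommunity"))
  meta <- community@metadata
  truth <- community@truth
  soil_dw <- meta$soil_fresh_g * meta$dry_matter_fraction
  rows <- lapply(seq_along(community@profiles), function(i) {
    prof <- community@profiles[[i]]
    acc <- splitSpike(prof)
    pct <- spikeAbundance(acc)
    clean <- profileWithoutSpike(acc)
    dom <- relativeAbundance(clean, "domain")
    prok_frac <- sum(dom[names(dom) != "Eukaryota"])
    naestd_total <- if (pct > 0)
      naestdTotalRNA(meta$spike_ng[i], pct) else NA_real_
    qm <- qmetraTranscripts(
      meta$extracted_rna_ng[i], meta$soil_fresh_g[i],
      meta$dry_matter_fraction[i], prok_frac, constants,
      sample_id = sampleId(prof),
      spike_ng_in_extract = meta$extracted_rna_ng[i] * pct / 100)
    data.frame(
      sample_id = sampleId(prof),
      spike_abundance_pct = pct,
      prok_count_fraction = prok_frac,
      naestd_total_rna_ng_per_g_dw = naestd_total / soil_dw[i],
      true_total_rna_ng_per_g_dw = truth$true_total_rna_ng_per_g_dw[i],
      naestd_rel_error = naestd_total / soil_dw[i] /
        truth$true_total_rna_ng_per_g_dw[i] - 1,
      qmetra_transcripts_per_g_dw = qm$transcripts_per_g_dw,
      true_transcripts_per_g_dw = truth$true_transcripts_per_g_dw[i],
      qmetra_truth_ratio = qm$transcripts_per_g_dw /
        truth$true_transcripts_per_g_dw[i],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
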