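#' @include spike.R
NULL

#' Construct a MockDesign
#'
#' @param n_sources number of source datasets (default 8)
#' @param spike_levels spike read proportions (default 10%, 1%, 0.1%)
#' @param include_controls add one unspiked control per source
#' @param reads_per_mock reads per mock (default 5e6; scale down for quick
#'   experiments)
#' @param subsample_per_source reads subsampled per source pool
#' @param seed RNG seed
#' @return a [MockDesign-class]
#' @examples
#' nMocks(MockDesign()) # 32
#' @export
MockDesign <- function(n_sources = 8, spike_levels = c(0.10, 0.01, 0.001),
                       include_controls = TRUE, reads_per_mock = 5e6,
                       subsample_per_source = 2e5, seed = 1) {
  new("MockDesign", n_sources = n_sources, spike_levels = spike_levels,
      include_controls = include_controls, reads_per_mock = reads_per_mock,
      subsample_per_source = subsample_per_source, seed = seed)
}

## multivariate hypergeometric draw: k reads without replacement from a pool
## of per-taxon counts. Sequential conditional hypergeometric draws.
.rmvhyper <- function(counts, k) {
  counts <- round(counts)
  total <- sum(counts)
  if (k > total)
    stop(sprintf("requested %d reads but the pool holds only %d", k, total))
  out <- numeric(length(counts))
  remaining_pool <- total
  remaining_draw <- k
  for (i in seq_along(counts)) {
    if (remaining_draw == 0) break
    remaining_pool <- remaining_pool - counts[i]
    if (remaining_pool == 0) {
      out[i] <- remaining_draw
      remaining_draw <- 0
      break
    }
    x <- stats::rhyper(1, counts[i], remaining_pool, remaining_draw)
    out[i] <- x
    remaining_draw <- remaining_draw - x
  }
  out
}

.poolCounts <- function(pool, what) {
  if (is(pool, "TaxonProfile")) pool <- taxonCounts(pool)
  if (is.null(names(pool)) || any(!nzchar(names(pool))))
    stop(what, " pool must be a lineage-named count vector or TaxonProfile")
  if (any(pool < 0) || any(pool != round(pool)))
    stop(what, " pool counts must be whole and non-negative")
  pool
}

#' Build in-silico mock samples from labelled read pools
#'
#' Each mock draws `round(level * reads_per_mock)` spike reads and the
#' remainder community reads without replacement (multivariate
#' hypergeometric, mirroring subsampling of finite read sets) from
#' per-source subsamples of the two pools. Ground-truth origin labels are
#' retained alongside the assigned lineages, so downstream evaluation can
#' score the spike-removal rules exactly.
#'
#' @param community_pool lineage-named count vector (or
#'   [TaxonProfile-class]) of natural-community reads
#' @param spike_pool same, for the spike organism's reads
#' @param design a [MockDesign-class]
#' @return a [MockExperiment-class]
#' @export
buildMocks <- function(community_pool, spike_pool, design = MockDesign()) {
  stopifnot(is(design, "MockDesign"))
  community_pool <- .poolCounts(community_pool, "community")
  spike_pool <- .poolCounts(spike_pool, "spike")
  set.seed(design@seed)

  levels <- design@spike_levels
  if (design@include_controls) levels <- c(levels, 0)
  samples <- list()
  ids <- character()
  lvl_out <- numeric()
  for (src in seq_len(design@n_sources)) {
    ## per-source subsample emulating the fixed-size subsampling step
    src_comm <- .rmvhyper(community_pool,
                          min(design@subsample_per_source,
                              sum(community_pool)))
    names(src_comm) <- names(community_pool)
    for (lvl in levels) {
      n_spike <- round(lvl * design@reads_per_mock)
      n_comm <- design@reads_per_mock - n_spike
      if (n_spike > sum(spike_pool))
        stop(sprintf("spike pool too small: need %d reads, have %d",
                     n_spike, sum(spike_pool)))
      ## community reads come from the per-source subsample: without
      ## replacement while it is deep enough, otherwise by multinomial
      ## resampling of its composition up to the requested depth
      comm_prob <- src_comm[src_comm > 0]
      comm_counts <- if (n_comm == 0) {
        structure(numeric(length(comm_prob)), names = names(comm_prob))
      } else if (n_comm <= sum(comm_prob)) {
        x <- .rmvhyper(comm_prob, n_comm)
        names(x) <- names(comm_prob)
        x
      } else {
        stats::rmultinom(1, n_comm, comm_prob)[, 1]
      }
      spike_counts <- .rmvhyper(spike_pool, n_spike)
      names(spike_counts) <- names(spike_pool)
      df <- rbind(
        data.frame(lineage = names(comm_counts),
                   origin = "community",
                   count = as.numeric(comm_counts),
                   stringsAsFactors = FALSE),
        data.frame(lineage = names(spike_counts),
                   origin = "spike",
                   count = as.numeric(spike_counts),
                   stringsAsFactors = FALSE))
      df <- df[df$count > 0, , drop = FALSE]
      rownames(df) <- NULL
      id <- sprintf("mock_src%d_lvl%g", src, lvl)
      samples[[id]] <- df
      ids <- c(ids, id)
      lvl_out <- c(lvl_out, lvl)
    }
  }
  new("MockExperiment", design = design, samples = samples,
      mock_id = ids, spike_level = lvl_out)
}

#' Confusion-model classifiers for mock evaluation
#'
#' Read classification is simulated at the count level: a classifier maps a
#' labelled (lineage, origin, count) table to the same table with possibly
#' reassigned lineages. `identityClassifier()` assigns every read its true
#' lineage. `mislabelClassifier(rate, target, origin)` draws, per row of the
#' chosen origin, a binomial number of reads (probability `rate`) and
#' reassigns them to `target` - e.g. spike reads escaping into a family the
#' removal rules do not touch.
#'
#' @param rate per-read mislabelling probability
#' @param target lineage string receiving the mislabelled reads
#' @param origin which ground-truth origin to perturb (`"spike"` or
#'   `"community"`)
#' @return a function of a mock data.frame, usable in [evaluateRecovery()]
#' @export
identityClassifier <- function() function(mock) mock

#' @rdname identityClassifier
#' @export
mislabelClassifier <- function(rate,
                               target = "Bacteria;Bacillota;Bacilli;Bacillales;Bacillaceae;Bacillus",
                               origin = "spike") {
  stopifnot(rate >= 0, rate <= 1)
  force(target); force(origin)
  function(mock) {
    idx <- which(mock$origin == origin & mock$count > 0)
    moved_rows <- NULL
    for (i in idx) {
      n <- stats::rbinom(1, mock$count[i], rate)
      if (n > 0) {
        mock$count[i] <- mock$count[i] - n
        moved_rows <- rbind(moved_rows, data.frame(
          lineage = target, origin = mock$origin[i], count = n,
          stringsAsFactors = FALSE))
      }
    }
    if (!is.null(moved_rows)) mock <- rbind(mock, moved_rows)
    mock
  }
}

#' Evaluate spike recovery, community loss and contamination on mocks
#'
#' Applies the classifier to each mock, runs the spike-removal rules on the
#' assigned lineages, and scores against the ground-truth origins:
#' * recovery - removed true-spike reads / all true-spike reads
#' * loss - removed true-community reads / all true-community reads
#' * contamination - surviving true-spike reads / all true-spike reads
#'
#' Recovery and contamination sum to 1 exactly. For unspiked controls the
#' spike-based fractions are `NA`.
#'
#' @param mocks a [MockExperiment-class]
#' @param spikedef a [SpikeDefinition-class]
#' @param classifier a confusion-model function, see [identityClassifier()]
#' @param seed optional seed for a stochastic classifier
#' @return data.frame with one row per mock: `mock_id`, `spike_level`,
#'   `spike_reads`, `community_reads`, `recovery`, `loss`, `contamination`
#' @export
evaluateRecovery <- function(mocks, spikedef = defaultSpikeDefinition(),
                             classifier = identityClassifier(),
                             seed = NULL) {
  stopifnot(is(mocks, "MockExperiment"))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_along(mocks@samples), function(i) {
    mock <- classifier(mocks@samples[[i]])
    removed <- .matchRules(mock$lineage, spikedef@ssu_rules)
    spike_total <- sum(mock$count[mock$origin == "spike"])
    comm_total <- sum(mock$count[mock$origin == "community"])
    spike_removed <- sum(mock$count[removed & mock$origin == "spike"])
    comm_removed <- sum(mock$count[removed & mock$origin == "community"])
    data.frame(
      mock_id = mocks@mock_id[i], spike_level = mocks@spike_level[i],
      spike_reads = spike_total, community_reads = comm_total,
      recovery = if (spike_total > 0) spike_removed / spike_total else NA_real_,
      loss = if (comm_total > 0) comm_removed / comm_total else NA_real_,
      contamination = if (spike_total > 0)
        (spike_total - spike_removed) / spike_total else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
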