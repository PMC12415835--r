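#' @include AllGenerics.R
NULL

#' Lineage parsing helpers
#'
#' Lineages are SILVA-style semicolon-delimited strings with positional
#' ranks domain; phylum; class; order; family; genus. `lineageRanks()`
#' splits and trims; `rankLabel()` extracts the label at a named rank
#' (`NA` when the lineage is not resolved that deep). Matching is
#' case-sensitive and exact.
#'
#' @param lineage character vector of lineage strings
#' @param rank one of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`
#' @return `lineageRanks()`: list of character vectors; `rankLabel()`:
#'   character vector of labels (or `NA`)
#' @examples
#' rankLabel("Bacteria;Firmicutes;Bacilli", "class")
#' @export
lineageRanks <- function(lineage) {
  lapply(strsplit(lineage, ";", fixed = TRUE), function(p) {
    p <- trimws(p)
    p[nzchar(p)]
  })
}

#' @rdname lineageRanks
#' @export
rankLabel <- function(lineage, rank) {
  rank <- match.arg(rank, names(.LINEAGE_RANKS))
  pos <- .LINEAGE_RANKS[[rank]]
  vapply(lineageRanks(lineage), function(p)
    if (length(p) >= pos) p[[pos]] else NA_character_, "")
}

#' Construct a TaxonProfile
#'
#' Duplicate lineages are summed (with one warning per duplicate), counts
#' are validated as whole and non-negative, and the read total is recorded.
#'
#' @param counts numeric vector of read counts; either named by lineage or
#'   accompanied by `lineages`
#' @param lineages character vector of lineage strings (optional when
#'   `counts` is named)
#' @param sample_id sample identifier
#' @param protocol library protocol: `"AMP"`, `"nonAMP"` or `"unknown"`
#' @param fraction `"SSU"` (default) or `"nonrRNA"`
#' @return a validated [TaxonProfile-class]
#' @examples
#' TaxonProfile(c("Bacteria;Firmicutes" = 10, "Archaea;Crenarchaeota" = 5),
#'              sample_id = "s1")
#' @export
TaxonProfile <- function(counts, lineages = names(counts), sample_id = "sample",
                         protocol = "unknown", fraction = "SSU") {
  if (is.null(lineages) && length(counts))
    stop("lineages are required (as names of 'counts' or explicitly)")
  if (length(lineages) != length(counts))
    stop("'lineages' and 'counts' must have equal length")
  counts <- as.numeric(counts)
  if (anyNA(counts)) stop("counts must not contain NA")
  lineages <- as.character(lineages)
  dup <- unique(lineages[duplicated(lineages)])
  if (length(dup)) {
    for (d in dup)
      warning("duplicate lineage merged: ", d, call. = FALSE)
    counts <- vapply(split(counts, factor(lineages, levels = unique(lineages))),
                     sum, numeric(1))
    lineages <- unique(lineages)
  }
  new("TaxonProfile", sample_id = as.character(sample_id),
      protocol = match.arg(protocol, .PROTOCOLS),
      fraction = match.arg(fraction, .FRACTIONS),
      lineages = unname(lineages), counts = unname(counts),
      total_reads = sum(counts))
}

.readDelim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a taxon count table from TSV/CSV
#'
#' Expects a header row and columns `lineage` and `count` (tab- or
#' comma-separated, detected from the header). Counts must parse as
#' non-negative whole numbers; duplicate lineages are summed with a warning.
#'
#' @param path file path
#' @param fraction `"SSU"` or `"nonrRNA"`
#' @param sample_id sample identifier; defaults to the file name
#' @param protocol library protocol label
#' @return a [TaxonProfile-class]
#' @export
readTaxonProfile <- function(path, fraction = "SSU",
                             sample_id = sub("\\.[^.]*$", "", basename(path)),
                             protocol = "unknown") {
  if (!file.exists(path)) stop("profile file not found: ", path)
  tab <- .readDelim(path)
  need <- c("lineage", "count")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("profile table ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  cnt <- suppressWarnings(as.numeric(tab$count))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad))
    stop("invalid count in row ", bad[1], " of ", path,
         " (value: ", tab$count[bad[1]], ")")
  TaxonProfile(cnt, lineages = tab$lineage, sample_id = sample_id,
               protocol = protocol, fraction = fraction)
}

#' Read a sample metadata table
#'
#' Required columns: `sample_id`, `extracted_rna_ng`, `spike_ng`,
#' `soil_fresh_g`, `dry_matter_fraction`; `dilution_factor` is optional and
#' defaults to 100 (qRT-PCR template dilution). Basic range checks are
#' applied per row.
#'
#' @param path TSV/CSV file path
#' @return a data.frame, one row per sample
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  tab <- .readDelim(path)
  need <- c("sample_id", "extracted_rna_ng", "spike_ng", "soil_fresh_g",
            "dry_matter_fraction")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("metadata table lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (!"dilution_factor" %in% names(tab)) tab$dilution_factor <- 100
  validateSampleMetadata(tab)
}

#' @rdname readSampleMetadata
#' @param meta a metadata data.frame to validate
#' @export
validateSampleMetadata <- function(meta) {
  stopifnot(is.data.frame(meta))
  chk <- function(cond, what) {
    bad <- which(!cond)
    if (length(bad))
      stop("invalid metadata (", what, ") for sample(s): ",
           paste(meta$sample_id[bad], collapse = ", "))
  }
  chk(meta$extracted_rna_ng >= 0, "extracted_rna_ng must be >= 0")
  chk(meta$spike_ng >= 0, "spike_ng must be >= 0")
  chk(meta$soil_fresh_g > 0, "soil_fresh_g must be > 0")
  chk(meta$dry_matter_fraction > 0 & meta$dry_matter_fraction <= 1,
      "dry_matter_fraction must lie in (0, 1]")
  chk(meta$dilution_factor > 0, "dilution_factor must be > 0")
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  meta
}

#' Write a results table as TSV
#'
#' Deterministic column order (as given), full numeric precision (values
#' survive a write/read round trip bit-exactly for integers and to full
#' double precision otherwise), and `NA` for missing cells.
#'
#' @param table a data.frame
#' @param path output file path
#' @return the path, invisibly
#' @export
writeResultsTable <- function(table, path) {
  if (is.null(table)) stop("table must not be NULL")
  stopifnot(is.data.frame(table))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  num <- vapply(table, is.numeric, TRUE)
  out <- table
  out[num] <- lapply(table[num], function(x)
    ifelse(is.na(x), NA, format(x, digits = 17, trim = TRUE,
                                scientific = NA)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  .readDelim(path)
}

#' Write a TaxonProfile to TSV
#'
#' Emits the two-column `lineage` / `count` format [readTaxonProfile()]
#' reads, in the profile's taxon order.
#'
#' @param profile a [TaxonProfile-class]
#' @param path output file path
#' @return the path, invisibly
#' @export
writeTaxonProfile <- function(profile, path) {
  stopifnot(is(profile, "TaxonProfile"))
  writeResultsTable(
    data.frame(lineage = profile@lineages, count = profile@counts,
               stringsAsFactors = FALSE),
    path)
}

#' @rdname relativeAbundance
setMethod("relativeAbundance", "TaxonProfile", function(profile, at_rank = NULL) {
  if (profile@total_reads == 0)
    stop("relative abundance is undefined for an empty profile (0 reads)")
  if (is.null(at_rank)) {
    ab <- profile@counts / profile@total_reads
    names(ab) <- profile@lineages
    return(ab)
  }
  key <- rankLabel(profile@lineages, at_rank)
  key[is.na(key)] <- "unclassified"
  pooled <- vapply(split(profile@counts, key), sum, numeric(1))
  pooled / profile@total_reads
})
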