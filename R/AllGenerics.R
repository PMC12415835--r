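#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor family for the package's S4 containers. Use these rather
#' than `@` slot access.
#'
#' @param object an S4 object from this package
#' @param ... passed to methods
#' @return the corresponding slot value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object, ...) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("totalReads", function(object, ...) standardGeneric("totalReads"))

#' @rdname accessors
#' @export
setGeneric("taxonCounts", function(object, ...) standardGeneric("taxonCounts"))

#' @rdname accessors
#' @export
setGeneric("libraryProtocol",
           function(object, ...) standardGeneric("libraryProtocol"))

#' @rdname accessors
#' @export
setGeneric("rnaFraction", function(object, ...) standardGeneric("rnaFraction"))

#' @rdname accessors
#' @export
setGeneric("spikeReads", function(object, ...) standardGeneric("spikeReads"))

#' @rdname accessors
#' @export
setGeneric("spikeAbundance",
           function(object, ...) standardGeneric("spikeAbundance"))

#' @rdname accessors
#' @export
setGeneric("profileWithoutSpike",
           function(object, ...) standardGeneric("profileWithoutSpike"))

#' @rdname accessors
#' @export
setGeneric("curveAccepted",
           function(object, ...) standardGeneric("curveAccepted"))

#' @rdname accessors
#' @export
setGeneric("curveEfficiency",
           function(object, ...) standardGeneric("curveEfficiency"))

#' @rdname accessors
#' @export
setGeneric("nMocks", function(object, ...) standardGeneric("nMocks"))

#' @rdname accessors
#' @export
setGeneric("worldTruth", function(object, ...) standardGeneric("worldTruth"))

#' @rdname accessors
#' @export
setGeneric("sampleMetadata",
           function(object, ...) standardGeneric("sampleMetadata"))

#' @rdname accessors
#' @export
setGeneric("sampleTruth", function(object, ...) standardGeneric("sampleTruth"))

#' @rdname accessors
#' @export
setGeneric("sampleProfiles",
           function(object, ...) standardGeneric("sampleProfiles"))

#' Relative abundances of a taxon profile
#'
#' @param profile a [TaxonProfile-class]
#' @param at_rank optional rank label (`"domain"` ... `"genus"`); when given,
#'   lineages are pooled by their label at that rank and lineages lacking the
#'   rank pool into `"unclassified"`
#' @return named numeric vector of fractions summing to 1
#' @export
setGeneric("relativeAbundance",
           function(profile, at_rank = NULL) standardGeneric("relativeAbundance"))

#' Identify and remove internal-standard reads from a profile
#'
#' @param profile a [TaxonProfile-class]
#' @param spikedef a [SpikeDefinition-class]; defaults to
#'   [defaultSpikeDefinition()]
#' @return a [SpikeAccounting-class]
#' @export
setGeneric("splitSpike",
           function(profile, spikedef = defaultSpikeDefinition())
             standardGeneric("splitSpike"))
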