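#' @include AllClasses.R
NULL

#' Construct a ConstantsSet
#'
#' Returns the default constants, with any named overrides applied. See
#' [ConstantsSet-class] for the meaning and default of each constant.
#'
#' @param ... named scalar overrides, e.g. `ribosomes_per_cell = 10000`
#' @return a validated [ConstantsSet-class]
#' @examples
#' defaultConstants()
#' ConstantsSet(cell_mass_g = 2e-13)
#' @export
ConstantsSet <- function(...) {
  overrides <- list(...)
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(!nzchar(nm)))
      stop("constants overrides must be named")
    unknown <- setdiff(nm, slotNames("ConstantsSet"))
    if (length(unknown))
      stop("unknown constants: ", paste(unknown, collapse = ", "))
  }
  do.call(new, c(list("ConstantsSet"), overrides))
}

#' @rdname ConstantsSet
#' @export
defaultConstants <- function() new("ConstantsSet")

#' Effective 16S rRNA molar mass
#'
#' The default is computed from the assumed 16S length and per-nucleotide
#' mass: `len_16s_nt * mass_per_nt_da + mass_triphosphate_da`
#' (1500 x 320.5 + 159 = 480,909 Da). If `molar_mass_16s_da` was set
#' explicitly in the constants it is returned unchanged, which is how the
#' commonly used rounded value of 4.5e5 Da can be selected.
#'
#' @param constants a [ConstantsSet-class]
#' @return molar mass in Da (g/mol)
#' @export
molarMass16S <- function(constants = defaultConstants()) {
  stopifnot(is(constants, "ConstantsSet"))
  mm <- constants@molar_mass_16s_da
  if (is.na(mm))
    mm <- constants@len_16s_nt * constants@mass_per_nt_da +
      constants@mass_triphosphate_da
  mm
}

#' Read constants overrides from a config file
#'
#' Accepts either a YAML mapping or a flat `key = value` / `key: value` text
#' file; keys must be slot names of [ConstantsSet-class]. Unknown keys are an
#' error so that typos cannot silently fall back to defaults.
#'
#' @param path path to the config file
#' @return a [ConstantsSet-class] with the overrides applied
#' @export
readConstants <- function(path) {
  if (!file.exists(path)) stop("constants file not found: ", path)
  vals <- tryCatch(yaml::read_yaml(path), error = function(e) NULL)
  if (!is.list(vals) || is.null(names(vals))) {
    ## flat key=value fallback
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    parts <- strsplit(lines, "[=:]", perl = TRUE)
    bad <- vapply(parts, length, 1L) < 2L
    if (any(bad)) stop("cannot parse constants line: ", lines[bad][1])
    vals <- lapply(parts, function(p)
      as.numeric(trimws(paste(p[-1], collapse = ":"))))
    names(vals) <- vapply(parts, function(p) trimws(p[1]), "")
  }
  vals <- lapply(vals, as.numeric)
  do.call(ConstantsSet, vals)
}
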