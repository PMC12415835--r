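#' @include constants.R quantify.R
NULL

#' Copy number of an in-vitro transcript standard
#'
#' Converts a measured RNA concentration into transcript copies per
#' microlitre: `concentration (g/uL) / (340 Da x fragment length) x
#' Avogadro`, i.e. mass over molar mass times molecules per mole.
#'
#' @param concentration_ng_ul measured concentration (ng / uL), > 0
#' @param fragment_len_nt transcript length (nt), > 0
#' @param constants a [ConstantsSet-class] (uses `qpcr_mass_per_nt_da` and
#'   `avogadro`)
#' @return copies per uL
#' @examples
#' standardCopiesPerUl(1, 1000) # 1.771e9
#' @export
standardCopiesPerUl <- function(concentration_ng_ul, fragment_len_nt,
                                constants = defaultConstants()) {
  if (any(concentration_ng_ul <= 0) || any(fragment_len_nt <= 0))
    stop("concentration and fragment length must be positive")
  concentration_ng_ul * 1e-9 /
    (constants@qpcr_mass_per_nt_da * fragment_len_nt) * constants@avogadro
}

#' Fit and qualify a qRT-PCR standard curve
#'
#' Least-squares fit of Cq on log10(copies). The amplification efficiency is
#' `10^(-1/slope) - 1`; a slope of -3.3219 (= -1/log10(2)) corresponds to
#' perfect doubling (efficiency 1.0). The curve is accepted when R-squared
#' lies within \[0.98, 1\] and efficiency within \[0.9, 1.10\]; rejected
#' curves refuse quantification in [sampleTranscriptsPerGram()].
#'
#' @param copies_per_ul copy numbers of the dilution series (>= 3 distinct
#'   values), or a data.frame with columns `copies_per_ul` and `cq`
#' @param cq measured quantification cycles (ignored when a data.frame is
#'   given)
#' @param r2_window,efficiency_window acceptance windows
#' @return a [QpcrStandard-class]
#' @examples
#' std <- fitStandardCurve(10^(2:8), 38 - 3.3219 * (2:8))
#' curveAccepted(std)
#' @export
fitStandardCurve <- function(copies_per_ul, cq = NULL,
                             r2_window = c(0.98, 1),
                             efficiency_window = c(0.9, 1.10)) {
  if (is.data.frame(copies_per_ul)) {
    cq <- copies_per_ul$cq
    copies_per_ul <- copies_per_ul$copies_per_ul
  }
  if (length(copies_per_ul) < 3L || length(unique(copies_per_ul)) < 3L)
    stop("standard curve needs >= 3 points with distinct copy numbers")
  if (length(cq) != length(copies_per_ul))
    stop("copies and cq must have equal length")
  if (any(copies_per_ul <= 0)) stop("copy numbers must be positive")
  lc <- log10(copies_per_ul)
  fit <- stats::lm(cq ~ lc)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ## computed directly (not via summary.lm) so that an exact dilution
  ## series does not trigger the perfect-fit warning
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  eff <- 10^(-1 / slope) - 1
  accepted <- is.finite(eff) &&
    r2 >= r2_window[1] && r2 <= r2_window[2] &&
    eff >= efficiency_window[1] && eff <= efficiency_window[2]
  new("QpcrStandard",
      points = data.frame(copies_per_ul = copies_per_ul, cq = cq),
      slope = slope, intercept = intercept, r_squared = r2,
      efficiency = eff, accepted = accepted)
}

#' Invert a standard curve at a sample Cq
#'
#' `copies = 10^((cq - intercept) / slope)` in the template, times the
#' dilution factor to get copies per uL of undiluted extract.
#'
#' @param cq sample quantification cycle(s)
#' @param std an accepted [QpcrStandard-class]
#' @param dilution_factor template dilution (default 100, i.e. 1:100)
#' @param strict if `TRUE`, Cq values outside the standard's range are an
#'   error; otherwise they are extrapolated with a warning
#' @return copies per uL of extract
#' @export
invertStandardCurve <- function(cq, std, dilution_factor = 100,
                                strict = FALSE) {
  stopifnot(is(std, "QpcrStandard"))
  if (!std@accepted)
    stop("standard curve was rejected (R^2 ", signif(std@r_squared, 4),
         ", efficiency ", signif(std@efficiency, 4),
         "); refusing quantification")
  rng <- range(std@points$cq)
  outside <- cq < rng[1] | cq > rng[2]
  if (any(outside)) {
    msg <- sprintf("%d Cq value(s) outside the standard range [%.2f, %.2f]",
                   sum(outside), rng[1], rng[2])
    if (strict) stop(msg, "; extrapolation disabled")
    warning(msg, "; extrapolating", call. = FALSE)
  }
  10^((cq - std@intercept) / std@slope) * dilution_factor
}

#' qRT-PCR 16S transcripts per gram dry soil
#'
#' Full per-sample chain: curve inversion at the sample Cq, scaling by the
#' template dilution, the extract elution volume (default 50 uL) and the
#' dry soil mass.
#'
#' @inheritParams invertStandardCurve
#' @param soil_fresh_g,dry_matter_fraction soil amounts (see [perGramDW()])
#' @param extract_volume_ul RNA extract elution volume (uL, default 50)
#' @param sample_id identifier carried into the result
#' @return one-row data.frame: `sample_id`, `method` (`"qRTPCR"`),
#'   `transcripts_per_g_dw`, plus `copies_per_ul_extract` and
#'   `copies_per_sample` intermediates
#' @export
sampleTranscriptsPerGram <- function(cq, std, soil_fresh_g,
                                     dry_matter_fraction,
                                     dilution_factor = 100,
                                     extract_volume_ul = 50,
                                     strict = FALSE, sample_id = "sample") {
  copies_ul <- invertStandardCurve(cq, std, dilution_factor, strict)
  copies_sample <- copies_ul * extract_volume_ul
  data.frame(
    sample_id = sample_id, method = "qRTPCR",
    transcripts_per_g_dw = perGramDW(copies_sample, soil_fresh_g,
                                     dry_matter_fraction),
    copies_per_ul_extract = copies_ul,
    copies_per_sample = copies_sample,
    cq = cq, stringsAsFactors = FALSE)
}
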