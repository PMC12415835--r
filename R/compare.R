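#' @include profiles-io.R
NULL

#' Bray-Curtis dissimilarity between two profiles
#'
#' Computed on relative abundances over the union of taxa, optionally after
#' pooling to a taxonomic rank: `BC = sum |x_i - y_i| / sum (x_i + y_i)`.
#' Identical profiles give 0, profiles sharing no taxa give 1. The actual
#' distance computation is delegated to [vegan::vegdist()].
#'
#' @param a,b [TaxonProfile-class] objects with at least one read each
#' @param rank optional rank label to pool at before comparison
#' @return dissimilarity in \[0, 1\]
#' @export
brayCurtis <- function(a, b, rank = NULL) {
  stopifnot(is(a, "TaxonProfile"), is(b, "TaxonProfile"))
  if (totalReads(a) == 0 || totalReads(b) == 0)
    stop("Bray-Curtis is undefined for an empty profile")
  ra <- relativeAbundance(a, rank)
  rb <- relativeAbundance(b, rank)
  taxa <- union(names(ra), names(rb))
  m <- rbind(ifelse(is.na(ra[taxa]), 0, ra[taxa]),
             ifelse(is.na(rb[taxa]), 0, rb[taxa]))
  as.numeric(vegan::vegdist(m, method = "bray"))
}

#' Pairwise Bray-Curtis matrix for a list of profiles
#'
#' @param profiles list of [TaxonProfile-class] objects
#' @param rank optional pooling rank
#' @return symmetric matrix with zero diagonal, dimnames from sample ids
#' @export
brayCurtisMatrix <- function(profiles, rank = NULL) {
  n <- length(profiles)
  ids <- vapply(profiles, sampleId, "")
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    m[i, j] <- m[j, i] <- brayCurtis(profiles[[i]], profiles[[j]], rank)
  }
  m
}

#' Cross-method correlation matrix
#'
#' Pearson correlations (with two-sided p-values) between per-sample
#' estimates of each method pair, computed pairwise-complete. With
#' `log_transform = TRUE` (the default) values are log10-transformed first,
#' matching the convention of log-log method comparisons; non-positive
#' values are dropped pairwise with a warning. A constant vector yields an
#' `NA` correlation flagged in the result rather than an error.
#'
#' @param estimates long data.frame with columns `sample_id`, `method` and
#'   a value column
#' @param value name of the value column (default
#'   `"transcripts_per_g_dw"`)
#' @param log_transform correlate log10 values
#' @return list with matrices `r`, `p`, `n`, and `flags` (character notes
#'   per degenerate pair)
#' @export
methodCorrelations <- function(estimates, value = "transcripts_per_g_dw",
                               log_transform = TRUE) {
  stopifnot(all(c("sample_id", "method", value) %in% names(estimates)))
  wide <- stats::reshape(
    estimates[, c("sample_id", "method", value)],
    idvar = "sample_id", timevar = "method", direction = "wide")
  methods <- sub(paste0("^", value, "\\."), "",
                 names(wide)[-1])
  x <- as.matrix(wide[, -1, drop = FALSE])
  colnames(x) <- methods
  if (log_transform) {
    if (any(x[is.finite(x)] <= 0))
      warning("non-positive values dropped before log10", call. = FALSE)
    x[x <= 0] <- NA
    x <- log10(x)
  }
  k <- length(methods)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(methods, methods))
  diag(r) <- 1; diag(p) <- 0
  flags <- character()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    ok <- stats::complete.cases(x[, i], x[, j])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < 3) { flags <- c(flags, sprintf(
      "%s~%s: fewer than 3 paired samples", methods[i], methods[j])); next }
    if (stats::sd(x[ok, i]) == 0 || stats::sd(x[ok, j]) == 0) {
      flags <- c(flags, sprintf("%s~%s: constant vector, correlation undefined",
                                methods[i], methods[j]))
      next
    }
    ct <- stats::cor.test(x[ok, i], x[ok, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  diag(n) <- colSums(is.finite(x))
  list(r = r, p = p, n = n, flags = flags)
}

#' Log-log regression slope between two methods
#'
#' Slope of `log10(y) ~ log10(x)` over paired positive values; a slope of 1
#' means the methods differ by a constant factor.
#'
#' @param x,y paired per-sample estimates (positive)
#' @return list with `slope`, `intercept`, `r_squared`, `n`
#' @export
logLogSlope <- function(x, y) {
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  if (sum(ok) < 3) stop("need at least 3 positive paired values")
  ly <- log10(y[ok])
  fit <- stats::lm(ly ~ log10(x[ok]))
  ss_tot <- sum((ly - mean(ly))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (ss_tot > 0)
         1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_,
       n = sum(ok))
}

#' Mean-ratio summary between two methods
#'
#' Summarises how far apart two estimate series lie: `k = mean(a) / mean(b)`
#' reported as a "1:k" relationship, and the detected fraction
#' `100 / k` percent rounded to one significant figure for display (the
#' ratio itself is computed from unrounded means). E.g. transcript means of
#' 1.4e12 vs 2.73e10 give roughly 1:51 and a detected fraction of ca. 2%.
#'
#' @param estimates_a,estimates_b numeric vectors of per-sample estimates
#' @return list with `k` (unrounded), `ratio_label` ("1:k", k rounded),
#'   `percent_detected` (1 significant figure), `percent_detected_exact`
#' @export
ratioSummary <- function(estimates_a, estimates_b) {
  ma <- mean(estimates_a, na.rm = TRUE)
  mb <- mean(estimates_b, na.rm = TRUE)
  if (!is.finite(ma) || !is.finite(mb) || ma == 0 || mb == 0)
    stop("ratio summary needs non-zero finite means")
  k <- ma / mb
  pct <- 100 / k
  list(k = k,
       ratio_label = sprintf("1:%g", round(k)),
       percent_detected = signif(pct, 1),
       percent_detected_exact = pct)
}

#' Dilution effect: spike abundance vs extracted RNA
#'
#' More extractable RNA dilutes a fixed spike mass, so the spike's relative
#' abundance is expected to correlate negatively with the amount of
#' extracted RNA. Pearson correlation with two-sided p-value; a constant
#' vector is flagged (`NA` correlation), not an error.
#'
#' @param spike_abundances_pct per-sample spike abundances (percent)
#' @param extracted_rna_ng per-sample extracted RNA (ng)
#' @return list with `r`, `p`, `n`, `flag`
#' @export
dilutionEffect <- function(spike_abundances_pct, extracted_rna_ng) {
  ok <- is.finite(spike_abundances_pct) & is.finite(extracted_rna_ng)
  if (sum(ok) < 3) stop("need at least 3 paired samples")
  a <- spike_abundances_pct[ok]; b <- extracted_rna_ng[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, n = sum(ok),
                flag = "constant vector, correlation undefined"))
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok), flag = "")
}

#' Per-method summary statistics
#'
#' @param estimates long data.frame with `method` and a value column
#' @param value name of the value column
#' @return data.frame with per-method mean, SD and median
#' @export
methodSummaries <- function(estimates, value = "transcripts_per_g_dw") {
  stopifnot(all(c("method", value) %in% names(estimates)))
  sp <- split(estimates[[value]], estimates$method)
  data.frame(
    method = names(sp),
    mean = vapply(sp, function(v) mean(v, na.rm = TRUE), numeric(1)),
    sd = vapply(sp, function(v) stats::sd(v, na.rm = TRUE), numeric(1)),
    median = vapply(sp, function(v) stats::median(v, na.rm = TRUE),
                    numeric(1)),
    n = vapply(sp, function(v) sum(is.finite(v)), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
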