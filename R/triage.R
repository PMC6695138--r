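# Confidence triage: allele balance, depth/AB confidence classes, and the
# low-allele-balance exclusion filter.

#' Triage thresholds
#'
#' Thresholds for the depth/allele-balance confidence criteria. A call is
#' high confidence when its depth is at least `min_depth` reads *and* its
#' allele balance at least `min_ab`; calls at or below `exclude_ab` are
#' removed in the stricter reporting mode. The defaults (100X, 0.40, 0.20)
#' are the criteria under which, in panel validation work of this kind,
#' every high-confidence call has been Sanger-confirmable.
#'
#' @param min_depth Minimum read depth for high confidence (reads).
#' @param min_ab Minimum allele balance for high confidence (proportion).
#' @param exclude_ab Exclusion boundary: calls with allele balance less than
#'   or equal to this proportion are dropped by [exclude_low_ab()].
#' @return A list of class `triage_thresholds`.
#' @export
triage_thresholds <- function(min_depth = 100, min_ab = 0.40, exclude_ab = 0.20) {
  if (!is_count(min_depth) || min_depth < 1)
    config_error("triage_thresholds: min_depth must be a count >= 1")
  if (!is_proportion(min_ab) || !is_proportion(exclude_ab))
    config_error("triage_thresholds: allele-balance thresholds must be proportions")
  if (!(exclude_ab < min_ab && min_ab < 1) || exclude_ab <= 0)
    config_error("triage_thresholds: need 0 < exclude_ab < min_ab < 1")
  structure(list(min_depth = min_depth, min_ab = min_ab,
                 exclude_ab = exclude_ab), class = "triage_thresholds")
}

#' Allele balance of a call
#'
#' The fraction of reads supporting the alternate allele,
#' `ad_alt / dp`: about 0.5 for a true heterozygote, 1.0 for a
#' homozygous-alternate call where the alternate allele is the only one
#' detected. Undefined (`NA`) at zero depth; such calls can never be
#' classified high confidence.
#'
#' @param ad_alt Alternate-allele read counts.
#' @param dp Total read depths.
#' @return Numeric proportions in `[0, 1]`, `NA` where `dp == 0`.
#' @export
allele_balance <- function(ad_alt, dp) {
  if (any(ad_alt < 0 | dp < 0, na.rm = TRUE) || any(ad_alt > dp, na.rm = TRUE))
    data_error("allele_balance: need 0 <= ad_alt <= dp")
  ifelse(dp == 0, NA_real_, ad_alt / dp)
}

#' Classify call confidence by depth and allele balance
#'
#' `"high"` iff `dp >= min_depth` and `ab >= min_ab` (both boundaries
#' inclusive), else `"low"`. A pure function of (depth, allele balance,
#' thresholds): raising either input can never demote a call.
#'
#' @param dp Total read depths.
#' @param ab Allele balances (see [allele_balance()]); `NA` yields `"low"`.
#' @param thresholds A [triage_thresholds()] object.
#' @return Character vector of `"high"` / `"low"`.
#' @export
classify_confidence <- function(dp, ab, thresholds = triage_thresholds()) {
  stopifnot(inherits(thresholds, "triage_thresholds"))
  high <- !is.na(ab) & dp >= thresholds$min_depth & ab >= thresholds$min_ab
  ifelse(high, "high", "low")
}

#' Compute allele balance and confidence for a call table
#'
#' Appends `ab` and `confidence` columns. The depth used is the call's own
#' reported depth (the VCF sample-field DP), not the locus average from the
#' coverage table: artifact calls sit at shallow depths even inside deeply
#' covered regions, and triage must see the call-level value.
#'
#' @param calls A call table with `dp` and `ad_alt` columns.
#' @param thresholds A [triage_thresholds()] object.
#' @return `calls` with added `ab` and `confidence` columns.
#' @export
triage_calls <- function(calls, thresholds = triage_thresholds()) {
  calls$ab <- allele_balance(calls$ad_alt, calls$dp)
  calls$confidence <- classify_confidence(calls$dp, calls$ab, thresholds)
  calls
}

#' Drop calls with low allele balance
#'
#' Keeps calls with allele balance strictly greater than the exclusion
#' boundary (a call exactly at `exclude_ab` is removed). Calls with
#' undefined allele balance are removed as well.
#'
#' @inheritParams triage_calls
#' @return The surviving subset of `calls`.
#' @export
exclude_low_ab <- function(calls, thresholds = triage_thresholds()) {
  stopifnot(inherits(thresholds, "triage_thresholds"))
  ab <- calls$ab %||% allele_balance(calls$ad_alt, calls$dp)
  calls[!is.na(ab) & ab > thresholds$exclude_ab, , drop = FALSE]
}
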