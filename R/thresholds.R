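#' Triage thresholds
#'
#' Bundles every tunable cutoff of the somatic/germline/CH decision procedure
#' and the cohort-level carrier-ratio filter. The defaults are the operating
#' point of the published pipeline this package implements: a candidate somatic
#' call in cfDNA needs depth >= 100x, >= 2 alt reads, VAF >= 0.3% and
#' population MAF <= 0.2%; a germline call needs PBL depth >= 30x and
#' PBL VAF >= 20%; a CH candidate needs Fisher p >= 0.05 with sample odds
#' ratio strictly inside (0.5, 1.5); recurrent candidates carried by more than
#' 0.25% of CH-positive patients are treated as technical artifacts.
#'
#' @param somatic_min_depth Minimum cfDNA depth for a somatic call.
#' @param min_alt_reads Minimum alt-supporting reads (cfDNA for somatic; both
#'   compartments for CH candidates).
#' @param somatic_min_vaf Minimum cfDNA VAF for a somatic call (fraction).
#' @param max_pop_maf Maximum population MAF (gnomAD/ExAC) for a somatic call.
#' @param germline_min_depth Minimum PBL depth to evaluate the germline/CH
#'   branches.
#' @param germline_min_vaf PBL VAF at or above which a call is germline.
#' @param ch_min_p Fisher two-sided p below which the paired counts are
#'   considered biased (not CH).
#' @param ch_or_low,ch_or_high Open odds-ratio window for CH candidates.
#' @param carrier_ratio_max Carrier-ratio ceiling; candidate CH variants
#'   carried by a larger fraction of CH-positive patients are removed.
#' @return An object of class `ch_thresholds` (a validated named list).
#' @examples
#' th <- ch_thresholds()
#' th$ch_min_p
#' @export
ch_thresholds <- function(somatic_min_depth = 100,
                          min_alt_reads = 2,
                          somatic_min_vaf = 0.003,
                          max_pop_maf = 0.002,
                          germline_min_depth = 30,
                          germline_min_vaf = 0.20,
                          ch_min_p = 0.05,
                          ch_or_low = 0.5,
                          ch_or_high = 1.5,
                          carrier_ratio_max = 0.0025) {
  th <- list(somatic_min_depth = somatic_min_depth,
             min_alt_reads = min_alt_reads,
             somatic_min_vaf = somatic_min_vaf,
             max_pop_maf = max_pop_maf,
             germline_min_depth = germline_min_depth,
             germline_min_vaf = germline_min_vaf,
             ch_min_p = ch_min_p,
             ch_or_low = ch_or_low,
             ch_or_high = ch_or_high,
             carrier_ratio_max = carrier_ratio_max)
  .stopifnot_scalar_number(th$somatic_min_depth, "somatic_min_depth", 0)
  .stopifnot_scalar_number(th$min_alt_reads, "min_alt_reads", 0)
  .stopifnot_scalar_number(th$somatic_min_vaf, "somatic_min_vaf", 0, 1)
  .stopifnot_scalar_number(th$max_pop_maf, "max_pop_maf", 0, 1)
  .stopifnot_scalar_number(th$germline_min_depth, "germline_min_depth", 0)
  .stopifnot_scalar_number(th$germline_min_vaf, "germline_min_vaf", 0, 1)
  .stopifnot_scalar_number(th$ch_min_p, "ch_min_p", 0, 1)
  .stopifnot_scalar_number(th$ch_or_low, "ch_or_low", 0)
  .stopifnot_scalar_number(th$ch_or_high, "ch_or_high", 0)
  .stopifnot_scalar_number(th$carrier_ratio_max, "carrier_ratio_max", 0, 1)
  if (!(th$ch_or_low < 1 && 1 < th$ch_or_high))
    stop("invalid odds-ratio window: need ch_or_low < 1 < ch_or_high")
  class(th) <- "ch_thresholds"
  th
}

#' @export
print.ch_thresholds <- function(x, ...) {
  cat("CH triage thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  invisible(x)
}
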