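# Per-patient triage of called variants into somatic / germline-pathogenic /
# candidate-CH / discard classes.
#
# Decision procedure, per variant, in order:
#   1. Not called in PBL -> candidate somatic; retained as SOMATIC iff cfDNA
#      depth >= 100x, alt reads >= 2, VAF >= 0.3%, population MAF <= 0.2%,
#      not (in dbSNP and not in COSMIC), not in the HLA locus.
#   2. PBL depth >= 30x and PBL VAF >= 20% -> germline; retained as
#      GERMLINE_PATHOGENIC iff ClinVar pathogenic/likely pathogenic.
#   3. PBL depth >= 30x and PBL VAF < 20% -> Fisher's exact test on
#      (cfDNA alt, cfDNA ref; PBL alt, PBL ref). p >= 0.05 with sample OR
#      strictly inside (0.5, 1.5) -> CANDIDATE_CH (needs >= 2 alt reads in
#      both compartments); p < 0.05 with OR > 1 -> candidate somatic, then the
#      branch-1 filters; any other outcome -> DISCORDANT_DISCARD.
#   4. PBL called but depth < 30x -> FILTERED("pbl_low_depth").
# dbSNP/COSMIC and HLA filters apply only to the somatic branch; boundary
# semantics are ">= " for "not smaller than" thresholds and strict "<" for
# "smaller than 20%".

#' Pre-filter called variants on annotation flags
#'
#' Removes blacklisted variants (annotation flag or BED membership) and
#' synonymous variants before triage, preserving order.
#'
#' @param variants Data.frame with `chrom,pos,ref,alt` columns.
#' @param annotations Annotation rows aligned to `variants`
#'   (see [annotation_for()]).
#' @param blacklist Optional `GRanges` from [read_blacklist()].
#' @return List with `kept` (row indices retained) and `removed` (data.frame
#'   of dropped row indices and the reason, `"blacklist"` or `"synonymous"`).
#' @export
prefilter <- function(variants, annotations, blacklist = NULL) {
  n <- nrow(variants)
  reason <- rep(NA_character_, n)
  in_bl <- annotations$in_blacklist
  if (!is.null(blacklist)) in_bl <- in_bl | is_blacklisted(variants, blacklist)
  reason[in_bl] <- "blacklist"
  syn <- is.na(reason) & annotations$consequence == "synonymous"
  reason[syn] <- "synonymous"
  list(kept = which(is.na(reason)),
       removed = data.frame(row = which(!is.na(reason)),
                            reason = reason[!is.na(reason)],
                            stringsAsFactors = FALSE))
}

# somatic-branch filters; returns character vector of failed-rule ids (empty = pass)
.somatic_reasons <- function(depth, alt, ann, th) {
  reasons <- character(0)
  if (depth == 0) return("zero_depth")
  if (depth < th$somatic_min_depth) reasons <- c(reasons, "somatic_low_depth")
  if (alt < th$min_alt_reads) reasons <- c(reasons, "somatic_min_alt")
  if (alt / depth < th$somatic_min_vaf) reasons <- c(reasons, "somatic_low_vaf")
  maf <- max(c(ann$maf_gnomad, ann$maf_exac), 0, na.rm = TRUE)
  if (maf > th$max_pop_maf) reasons <- c(reasons, "pop_maf")
  if (isTRUE(ann$in_dbsnp) && !isTRUE(ann$in_cosmic))
    reasons <- c(reasons, "dbsnp_not_cosmic")
  if (isTRUE(ann$is_hla)) reasons <- c(reasons, "hla")
  reasons
}

#' Classify one paired observation
#'
#' Applies the somatic/germline/CH decision procedure to a single variant of a
#' single patient. `pbl_depth`/`pbl_alt` of `NA` mean the variant was not
#' called in PBL (distinct from called with zero alt reads).
#'
#' @param cfdna_depth,cfdna_alt cfDNA total depth and alt-supporting reads.
#' @param pbl_depth,pbl_alt PBL counts, or `NA` if not called in PBL.
#' @param annotation One-row data.frame (or list) of annotation fields.
#' @param thresholds A [ch_thresholds()] object.
#' @return List with `label`, `p_value`, `odds_ratio`, `reasons` (character
#'   vector of rule identifiers that fired; non-empty for FILTERED and
#'   DISCORDANT_DISCARD).
#' @export
classify_variant <- function(cfdna_depth, cfdna_alt, pbl_depth = NA, pbl_alt = NA,
                             annotation = NULL, thresholds = ch_thresholds()) {
  th <- thresholds
  ann <- if (is.null(annotation)) annotation_for(data.frame(chrom = "chr1", pos = 1,
                                                            ref = "A", alt = "C"))[1, ]
         else annotation
  p <- NA_real_; or <- NA_real_

  if (is.na(pbl_depth)) {                              # branch 1: cfDNA only
    reasons <- .somatic_reasons(cfdna_depth, cfdna_alt, ann, th)
    if (length(reasons) == 0L)
      return(list(label = "SOMATIC", p_value = p, odds_ratio = or,
                  reasons = "somatic_pass"))
    return(list(label = "FILTERED", p_value = p, odds_ratio = or, reasons = reasons))
  }

  if (pbl_depth == 0)
    return(list(label = "FILTERED", p_value = p, odds_ratio = or,
                reasons = "zero_depth"))

  if (pbl_depth >= th$germline_min_depth &&
      pbl_alt / pbl_depth >= th$germline_min_vaf) {    # branch 2: germline
    if (ann$clinvar %in% c("pathogenic", "likely_pathogenic"))
      return(list(label = "GERMLINE_PATHOGENIC", p_value = p, odds_ratio = or,
                  reasons = "germline_pathogenic"))
    return(list(label = "FILTERED", p_value = p, odds_ratio = or,
                reasons = "germline_not_pathogenic"))
  }

  if (pbl_depth >= th$germline_min_depth) {            # branch 3: paired test
    if (cfdna_depth == 0)
      return(list(label = "FILTERED", p_value = p, odds_ratio = or,
                  reasons = "zero_depth"))
    po <- .fisher_p_or(cfdna_alt, cfdna_depth - cfdna_alt,
                       pbl_alt, pbl_depth - pbl_alt)
    p <- po[1L]; or <- po[2L]
    if (p >= th$ch_min_p && or > th$ch_or_low && or < th$ch_or_high) {
      if (cfdna_alt >= th$min_alt_reads && pbl_alt >= th$min_alt_reads)
        return(list(label = "CANDIDATE_CH", p_value = p, odds_ratio = or,
                    reasons = "ch_window"))
      return(list(label = "FILTERED", p_value = p, odds_ratio = or,
                  reasons = "ch_min_alt"))
    }
    if (p < th$ch_min_p && or > 1) {                   # cfDNA-enriched: somatic
      reasons <- .somatic_reasons(cfdna_depth, cfdna_alt, ann, th)
      if (length(reasons) == 0L)
        return(list(label = "SOMATIC", p_value = p, odds_ratio = or,
                    reasons = "somatic_pass"))
      return(list(label = "FILTERED", p_value = p, odds_ratio = or,
                  reasons = reasons))
    }
    reason <- if (p < th$ch_min_p) "pbl_enriched" else "or_outside_window"
    return(list(label = "DISCORDANT_DISCARD", p_value = p, odds_ratio = or,
                reasons = reason))
  }

  list(label = "FILTERED", p_value = p, odds_ratio = or,
       reasons = "pbl_low_depth")                      # branch 4: low PBL depth
}

#' Classify every observation of a cohort (or one patient)
#'
#' Applies [prefilter()] and then [classify_variant()] to each row of a wide
#' observation table. Output has exactly one row and one label per input row;
#' prefiltered variants appear as FILTERED records with their prefilter
#' reason. Deterministic: identical inputs and thresholds give identical
#' output.
#'
#' @param observations Data.frame with columns `patient_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `cfdna_depth`, `cfdna_alt`, and optionally `pbl_depth`,
#'   `pbl_alt` (`NA` = not called in PBL).
#' @param annotations Annotation table ([read_annotations()] layout) or NULL.
#' @param thresholds A [ch_thresholds()] object.
#' @param blacklist Optional `GRanges` blacklist.
#' @return Data.frame with columns `patient_id,chrom,pos,ref,alt,gene,label,
#'   p_value,odds_ratio,reasons` (reasons semicolon-joined).
#' @export
classify_cohort <- function(observations, annotations = NULL,
                            thresholds = ch_thresholds(), blacklist = NULL) {
  obs <- observations
  n <- nrow(obs)
  if (!"pbl_depth" %in% names(obs)) obs$pbl_depth <- NA_integer_
  if (!"pbl_alt" %in% names(obs)) obs$pbl_alt <- NA_integer_
  ann <- annotation_for(obs, annotations)
  out <- data.frame(patient_id = as.character(obs$patient_id),
                    chrom = obs$chrom, pos = obs$pos, ref = obs$ref, alt = obs$alt,
                    gene = ann$gene,
                    label = rep(NA_character_, n),
                    p_value = rep(NA_real_, n),
                    odds_ratio = rep(NA_real_, n),
                    reasons = rep("", n), stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  pf <- prefilter(obs, ann, blacklist)
  if (nrow(pf$removed) > 0L) {
    out$label[pf$removed$row] <- "FILTERED"
    out$reasons[pf$removed$row] <- pf$removed$reason
  }
  for (i in pf$kept) {
    res <- classify_variant(obs$cfdna_depth[i], obs$cfdna_alt[i],
                            obs$pbl_depth[i], obs$pbl_alt[i],
                            ann[i, ], thresholds)
    out$label[i] <- res$label
    out$p_value[i] <- res$p_value
    out$odds_ratio[i] <- res$odds_ratio
    out$reasons[i] <- paste(res$reasons, collapse = ";")
  }
  out
}

#' @describeIn classify_cohort Convenience wrapper for a single patient:
#'   `observations` need not carry a `patient_id` column.
#' @param patient_id Patient identifier used when `observations` lacks one.
#' @export
classify_patient <- function(observations, annotations = NULL,
                             thresholds = ch_thresholds(), blacklist = NULL,
                             patient_id = "patient") {
  if (!"patient_id" %in% names(observations))
    observations$patient_id <- patient_id
  classify_cohort(observations, annotations, thresholds, blacklist)
}
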