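# Internal helpers shared across modules.

KEY_COLS <- c("chrom", "pos", "ref", "alt")

CONSEQUENCE_LEVELS <- c("synonymous", "missense", "nonsense", "frameshift_indel",
                        "inframe_indel", "splice", "other")
CLINVAR_LEVELS <- c("pathogenic", "likely_pathogenic", "other", "none")

LABELS <- c("SOMATIC", "GERMLINE_PATHOGENIC", "CANDIDATE_CH", "CH",
            "DISCORDANT_DISCARD", "FILTERED")

#' Build the canonical string key for a variant
#'
#' A variant is identified by chromosome, 1-based position of the first
#' reference base, reference allele and alternate allele; two variants are the
#' same iff all four fields agree. The string form `chrom:pos:ref:alt` is used
#' internally for joins and grouping.
#'
#' @param chrom Chromosome names (character).
#' @param pos 1-based positions (integer, >= 1).
#' @param ref,alt Uppercase A/C/G/T allele strings, `ref != alt`.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

.df_key <- function(df) variant_key(df$chrom, df$pos, df$ref, df$alt)

.check_variant_fields <- function(df, where = "input") {
  miss <- setdiff(KEY_COLS, names(df))
  if (length(miss) > 0L)
    stop(sprintf("%s is missing column(s): %s", where, paste(miss, collapse = ", ")))
  pos <- df$pos
  if (any(is.na(pos)) || any(pos < 1) || any(pos != floor(pos)))
    stop(sprintf("%s: pos must be integer >= 1 (1-based)", where))
  bad_allele <- !grepl("^[ACGT]+$", df$ref) | !grepl("^[ACGT]+$", df$alt)
  if (any(bad_allele))
    stop(sprintf("%s: alleles must be non-empty uppercase A/C/G/T strings (first bad row %d)",
                 where, which(bad_allele)[1L]))
  same <- df$ref == df$alt
  if (any(same))
    stop(sprintf("%s: ref and alt must differ (first bad row %d)", where, which(same)[1L]))
  invisible(df)
}

.stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("invalid field '%s': must be a number in [%s, %s]", name, lo, hi))
  invisible(x)
}

# row-bind that tolerates a zero-row or NULL piece
.rbind_all <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0L, lst)
  if (length(lst) == 0L) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
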