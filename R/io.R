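# Readers and writers for the standard formats the pipeline touches.
# All variant tables are 1-based (VCF convention); BED input is converted at
# the boundary. Indel normalization (left-alignment) is NOT performed here:
# inputs are assumed consistently normalized by the upstream caller.

#' Read a per-sample variant call table
#'
#' Reads one compartment's calls as `(variant, depth, alt_reads)` records.
#' The TSV dialect has columns `chrom,pos,ref,alt,depth,alt_reads` (tab
#' separated, 1-based positions). For VCF input the per-sample `AD` allele
#' depths are used: each alternate allele of a multi-allelic record becomes
#' its own row, `alt_reads` being that allele's depth and `depth` the sum of
#' all allele depths of the record. Only called records are emitted -- a
#' variant absent from a compartment's table is "not called" there, which the
#' triage treats differently from "called with 0 alt reads".
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`.
#' @param sample For VCF input, the sample column to read (default: first).
#' @return A data.frame with columns `chrom,pos,ref,alt,depth,alt_reads`.
#' @export
read_calls <- function(path, format = c("tsv", "vcf"), sample = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "tsv") .read_calls_tsv(path) else .read_calls_vcf(path, sample)
}

.read_calls_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c(chrom = "character", ref = "character",
                                         alt = "character"),
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "depth", "alt_reads")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  df <- df[, need]
  if (nrow(df) == 0L) return(df)
  for (col in c("pos", "depth", "alt_reads")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) | v != floor(v) | v < 0
    if (any(bad))
      stop(sprintf("%s line %d: malformed %s", path, which(bad)[1L] + 1L, col))
    df[[col]] <- as.integer(v)
  }
  tryCatch(.check_variant_fields(df, path), error = function(e) stop(e$message))
  over <- df$alt_reads > df$depth
  if (any(over))
    stop(sprintf("%s line %d: alt_reads > depth", path, which(over)[1L] + 1L))
  df
}

.read_calls_vcf <- function(path, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  empty <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), depth = integer(0), alt_reads = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(fix) || nrow(v@gt) == 0L) return(empty)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1L]
  if (is.null(sample)) sample <- samples[1L]
  if (!sample %in% samples) stop(sprintf("sample '%s' not in VCF", sample))
  ad <- vcfR::extract.gt(v, element = "AD")[, sample]
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    if (is.na(ad[i])) stop(sprintf("%s record %d: missing AD field", path, i))
    depths <- suppressWarnings(as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1L]]))
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    if (anyNA(depths) || length(depths) != length(alts) + 1L)
      stop(sprintf("%s record %d: malformed AD field", path, i))
    out[[i]] <- data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
                           ref = fix$REF[i], alt = alts,
                           depth = sum(depths), alt_reads = depths[-1L],
                           stringsAsFactors = FALSE)
  }
  df <- .rbind_all(out)
  if (is.null(df)) return(empty)
  .check_variant_fields(df, path)
  df
}

#' Read a blacklist of genomic intervals (BED)
#'
#' BED intervals are 0-based half-open `[start, end)`; they are converted to
#' 1-based closed ranges in a [GenomicRanges::GRanges] at the boundary, so a
#' variant with 1-based position `p` is blacklisted iff `p - 1` falls inside an
#' interval on the same chromosome.
#'
#' @param path BED file path (first three columns used).
#' @return A `GRanges` holding the converted intervals.
#' @export
read_blacklist <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    return(GenomicRanges::GRanges())
  if (ncol(df) < 3L) stop(sprintf("%s: BED needs >= 3 columns", path))
  start0 <- as.numeric(df[[2L]]); end0 <- as.numeric(df[[3L]])
  if (anyNA(start0) || anyNA(end0)) stop(sprintf("%s: non-numeric BED coordinates", path))
  if (any(start0 >= end0)) stop(sprintf("%s: BED interval with start >= end", path))
  GenomicRanges::GRanges(seqnames = as.character(df[[1L]]),
                         ranges = IRanges::IRanges(start = start0 + 1, end = end0))
}

#' Test variants for blacklist membership
#'
#' @param variants Data.frame with `chrom` and 1-based `pos` columns.
#' @param blacklist A `GRanges` from [read_blacklist()].
#' @return Logical vector, one entry per row of `variants`.
#' @export
is_blacklisted <- function(variants, blacklist) {
  if (nrow(variants) == 0L) return(logical(0))
  if (length(blacklist) == 0L) return(rep(FALSE, nrow(variants)))
  q <- GenomicRanges::GRanges(seqnames = variants$chrom,
                              ranges = IRanges::IRanges(start = variants$pos,
                                                        width = 1L))
  GenomicRanges::countOverlaps(q, blacklist) > 0L
}

ANNOTATION_COLS <- c("gene", "consequence", "maf_gnomad", "maf_exac",
                     "in_dbsnp", "in_cosmic", "is_hla", "in_blacklist", "clinvar")

#' Read a per-variant annotation table
#'
#' TSV keyed by `chrom,pos,ref,alt` with columns `gene`, `consequence` (one of
#' synonymous/missense/nonsense/frameshift_indel/inframe_indel/splice/other),
#' `maf_gnomad`, `maf_exac` (population MAF in `[0,1]`, empty = unknown),
#' logical `in_dbsnp`, `in_cosmic`, `is_hla`, `in_blacklist`, and `clinvar`
#' (pathogenic/likely_pathogenic/other/none). Duplicate keys with identical
#' annotations are collapsed; conflicting duplicates are an error.
#'
#' @param path TSV file path.
#' @return Data.frame keyed by the four variant columns.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c(chrom = "character", ref = "character",
                                         alt = "character", gene = "character"),
                          stringsAsFactors = FALSE)
  need <- c(KEY_COLS, ANNOTATION_COLS)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  df <- df[, need]
  if (nrow(df) == 0L) return(df)
  .check_variant_fields(df, path)
  for (col in c("in_dbsnp", "in_cosmic", "is_hla", "in_blacklist"))
    df[[col]] <- as.logical(df[[col]])
  for (col in c("maf_gnomad", "maf_exac")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    ok <- is.na(df[[col]]) | (df[[col]] >= 0 & df[[col]] <= 1)
    if (!all(ok)) stop(sprintf("%s: %s outside [0,1]", path, col))
  }
  if (!all(df$consequence %in% CONSEQUENCE_LEVELS))
    stop(sprintf("%s: unknown consequence value", path))
  if (!all(df$clinvar %in% CLINVAR_LEVELS))
    stop(sprintf("%s: unknown clinvar value", path))
  key <- .df_key(df)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    for (k in dup) {
      rows <- df[key == k, ]
      if (nrow(unique(rows)) > 1L)
        stop(sprintf("%s: conflicting annotation rows for %s", path, k))
    }
    df <- df[!duplicated(key), ]
  }
  df
}

#' Resolve annotations for a set of variants
#'
#' Looks up each variant in an annotation table; unannotated variants receive
#' the default annotation (all flags `FALSE`, MAFs unknown, consequence
#' `"other"`, clinvar `"none"`). Unknown population MAF is treated as 0 by the
#' triage filters (novel variants are not common polymorphisms).
#'
#' @param variants Data.frame with the `chrom,pos,ref,alt` key columns.
#' @param annotations Table from [read_annotations()] (or equivalent), or NULL.
#' @return Data.frame of annotation columns aligned row-for-row to `variants`.
#' @export
annotation_for <- function(variants, annotations = NULL) {
  n <- nrow(variants)
  out <- data.frame(gene = rep(NA_character_, n),
                    consequence = rep("other", n),
                    maf_gnomad = rep(NA_real_, n),
                    maf_exac = rep(NA_real_, n),
                    in_dbsnp = rep(FALSE, n), in_cosmic = rep(FALSE, n),
                    is_hla = rep(FALSE, n), in_blacklist = rep(FALSE, n),
                    clinvar = rep("none", n), stringsAsFactors = FALSE)
  if (is.null(annotations) || nrow(annotations) == 0L || n == 0L) return(out)
  idx <- match(.df_key(variants), .df_key(annotations))
  hit <- !is.na(idx)
  out[hit, ANNOTATION_COLS] <- annotations[idx[hit], ANNOTATION_COLS]
  out
}

#' Read an actionable-mutation knowledge base
#'
#' TSV keyed by `chrom,pos,ref,alt` with `gene` and a free-text `assertion`
#' column (drug/assertion). Used for exact-match overlap with final CH calls.
#'
#' @param path TSV file path.
#' @return Data.frame with the key columns plus `gene` and `assertion`.
#' @export
read_knowledge_base <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c(chrom = "character", ref = "character",
                                         alt = "character"),
                          stringsAsFactors = FALSE)
  need <- c(KEY_COLS, "gene", "assertion")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  df <- df[, need]
  if (nrow(df) > 0L) .check_variant_fields(df, path)
  df
}

CLASSIFIED_COLS <- c("patient_id", "chrom", "pos", "ref", "alt", "gene",
                     "label", "p_value", "odds_ratio", "reasons")

#' Write / read classified-variant tables
#'
#' The classified TSV carries one row per (patient, variant) with the triage
#' label, the Fisher evidence when the paired test was run, and the
#' semicolon-joined rule identifiers that fired. Numeric columns are written
#' at full precision so that write-then-read is the identity on content.
#'
#' @param records Data.frame of classified variants.
#' @param path Output/input TSV path.
#' @return `write_classified` returns `path` invisibly; `read_classified`
#'   returns the data.frame.
#' @export
write_classified <- function(records, path) {
  df <- records[, intersect(CLASSIFIED_COLS, names(records))]
  for (col in c("p_value", "odds_ratio"))
    if (col %in% names(df))
      df[[col]] <- ifelse(is.na(df[[col]]), "", sprintf("%.17g", df[[col]]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_classified
#' @export
read_classified <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c(chrom = "character", ref = "character",
                                         alt = "character",
                                         patient_id = "character"),
                          stringsAsFactors = FALSE)
  for (col in c("p_value", "odds_ratio"))
    if (col %in% names(df)) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  if ("reasons" %in% names(df)) {
    df$reasons <- as.character(df$reasons)
    df$reasons[is.na(df$reasons)] <- ""
  }
  if ("gene" %in% names(df)) df$gene <- as.character(df$gene)
  df
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene symbols.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (unique gene symbols per set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop("malformed GMT line (need name, description, genes)")
    sets[[parts[1L]]] <- unique(parts[-(1:2)])
  }
  sets
}
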