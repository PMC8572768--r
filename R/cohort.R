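# Cohort-level analytics: the candidate-CH funnel (carrier ratio, tumor
# crosscheck), age-prevalence trend, gene summaries, preferred-class labels,
# two-cohort comparison, actionable-mutation interference, and generic
# gene-set over-representation.

#' Carrier ratio of candidate CH variants
#'
#' For every distinct candidate-CH variant, the fraction of CH-positive
#' patients (patients with at least one candidate CH call) that carry it.
#' The denominator is computed once on the candidate set and is not iterated
#' when variants are subsequently removed.
#'
#' @param candidates Data.frame of candidate CH rows with `patient_id` and the
#'   `chrom,pos,ref,alt` key columns (e.g. the `CANDIDATE_CH` rows of
#'   [classify_cohort()] output).
#' @return Data.frame `chrom,pos,ref,alt,carriers,ratio` (empty if no
#'   candidates), plus attribute `n_positive` (the denominator).
#' @export
carrier_ratio <- function(candidates) {
  if (nrow(candidates) == 0L) {
    out <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), carriers = integer(0), ratio = numeric(0))
    attr(out, "n_positive") <- 0L
    return(out)
  }
  n_pos <- length(unique(candidates$patient_id))
  key <- .df_key(candidates)
  carriers <- tapply(candidates$patient_id, key,
                     function(p) length(unique(p)))
  first <- candidates[!duplicated(key), KEY_COLS]
  first_key <- .df_key(first)
  out <- data.frame(first,
                    carriers = as.integer(carriers[first_key]),
                    ratio = as.numeric(carriers[first_key]) / n_pos,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_positive") <- n_pos
  out
}

#' Remove recurrent candidate CH variants by carrier ratio
#'
#' Variants whose carrier ratio strictly exceeds `thresholds$carrier_ratio_max`
#' are removed for every patient (recurrent candidates are treated as
#' technical artifacts); a ratio exactly at the ceiling is retained.
#'
#' @param candidates Candidate-CH rows (as for [carrier_ratio()]).
#' @param thresholds A [ch_thresholds()] object.
#' @return List: `kept` and `removed` row subsets of `candidates`,
#'   `removed_variants` (per-variant table with ratios), `retention` (fraction
#'   of candidate rows retained), `ratios` (the full [carrier_ratio()] table).
#' @export
filter_carrier_ratio <- function(candidates, thresholds = ch_thresholds()) {
  ratios <- carrier_ratio(candidates)
  if (nrow(candidates) == 0L)
    return(list(kept = candidates, removed = candidates,
                removed_variants = ratios, retention = NA_real_, ratios = ratios))
  bad_keys <- .df_key(ratios)[ratios$ratio > thresholds$carrier_ratio_max]
  is_bad <- .df_key(candidates) %in% bad_keys
  list(kept = candidates[!is_bad, , drop = FALSE],
       removed = candidates[is_bad, , drop = FALSE],
       removed_variants = ratios[.df_key(ratios) %in% bad_keys, , drop = FALSE],
       retention = mean(!is_bad),
       ratios = ratios)
}

#' Remove candidates called somatic in the matched tumor
#'
#' A candidate is removed for a patient iff the same variant appears among
#' that same patient's tumor somatic calls; candidates of patients without
#' tumor data (and matches in other patients' tumors) pass through.
#'
#' @param candidates Candidate-CH rows with `patient_id` + key columns.
#' @param tumor_calls Data.frame of per-patient tumor somatic calls
#'   (`patient_id` + key columns), or NULL for none.
#' @return List with `kept` and `removed` row subsets.
#' @export
tumor_crosscheck <- function(candidates, tumor_calls = NULL) {
  if (is.null(tumor_calls) || nrow(tumor_calls) == 0L || nrow(candidates) == 0L)
    return(list(kept = candidates, removed = candidates[0, , drop = FALSE]))
  cand_id <- paste(candidates$patient_id, .df_key(candidates), sep = "|")
  tum_id <- paste(tumor_calls$patient_id, .df_key(tumor_calls), sep = "|")
  hit <- cand_id %in% tum_id
  list(kept = candidates[!hit, , drop = FALSE],
       removed = candidates[hit, , drop = FALSE])
}

AGE_GROUP_LABELS <- c("<=40", "40-50", "50-60", "60-70", "70-80", "80-90", ">90")

#' Assign diagnostic ages to prevalence age groups
#'
#' Bins are right-closed: `[0,40]`, `(40,50]`, ..., `(80,90]`, `(90,Inf)`.
#'
#' @param age Ages in years (numeric, >= 0).
#' @return Factor with levels `r paste(AGE_GROUP_LABELS, collapse=", ")`.
#' @export
age_group <- function(age) {
  if (anyNA(age) || any(age < 0)) stop("ages must be non-negative")
  cut(age, breaks = c(-Inf, 40, 50, 60, 70, 80, 90, Inf),
      labels = AGE_GROUP_LABELS, right = TRUE)
}

#' Age-group CH prevalence trend
#'
#' Percentage of patients carrying at least one CH mutation per age group,
#' and the Pearson correlation between the group index (equally spaced) and
#' the percentage. Empty groups are excluded from the correlation; with fewer
#' than three nonempty groups, or zero variance, `r` is `NA`.
#'
#' @param patients Data.frame with `patient_id` and `age`.
#' @param ch_patient_ids Patient ids carrying at least one final CH mutation.
#' @return List with `table` (group, carriers, total, percent) and `r`.
#' @export
age_trend <- function(patients, ch_patient_ids) {
  grp <- age_group(patients$age)
  total <- as.integer(table(grp))
  carrier <- patients$patient_id %in% ch_patient_ids
  carriers <- as.integer(tapply(carrier, grp, sum, default = 0L))
  age_trend_counts(carriers, total)
}

#' @describeIn age_trend Trend from pre-tabulated per-group counts (e.g. a
#'   published prevalence table); `carriers` and `totals` are aligned to the
#'   seven age-group labels.
#' @param carriers,totals Integer vectors of per-group carrier / total counts.
#' @export
age_trend_counts <- function(carriers, totals) {
  if (length(carriers) != length(totals))
    stop("carriers and totals must have equal length")
  labels <- if (length(carriers) == length(AGE_GROUP_LABELS)) AGE_GROUP_LABELS
            else paste0("group", seq_along(carriers))
  percent <- ifelse(totals > 0, 100 * carriers / totals, NA_real_)
  tab <- data.frame(group = labels, carriers = carriers, total = totals,
                    percent = percent, stringsAsFactors = FALSE)
  nonempty <- which(totals > 0)
  r <- NA_real_
  if (length(nonempty) >= 3L && stats::var(percent[nonempty]) > 0)
    r <- pearson_r(seq_along(nonempty), percent[nonempty])
  list(table = tab, r = r)
}

#' Per-gene and per-variant CH carrier summary
#'
#' Counts, over a patient cohort, how many patients carry at least one CH
#' mutation per gene, how many patients carry each distinct variant, and how
#' many distinct mutational sites each gene contributes. An optional panel
#' gene list restricts the CH calls before counting (used when comparing
#' cohorts sequenced with different panels).
#'
#' @param ch_calls Final CH calls: `patient_id`, key columns, `gene`.
#' @param patients Cohort patient table (`patient_id`, optional `cancer_type`).
#' @param panel Optional character vector of gene symbols to restrict to.
#' @return List of class `ch_cohort_summary`: `total_samples`,
#'   `ch_positive_samples`, `per_gene` (gene, carriers, without, pct_of_total),
#'   `per_variant` (key cols, carriers), `per_gene_sites` (gene, sites,
#'   pct_of_sites), `mutations_per_patient` (mean CH events per CH-positive
#'   patient).
#' @export
gene_summary <- function(ch_calls, patients, panel = NULL) {
  calls <- ch_calls
  if (!is.null(panel)) calls <- calls[calls$gene %in% panel, , drop = FALSE]
  total <- nrow(patients)
  pos_ids <- unique(calls$patient_id)
  if (nrow(calls) > 0L) {
    pg <- tapply(calls$patient_id, calls$gene, function(p) length(unique(p)))
    per_gene <- data.frame(gene = names(pg), carriers = as.integer(pg),
                           without = total - as.integer(pg),
                           pct_of_total = 100 * as.integer(pg) / total,
                           pct_of_ch_positive = 100 * as.integer(pg) / length(pos_ids),
                           stringsAsFactors = FALSE, row.names = NULL)
    per_gene <- per_gene[order(-per_gene$carriers, per_gene$gene), ]
    key <- .df_key(calls)
    pv <- tapply(calls$patient_id, key, function(p) length(unique(p)))
    first <- calls[!duplicated(key), c(KEY_COLS, "gene")]
    per_variant <- data.frame(first, carriers = as.integer(pv[.df_key(first)]),
                              stringsAsFactors = FALSE, row.names = NULL)
    n_sites <- nrow(per_variant)
    sg <- table(per_variant$gene)
    per_gene_sites <- data.frame(gene = names(sg), sites = as.integer(sg),
                                 pct_of_sites = 100 * as.integer(sg) / n_sites,
                                 stringsAsFactors = FALSE, row.names = NULL)
    mut_per_patient <- nrow(calls) / length(pos_ids)
  } else {
    per_gene <- data.frame(gene = character(0), carriers = integer(0),
                           without = integer(0), pct_of_total = numeric(0),
                           pct_of_ch_positive = numeric(0))
    per_variant <- data.frame(chrom = character(0), pos = integer(0),
                              ref = character(0), alt = character(0),
                              gene = character(0), carriers = integer(0))
    per_gene_sites <- data.frame(gene = character(0), sites = integer(0),
                                 pct_of_sites = numeric(0))
    mut_per_patient <- NA_real_
  }
  out <- list(total_samples = total,
              ch_positive_samples = length(pos_ids),
              per_gene = per_gene,
              per_variant = per_variant,
              per_gene_sites = per_gene_sites,
              mutations_per_patient = mut_per_patient)
  class(out) <- "ch_cohort_summary"
  out
}

#' @export
print.ch_cohort_summary <- function(x, ...) {
  cat(sprintf("CH cohort summary: %d of %d samples CH-positive (%.1f%%), %d genes, %d sites\n",
              x$ch_positive_samples, x$total_samples,
              100 * x$ch_positive_samples / max(1, x$total_samples),
              nrow(x$per_gene), nrow(x$per_variant)))
  invisible(x)
}

#' Compare CH prevalence between two cohorts
#'
#' Reports the prevalence ratio `(carriers_a/total_a)/(carriers_b/total_b)`
#' together with a Fisher exact test on the 2x2 carrier table
#' `(carriers_a, total_a - carriers_a; carriers_b, total_b - carriers_b)`.
#' The two quantities are distinct estimands and are labelled as such: the
#' prevalence ratio is not the cross-product odds ratio.
#'
#' @param carriers_a,total_a Carrier and total sample counts, cohort A.
#' @param carriers_b,total_b Carrier and total sample counts, cohort B.
#' @return List with `prevalence_ratio` and `fisher` (a [fisher_exact()]
#'   result holding `or_sample` and `p_two_sided`).
#' @export
prevalence_compare <- function(carriers_a, total_a, carriers_b, total_b) {
  if (total_a <= 0 || total_b <= 0) stop("totals must be positive")
  if (carriers_a > total_a || carriers_b > total_b)
    stop("carriers cannot exceed totals")
  ratio <- (carriers_a / total_a) / (carriers_b / total_b)
  list(prevalence_ratio = ratio,
       fisher = fisher_exact(carriers_a, total_a - carriers_a,
                             carriers_b, total_b - carriers_b))
}

#' Label polymorphic CH mutations and their genes by preferred class
#'
#' A polymorphic CH mutation is one observed as CH in at least one patient and
#' as germline or somatic in at least one other. Its preferred class is the
#' class holding a strict majority (> 50%) of its patient-level occurrences;
#' otherwise it stays unlabeled. Gene labels are derived from labeled
#' mutations only: CH-preferred iff all labeled mutations are CH-preferred;
#' germline-preferred iff the gene has >= 1 CH-preferred mutation and strictly
#' more germline- than somatic-preferred mutations; somatic-preferred
#' symmetrically; ties (and genes without a CH-preferred mutation) are
#' unlabeled.
#'
#' @param occurrences Data.frame with key columns `chrom,pos,ref,alt`, `gene`,
#'   and patient-level occurrence counts `n_ch`, `n_germline`, `n_somatic`.
#' @return List with `mutations` (occurrences of polymorphic mutations plus
#'   `label`) and `genes` (gene, counts per label class, `label`).
#' @export
classify_preferred <- function(occurrences) {
  occ <- occurrences
  poly <- occ$n_ch >= 1L & (occ$n_germline + occ$n_somatic) >= 1L
  occ <- occ[poly, , drop = FALSE]
  n <- occ$n_ch + occ$n_germline + occ$n_somatic
  label <- rep("unlabeled", nrow(occ))
  label[occ$n_ch / n > 0.5] <- "CH_preferred"
  label[occ$n_germline / n > 0.5] <- "germline_preferred"
  label[occ$n_somatic / n > 0.5] <- "somatic_preferred"
  occ$label <- label
  genes <- unique(occ$gene)
  gl <- data.frame(gene = genes,
                   n_ch_pref = rep(NA_integer_, length(genes)),
                   n_germ_pref = rep(NA_integer_, length(genes)),
                   n_som_pref = rep(NA_integer_, length(genes)),
                   label = rep("unlabeled", length(genes)),
                   stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    sub <- occ[occ$gene == genes[i] & occ$label != "unlabeled", ]
    nc <- sum(sub$label == "CH_preferred")
    ng <- sum(sub$label == "germline_preferred")
    ns <- sum(sub$label == "somatic_preferred")
    gl$n_ch_pref[i] <- nc; gl$n_germ_pref[i] <- ng; gl$n_som_pref[i] <- ns
    if (nc >= 1L) {
      if (ng == 0L && ns == 0L) gl$label[i] <- "CH_preferred"
      else if (ng > ns) gl$label[i] <- "germline_preferred"
      else if (ns > ng) gl$label[i] <- "somatic_preferred"
    }
  }
  list(mutations = occ, genes = gl)
}

#' Patient-level class occurrence counts per variant
#'
#' Builds the input of [classify_preferred()] from classified tables: for
#' every variant, how many patients carry it as final CH, as a germline
#' determination (PBL VAF >= 20% branch, pathogenic or not), and as a retained
#' somatic call. Each patient contributes one determination per variant per
#' class.
#'
#' @param classified Full classified table (after the funnel relabels final
#'   CH as `"CH"`).
#' @return Data.frame suitable for [classify_preferred()].
#' @export
preferred_counts <- function(classified) {
  cls <- rep(NA_character_, nrow(classified))
  cls[classified$label == "CH"] <- "ch"
  cls[classified$label == "GERMLINE_PATHOGENIC" |
        (classified$label == "FILTERED" &
           grepl("germline_not_pathogenic", classified$reasons))] <- "germline"
  cls[classified$label == "SOMATIC"] <- "somatic"
  sub <- classified[!is.na(cls), , drop = FALSE]
  cls <- cls[!is.na(cls)]
  if (nrow(sub) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), gene = character(0), n_ch = integer(0),
                      n_germline = integer(0), n_somatic = integer(0)))
  key <- .df_key(sub)
  id <- paste(key, cls, sub$patient_id, sep = "|")
  keep <- !duplicated(id)                 # one count per patient per class
  sub <- sub[keep, , drop = FALSE]; cls <- cls[keep]; key <- key[keep]
  first <- sub[!duplicated(key), c(KEY_COLS, "gene")]
  fkey <- .df_key(first)
  count_of <- function(class) {
    t <- table(key[cls == class])
    out <- as.integer(t[fkey]); out[is.na(out)] <- 0L; out
  }
  data.frame(first, n_ch = count_of("ch"), n_germline = count_of("germline"),
             n_somatic = count_of("somatic"), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Per-gene 2x2 comparison of CH carriers between two cohorts
#'
#' For each gene, lays out samples with/without CH mutations in that gene in
#' the two cohorts as the 2x2 table `(with_A, with_B; without_A, without_B)`,
#' reports the cross-product odds ratio `(a*d)/(b*c)` (Haldane-corrected when
#' a cell is zero), the two-tailed Fisher p, and Benjamini-Hochberg q-values
#' over the tested gene universe. The default universe is the genes carrying
#' CH in both cohorts.
#'
#' @param summary_a,summary_b [gene_summary()] results (or data.frames with
#'   `gene`, `carriers` columns plus a `total_samples` attribute-equivalent
#'   passed via `total_a`/`total_b`).
#' @param universe Optional character vector of genes to test.
#' @return Data.frame `gene,a,b,c,d,odds_ratio,p,q` sorted by p.
#' @export
compare_cohorts <- function(summary_a, summary_b, universe = NULL) {
  pg_a <- summary_a$per_gene; pg_b <- summary_b$per_gene
  tot_a <- summary_a$total_samples; tot_b <- summary_b$total_samples
  if (is.null(universe))
    universe <- intersect(pg_a$gene[pg_a$carriers > 0],
                          pg_b$gene[pg_b$carriers > 0])
  if (length(universe) == 0L)
    return(data.frame(gene = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), q = numeric(0)))
  ca <- pg_a$carriers[match(universe, pg_a$gene)]; ca[is.na(ca)] <- 0L
  cb <- pg_b$carriers[match(universe, pg_b$gene)]; cb[is.na(cb)] <- 0L
  out <- data.frame(gene = universe, a = ca, b = cb,
                    c = tot_a - ca, d = tot_b - cb, stringsAsFactors = FALSE)
  stats <- t(vapply(seq_len(nrow(out)), function(i) {
    fr <- fisher_exact(out$a[i], out$b[i], out$c[i], out$d[i])
    c(fr$or_sample, fr$p_two_sided)
  }, numeric(2)))
  out$odds_ratio <- stats[, 1L]
  out$p <- stats[, 2L]
  out$q <- bh_fdr(out$p)
  out[order(out$p, out$gene), ]
}

#' Overlap final CH calls with an actionable-mutation knowledge base
#'
#' A CH mutation interferes with liquid-biopsy reporting when it coincides
#' with a clinically actionable somatic mutation. Overlaps require an exact
#' match of genomic position and alternate allele. Alongside the hit list and
#' descriptive fractions, a per-gene Fisher test (with BH correction) asks
#' whether hits concentrate in a gene relative to the gene distribution of CH
#' in non-hit patients.
#'
#' @param ch_calls Final CH calls (`patient_id`, key columns, `gene`).
#' @param kb Knowledge base from [read_knowledge_base()].
#' @return List: `hits` (one row per patient x hit variant with assertion),
#'   `n_hit_variants`, `pct_of_ch_variants`, `n_hit_patients`,
#'   `pct_of_ch_patients`, `per_gene` (gene, patients, frac_of_hit_patients,
#'   p, q).
#' @export
actionable_overlap <- function(ch_calls, kb) {
  pos_alt <- function(df) paste(df$chrom, df$pos, df$alt, sep = ":")
  ch_id <- pos_alt(ch_calls)
  hit <- ch_id %in% pos_alt(kb)
  hits <- ch_calls[hit, , drop = FALSE]
  if (nrow(hits) > 0L) {
    kb_idx <- match(pos_alt(hits), pos_alt(kb))
    hits$assertion <- kb$assertion[kb_idx]
  } else hits$assertion <- character(0)
  n_var <- length(unique(.df_key(ch_calls)))
  n_hit_var <- length(unique(.df_key(hits)))
  pat <- unique(ch_calls$patient_id)
  hit_pat <- unique(hits$patient_id)
  per_gene <- data.frame(gene = character(0), patients = integer(0),
                         frac_of_hit_patients = numeric(0), p = numeric(0),
                         q = numeric(0))
  if (nrow(hits) > 0L) {
    pg <- tapply(hits$patient_id, hits$gene, function(p) length(unique(p)))
    per_gene <- data.frame(gene = names(pg), patients = as.integer(pg),
                           frac_of_hit_patients = as.integer(pg) / length(hit_pat),
                           stringsAsFactors = FALSE, row.names = NULL)
    nonhit_pat <- setdiff(pat, hit_pat)
    nonhit_calls <- ch_calls[ch_calls$patient_id %in% nonhit_pat, , drop = FALSE]
    stats <- t(vapply(per_gene$gene, function(g) {
      a <- per_gene$patients[per_gene$gene == g]
      b <- length(hit_pat) - a
      cc <- length(unique(nonhit_calls$patient_id[nonhit_calls$gene == g]))
      d <- length(nonhit_pat) - cc
      fr <- fisher_exact(a, b, cc, d)
      c(fr$p_two_sided, fr$or_sample)
    }, numeric(2)))
    per_gene$odds_ratio <- stats[, 2L]
    per_gene$p <- stats[, 1L]
    per_gene$q <- bh_fdr(per_gene$p)
    per_gene <- per_gene[order(-per_gene$patients, per_gene$gene), ]
    row.names(per_gene) <- NULL
  }
  list(hits = hits,
       n_hit_variants = n_hit_var,
       pct_of_ch_variants = if (n_var > 0) 100 * n_hit_var / n_var else NA_real_,
       n_hit_patients = length(hit_pat),
       pct_of_ch_patients = if (length(pat) > 0) 100 * length(hit_pat) / length(pat)
                            else NA_real_,
       per_gene = per_gene)
}

#' Gene-set over-representation by Fisher's exact test
#'
#' For each set S in a user-supplied GMT collection, tests the 2x2 table
#' `(|genes & S|, |genes \ S|; |background & S \ genes|,
#' |background \ S \ genes|)`; odds ratios are sample cross-product ratios
#' (Haldane-corrected for zero cells), with BH q-values over all sets.
#'
#' @param genes Query gene symbols (must be a subset of `background`).
#' @param background Background gene symbols.
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @return Data.frame `set,n_overlap,set_size,odds_ratio,p,q` sorted by p.
#' @export
enrich_gene_sets <- function(genes, background, sets) {
  genes <- unique(genes); background <- unique(background)
  if (!all(genes %in% background))
    stop("query genes must be a subset of the background")
  out <- data.frame(set = names(sets), n_overlap = NA_integer_,
                    set_size = NA_integer_, odds_ratio = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    a <- length(intersect(genes, s))
    b <- length(setdiff(genes, s))
    cc <- length(setdiff(intersect(background, s), genes))
    d <- length(setdiff(setdiff(background, s), genes))
    fr <- fisher_exact(a, b, cc, d)
    out$n_overlap[i] <- a
    out$set_size[i] <- length(intersect(background, s))
    out$odds_ratio[i] <- fr$or_sample
    out$p[i] <- fr$p_two_sided
  }
  out$q <- bh_fdr(out$p)
  out[order(out$p, out$set), ]
}
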