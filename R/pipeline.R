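# End-to-end orchestration: prefilter -> triage -> candidate-CH funnel
# (min alt reads -> carrier ratio -> tumor crosscheck) -> cohort analytics.
# The analysis pipeline is deterministic; all randomness lives in the
# simulator.

#' Run the full CH identification pipeline on a cohort
#'
#' Classifies every called variant, funnels candidate CH through the
#' cohort-level filters, and computes the standard analytics. The funnel
#' stages are applied once, in order: the minimum-alt-read rule (inside the
#' triage), the carrier-ratio filter (denominator fixed on the post-min-alt
#' candidate set), and the matched-tumor crosscheck. Final CH rows are
#' relabelled `"CH"`; rows removed by the funnel become `FILTERED` with
#' reasons `"carrier_ratio"` / `"tumor_somatic"`. Conservation holds by
#' construction: candidates in = final CH + removed at each stage.
#'
#' @param observations Wide per-variant call table (see [classify_cohort()]).
#' @param patients Patient table (`patient_id`, `age`, optional
#'   `cancer_type`).
#' @param annotations Optional annotation table ([read_annotations()]).
#' @param thresholds A [ch_thresholds()] object.
#' @param blacklist Optional `GRanges` from [read_blacklist()].
#' @param tumor_calls Optional per-patient tumor somatic calls.
#' @param kb Optional actionable knowledge base ([read_knowledge_base()]).
#' @param panel Optional gene list restricting the gene summary.
#' @return Object of class `ch_pipeline`: `classified` (full labelled table),
#'   `ch_calls` (final CH rows), `funnel` (stage counts + removed variant
#'   tables), `carrier_ratios`, `age_trend`, `gene_summary`, `preferred`,
#'   `actionable` (NULL without `kb`), `reason_tally`, `thresholds`,
#'   `wall_time` (seconds).
#' @examples
#' sim <- simulate_cohort(ch_sim_config(n_patients = 50), seed = 1)
#' fit <- ch_pipeline(sim$observations, sim$patients, sim$annotations,
#'                    tumor_calls = sim$tumor_calls)
#' fit
#' @export
ch_pipeline <- function(observations, patients, annotations = NULL,
                        thresholds = ch_thresholds(), blacklist = NULL,
                        tumor_calls = NULL, kb = NULL, panel = NULL) {
  t0 <- proc.time()[["elapsed"]]
  classified <- classify_cohort(observations, annotations, thresholds, blacklist)

  cand_sel <- which(classified$label == "CANDIDATE_CH")
  removed_min_alt <- sum(classified$label == "FILTERED" &
                           classified$reasons == "ch_min_alt")
  candidates <- classified[cand_sel, , drop = FALSE]
  candidates$.row <- cand_sel

  fc <- filter_carrier_ratio(candidates, thresholds)
  tc <- tumor_crosscheck(fc$kept, tumor_calls)

  classified$label[fc$removed$.row] <- "FILTERED"
  classified$reasons[fc$removed$.row] <- "carrier_ratio"
  classified$label[tc$removed$.row] <- "FILTERED"
  classified$reasons[tc$removed$.row] <- "tumor_somatic"
  classified$label[tc$kept$.row] <- "CH"

  ch_calls <- classified[classified$label == "CH", , drop = FALSE]
  funnel <- list(candidates_in = length(cand_sel) + removed_min_alt,
                 removed_min_alt = removed_min_alt,
                 removed_carrier_ratio = nrow(fc$removed),
                 removed_tumor = nrow(tc$removed),
                 ch_final = nrow(tc$kept),
                 removed_carrier_variants = fc$removed_variants)

  filtered <- classified$label %in% c("FILTERED", "DISCORDANT_DISCARD")
  reason_tally <- as.list(table(classified$reasons[filtered]))

  trend <- age_trend(patients, unique(ch_calls$patient_id))
  gsum <- gene_summary(ch_calls, patients, panel)
  preferred <- classify_preferred(preferred_counts(classified))
  actionable <- if (!is.null(kb) && nrow(ch_calls) > 0L)
    actionable_overlap(ch_calls, kb) else NULL

  out <- list(classified = classified, ch_calls = ch_calls, funnel = funnel,
              carrier_ratios = fc$ratios, age_trend = trend,
              gene_summary = gsum, preferred = preferred,
              actionable = actionable, reason_tally = reason_tally,
              thresholds = thresholds,
              n_patients = nrow(patients),
              wall_time = proc.time()[["elapsed"]] - t0)
  class(out) <- "ch_pipeline"
  out
}

#' @export
print.ch_pipeline <- function(x, ...) {
  f <- x$funnel
  cat("CH identification pipeline\n")
  cat(sprintf("  patients: %d; classified variants: %d\n",
              x$n_patients, nrow(x$classified)))
  cat(sprintf("  candidate CH funnel: %d -> min-alt -%d -> carrier-ratio -%d -> tumor -%d -> %d CH\n",
              f$candidates_in, f$removed_min_alt, f$removed_carrier_ratio,
              f$removed_tumor, f$ch_final))
  cat(sprintf("  CH-positive patients: %d of %d (%.1f%%)\n",
              x$gene_summary$ch_positive_samples, x$n_patients,
              100 * x$gene_summary$ch_positive_samples / max(1, x$n_patients)))
  if (!is.na(x$age_trend$r))
    cat(sprintf("  age trend: Pearson r = %.3f across age groups\n", x$age_trend$r))
  invisible(x)
}

#' @export
summary.ch_pipeline <- function(object, ...) {
  print(object)
  cat("\nLabel counts:\n")
  print(table(object$classified$label))
  cat("\nAge-group prevalence:\n")
  print(object$age_trend$table, row.names = FALSE)
  pg <- object$gene_summary$per_gene
  if (nrow(pg) > 0L) {
    cat("\nTop genes by CH carriers:\n")
    print(utils::head(pg, 10), row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.ch_pipeline <- function(x, ...) {
  tab <- x$age_trend$table
  bp <- graphics::barplot(tab$percent, names.arg = tab$group,
                          ylab = "% patients with >=1 CH mutation",
                          xlab = "diagnostic age group",
                          main = "CH prevalence by age", ...)
  if (!is.na(x$age_trend$r))
    graphics::legend("topleft", bty = "n",
                     legend = sprintf("Pearson r = %.3f", x$age_trend$r))
  invisible(bp)
}

#' Machine-readable run summary
#'
#' Collects the threshold echo, funnel stage counts, per-reason filter
#' tallies, cohort counts and wall time into a JSON-serialisable list, and
#' optionally writes it to disk.
#'
#' @param x A `ch_pipeline` object.
#' @param path Optional output path for the JSON document.
#' @param seed Optional seed to record (for simulated inputs).
#' @return The summary list, invisibly when `path` is given.
#' @export
run_summary <- function(x, path = NULL, seed = NULL) {
  stopifnot(inherits(x, "ch_pipeline"))
  th <- x$thresholds; class(th) <- NULL
  s <- list(thresholds = th,
            n_patients = x$n_patients,
            n_observations = nrow(x$classified),
            funnel = x$funnel[c("candidates_in", "removed_min_alt",
                                "removed_carrier_ratio", "removed_tumor",
                                "ch_final")],
            reason_tally = x$reason_tally,
            ch_positive_samples = x$gene_summary$ch_positive_samples,
            age_trend_r = x$age_trend$r,
            seed = seed,
            wall_time = x$wall_time)
  if (!is.null(path)) {
    jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(s))
  }
  s
}

#' Persist pipeline outputs as plain-text tables
#'
#' Writes `classified.tsv`, `carrier_ratios.tsv`, `age_trend.tsv`,
#' `gene_summary.tsv`, `preferred_genes.tsv` and `funnel.json` (the run
#' summary with an output manifest) into a directory.
#'
#' @param x A `ch_pipeline` object.
#' @param dir Output directory (created if needed).
#' @param seed Optional seed to record in the run summary.
#' @return `dir`, invisibly.
#' @export
save_outputs <- function(x, dir, seed = NULL) {
  stopifnot(inherits(x, "ch_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_classified(x$classified, file.path(dir, "classified.tsv"))
  wr <- function(df, name) utils::write.table(df, file.path(dir, name), sep = "\t",
                                              quote = FALSE, row.names = FALSE)
  wr(x$carrier_ratios, "carrier_ratios.tsv")
  wr(x$age_trend$table, "age_trend.tsv")
  wr(x$gene_summary$per_gene, "gene_summary.tsv")
  wr(x$preferred$genes, "preferred_genes.tsv")
  s <- run_summary(x, seed = seed)
  s$manifest <- c("classified.tsv", "carrier_ratios.tsv", "age_trend.tsv",
                  "gene_summary.tsv", "preferred_genes.tsv", "funnel.json")
  jsonlite::write_json(s, file.path(dir, "funnel.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
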