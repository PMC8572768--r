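# Cohort analytics: carrier-ratio funnel, age trend, gene summaries,
# preferred classes, cohort comparison, actionable overlap, enrichment.

# candidate table: 400 patients each carrying a private variant
singleton_candidates <- function(n = 400) {
  make_obs(n, patient_id = sprintf("C%04d", seq_len(n)), pos = 1000 + seq_len(n))
}

test_that("carrier ratio uses the CH-positive denominator computed once", {
  cand <- singleton_candidates(400)
  cr <- carrier_ratio(cand)
  expect_equal(attr(cr, "n_positive"), 400L)
  expect_true(all(cr$ratio == 1 / 400))     # 0.0025 each

  # a variant carried by every CH-positive patient has ratio 1
  all_carried <- cand
  all_carried$pos <- 1L
  expect_equal(carrier_ratio(all_carried)$ratio, 1)

  expect_equal(nrow(carrier_ratio(make_obs(0))), 0L)
})

test_that("carrier-ratio filtering is strict and monotone in the ceiling", {
  cand <- singleton_candidates(400)          # each ratio exactly 0.25%
  fc <- filter_carrier_ratio(cand)
  expect_equal(nrow(fc$kept), 400L)          # boundary value retained
  expect_equal(nrow(fc$removed), 0L)

  # add one recurrent variant carried by 5 of the 400 patients (ratio 1.25%)
  rec <- make_obs(5, patient_id = sprintf("C%04d", 1:5), pos = 9999L)
  cand2 <- rbind(cand, rec)
  fc2 <- filter_carrier_ratio(cand2)
  expect_equal(nrow(fc2$removed), 5L)
  expect_equal(unique(fc2$removed$pos), 9999L)
  expect_equal(fc2$retention, 400 / 405)

  # lowering the ceiling never grows the kept set
  fc3 <- filter_carrier_ratio(cand2, ch_thresholds(carrier_ratio_max = 0.001))
  expect_true(all(paste(fc3$kept$patient_id, fc3$kept$pos) %in%
                    paste(fc2$kept$patient_id, fc2$kept$pos)))
})

test_that("tumor crosscheck removes only same-patient exact matches", {
  cand <- make_obs(2, patient_id = c("A", "B"), pos = c(10L, 10L))
  tumor <- data.frame(patient_id = "A", chrom = "chr1", pos = 10L,
                      ref = "A", alt = "G")
  tc <- tumor_crosscheck(cand, tumor)
  expect_equal(tc$removed$patient_id, "A")
  expect_equal(tc$kept$patient_id, "B")       # other patient's tumor: retained
  expect_equal(nrow(tumor_crosscheck(cand, NULL)$removed), 0L)
})

test_that("age groups are right-closed with open first and last bins", {
  expect_equal(as.character(age_group(c(40, 50, 96, 13, 90, 91))),
               c("<=40", "40-50", ">90", "<=40", "80-90", ">90"))
  expect_error(age_group(-1), "non-negative")
})

test_that("age trend reproduces the reference prevalence table and r", {
  tr <- age_trend_counts(REF_AGE_CARRIERS, REF_AGE_TOTALS)
  expect_equal(round(tr$table$percent, 2),
               c(26.17, 30.39, 38.57, 47.95, 57.10, 65.36, 71.43))
  expect_equal(round(tr$r, 3), 0.997)

  # zero-variance percents: r undefined, reported absent
  expect_true(is.na(age_trend_counts(c(10, 10, 10), c(100, 100, 100))$r))
  # fewer than 3 nonempty groups: r absent
  expect_true(is.na(age_trend_counts(c(5, 7, 0), c(10, 10, 0))$r))

  pts <- data.frame(patient_id = c("a", "b", "c", "d"), age = c(35, 45, 55, 95))
  tr2 <- age_trend(pts, c("b", "d"))
  expect_equal(tr2$table$carriers, c(0L, 1L, 0L, 0L, 0L, 0L, 1L))
  expect_equal(tr2$table$total, c(1L, 1L, 1L, 0L, 0L, 0L, 1L))
})

test_that("gene summary counts carriers, sites and panel restriction", {
  calls <- data.frame(patient_id = c("P1", "P1", "P2", "P3"),
                      chrom = "chr1", pos = c(1L, 2L, 2L, 3L),
                      ref = "A", alt = "G",
                      gene = c("DNMT3A", "TET2", "TET2", "DNMT3A"))
  pts <- data.frame(patient_id = sprintf("P%d", 1:5), age = 50)
  gs <- gene_summary(calls, pts)
  expect_equal(gs$total_samples, 5L)
  expect_equal(gs$ch_positive_samples, 3L)
  pg <- gs$per_gene
  expect_equal(pg$carriers[pg$gene == "DNMT3A"], 2L)
  expect_equal(pg$without[pg$gene == "TET2"], 3L)
  expect_equal(gs$per_gene_sites$sites[gs$per_gene_sites$gene == "DNMT3A"], 2L)
  expect_equal(gs$mutations_per_patient, 4 / 3)

  gs_panel <- gene_summary(calls, pts, panel = "TET2")
  expect_equal(gs_panel$ch_positive_samples, 2L)
  expect_equal(nrow(gs_panel$per_gene), 1L)
  expect_equal(nrow(gene_summary(calls, pts, panel = character(0))$per_gene), 0L)
})

test_that("prevalence comparison separates the ratio from the cross-product OR", {
  pc <- prevalence_compare(4, 30, 1698, 11725)
  expect_equal(round(pc$prevalence_ratio, 3), 0.921)
  expect_equal(pc$fisher$or_sample, (4 * 10027) / (26 * 1698))
  expect_equal(round(pc$fisher$p_two_sided, 2), 1)

  expect_equal(prevalence_compare(10, 100, 30, 300)$prevalence_ratio, 1)
  expect_error(prevalence_compare(1, 0, 1, 10), "positive")
})

test_that("preferred-class labels follow the strict-majority and gene rules", {
  occ <- data.frame(chrom = "chr1", pos = 1:6, ref = "A", alt = "G",
                    gene = c("G1", "G1", "G1", "G2", "G3", "G3"),
                    n_ch = c(3L, 1L, 1L, 2L, 1L, 1L),
                    n_germline = c(1L, 0L, 0L, 1L, 2L, 1L),
                    n_somatic = c(0L, 1L, 3L, 0L, 0L, 3L))
  res <- classify_preferred(occ)
  m <- res$mutations
  expect_equal(m$label[m$pos == 1], "CH_preferred")       # share 0.75
  expect_equal(m$label[m$pos == 2], "unlabeled")          # 0.5 tie
  expect_equal(m$label[m$pos == 3], "somatic_preferred")
  expect_equal(m$label[m$pos == 5], "germline_preferred")
  g <- res$genes
  expect_equal(g$label[g$gene == "G2"], "CH_preferred")   # CH-preferred only
  expect_equal(g$label[g$gene == "G1"], "somatic_preferred")
  expect_equal(g$label[g$gene == "G3"], "unlabeled")      # no CH-preferred mutation

  # non-polymorphic variants never enter
  pure <- data.frame(chrom = "chr1", pos = 9L, ref = "A", alt = "G",
                     gene = "G9", n_ch = 5L, n_germline = 0L, n_somatic = 0L)
  expect_equal(nrow(classify_preferred(pure)$mutations), 0L)
})

test_that("preferred_counts tallies patient-level determinations per class", {
  cls <- data.frame(patient_id = c("P1", "P2", "P3", "P3"),
                    chrom = "chr1", pos = c(1L, 1L, 1L, 1L), ref = "A", alt = "G",
                    gene = "TET2",
                    label = c("CH", "SOMATIC", "FILTERED", "FILTERED"),
                    reasons = c("ch_window", "somatic_pass",
                                "germline_not_pathogenic",
                                "germline_not_pathogenic"))
  pc <- preferred_counts(cls)
  expect_equal(pc$n_ch, 1L)
  expect_equal(pc$n_somatic, 1L)
  expect_equal(pc$n_germline, 1L)   # duplicate same-patient rows count once
})

test_that("two-cohort per-gene comparison builds the 2x2s and BH-adjusts", {
  mk <- function(genes, carriers, total) {
    s <- list(per_gene = data.frame(gene = genes, carriers = carriers),
              total_samples = total)
    s
  }
  a <- mk(c("G1", "G2", "G3"), c(10L, 5L, 0L), 100L)
  b <- mk(c("G1", "G2", "G3"), c(1L, 5L, 2L), 100L)
  cc <- compare_cohorts(a, b)
  expect_setequal(cc$gene, c("G1", "G2"))   # default universe: CH in both
  g1 <- cc[cc$gene == "G1", ]
  expect_equal(g1$odds_ratio, (10 * 99) / (90 * 1))
  expect_equal(g1$p, 0.00965811594351825, tolerance = 1e-9)  # frozen oracle value
  g2 <- cc[cc$gene == "G2", ]
  expect_equal(g2$odds_ratio, 1)
  expect_equal(g2$p, 1)
  expect_equal(cc$q, bh_fdr(cc$p))

  cc3 <- compare_cohorts(a, b, universe = c("G1", "G2", "G3"))
  expect_equal(nrow(cc3), 3L)
})

test_that("actionable overlap is exact on position and alternate allele", {
  ch <- data.frame(patient_id = c("P1", "P2", "P3"),
                   chrom = "chr12", pos = c(100L, 100L, 200L),
                   ref = "C", alt = c("T", "A", "T"),
                   gene = c("KRAS", "KRAS", "TP53"))
  kb <- data.frame(chrom = "chr12", pos = 100L, ref = "C", alt = "T",
                   gene = "KRAS", assertion = "therapy target")
  ov <- actionable_overlap(ch, kb)
  expect_equal(ov$n_hit_variants, 1L)
  expect_equal(ov$n_hit_patients, 1L)          # same pos, different alt: no hit
  expect_equal(ov$hits$patient_id, "P1")
  expect_equal(ov$per_gene$frac_of_hit_patients, 1)
  expect_equal(round(ov$pct_of_ch_variants, 1), 33.3)
})

test_that("gene-set enrichment matches hand counts and is order-stable", {
  genes <- c("A", "B", "C", "D", "E")
  background <- c(genes, sprintf("X%d", 1:15))
  sets <- list(S1 = c("A", "B", "X1", "X2"), S2 = c("X3", "X4", "X5"))
  en <- enrich_gene_sets(genes, background, sets)
  s1 <- en[en$set == "S1", ]
  expect_equal(s1$n_overlap, 2L)
  # table (2,3;2,13) against the enumeration oracle
  expect_equal(s1$p, fisher_oracle(2, 3, 2, 13), tolerance = 1e-12)
  expect_equal(s1$odds_ratio, (2 * 13) / (3 * 2))

  perm <- enrich_gene_sets(genes, background, sets[c(2, 1)])
  expect_equal(perm[order(perm$set), ]$q, en[order(en$set), ]$q)

  # saturated degenerate case: Haldane keeps the OR finite, p = 1
  sat <- enrich_gene_sets(genes, genes, list(S = genes))
  expect_true(is.finite(sat$odds_ratio))
  expect_equal(sat$p, 1)
  expect_error(enrich_gene_sets(c("A", "ZZ"), genes, sets), "subset")
})
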