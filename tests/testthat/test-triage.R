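# The somatic / germline / candidate-CH decision procedure.

test_that("prefilter removes blacklisted and synonymous variants in order", {
  v <- make_obs(3)
  ann <- rbind(ann_row(consequence = "missense", in_blacklist = TRUE),
               ann_row(consequence = "synonymous"),
               ann_row(consequence = "missense"))
  pf <- prefilter(v, ann)
  expect_equal(pf$kept, 3L)
  expect_equal(pf$removed$reason, c("blacklist", "synonymous"))
})

test_that("cfDNA-only variants pass or fail the somatic criteria", {
  # 10/1000 (VAF 1%), unannotated: all somatic thresholds met
  r <- classify_variant(1000, 10)
  expect_equal(r$label, "SOMATIC")
  expect_true(is.na(r$p_value))

  # dbSNP-recorded but not COSMIC-recorded: filtered
  r <- classify_variant(1000, 10, annotation = ann_row(in_dbsnp = TRUE))
  expect_equal(r$label, "FILTERED")
  expect_true("dbsnp_not_cosmic" %in% r$reasons)
  # dbSNP + COSMIC: retained
  expect_equal(classify_variant(1000, 10,
                                annotation = ann_row(in_dbsnp = TRUE,
                                                     in_cosmic = TRUE))$label,
               "SOMATIC")

  # each somatic threshold fires its own reason
  expect_true("somatic_low_depth" %in% classify_variant(99, 10)$reasons)
  expect_true("somatic_min_alt" %in% classify_variant(1000, 1)$reasons)
  expect_true("somatic_low_vaf" %in% classify_variant(1000, 2)$reasons)
  expect_true("pop_maf" %in%
                classify_variant(1000, 10,
                                 annotation = ann_row(maf_gnomad = 0.01))$reasons)
  expect_true("hla" %in%
                classify_variant(1000, 10, annotation = ann_row(is_hla = TRUE))$reasons)
  # population MAF exactly at the ceiling passes ("not larger than")
  expect_equal(classify_variant(1000, 10,
                                annotation = ann_row(maf_gnomad = 0.002))$label,
               "SOMATIC")
})

test_that("high-PBL-VAF calls are germline, kept only when ClinVar-pathogenic", {
  r <- classify_variant(1000, 480, 200, 100, ann_row())
  expect_equal(r$label, "FILTERED")
  expect_equal(r$reasons, "germline_not_pathogenic")
  expect_equal(classify_variant(1000, 480, 200, 100,
                                ann_row(clinvar = "likely_pathogenic"))$label,
               "GERMLINE_PATHOGENIC")
  # VAF exactly 20% is germline (">= 20%"), depth exactly 30 is evaluated
  expect_equal(classify_variant(1000, 480, 30, 6, ann_row())$reasons,
               "germline_not_pathogenic")
})

test_that("the paired Fisher branch routes CH, somatic and discordant cases", {
  # matched low VAF: OR = (11*495)/(989*5) = 1.101, p = 1 -> candidate CH
  r <- classify_variant(1000, 11, 500, 5)
  expect_equal(r$label, "CANDIDATE_CH")
  expect_equal(r$odds_ratio, (11 * 495) / (989 * 5))
  expect_equal(r$p_value, 1, tolerance = 1e-9)   # frozen via enumeration oracle

  # cfDNA-enriched significant: OR = 9.51, p = 1.83e-5 -> somatic filters apply
  r <- classify_variant(1000, 60, 300, 2)
  expect_equal(r$label, "SOMATIC")
  expect_equal(r$p_value, 1.82647315655466e-05, tolerance = 1e-9)
  expect_gt(r$odds_ratio, 1)

  # candidate CH needs >= 2 alt reads in BOTH compartments
  r <- classify_variant(1000, 3, 300, 1)   # OR = 0.90, p = 1, PBL alt = 1
  expect_equal(r$label, "FILTERED")
  expect_equal(r$reasons, "ch_min_alt")

  # PBL-enriched significant counts: discordant, never CH
  r <- classify_variant(1000, 2, 100, 15)  # PBL VAF 15%, OR = 0.011, p ~ 1e-14
  expect_equal(r$label, "DISCORDANT_DISCARD")
  expect_equal(r$reasons, "pbl_enriched")

  # non-significant but OR outside the window: discordant
  r <- classify_variant(1000, 10, 200, 4)    # OR = (10*196)/(990*4) = 0.495
  expect_equal(r$label, "DISCORDANT_DISCARD")
  expect_equal(r$reasons, "or_outside_window")
})

test_that("low or zero depth is filtered, never a crash", {
  expect_equal(classify_variant(1000, 10, 20, 2)$reasons, "pbl_low_depth")
  expect_equal(classify_variant(0, 0, 200, 2)$reasons, "zero_depth")
  expect_equal(classify_variant(0, 0)$reasons, "zero_depth")
  expect_equal(classify_variant(0, 0, 0, 0)$reasons, "zero_depth")
})

test_that("every observation receives exactly one label and CH obeys its gates", {
  set.seed(21)
  n <- 300
  obs <- make_obs(n,
                  cfdna_depth = sample(50:1500, n, TRUE),
                  cfdna_alt = 0L, pbl_depth = NA_integer_, pbl_alt = NA_integer_)
  obs$cfdna_alt <- rbinom(n, obs$cfdna_depth, runif(n, 0, 0.4))
  has_pbl <- runif(n) < 0.8
  obs$pbl_depth[has_pbl] <- sample(10:400, sum(has_pbl), TRUE)
  obs$pbl_alt[has_pbl] <- rbinom(sum(has_pbl), obs$pbl_depth[has_pbl],
                                 runif(sum(has_pbl), 0, 0.4))
  cls <- classify_cohort(obs)
  expect_equal(nrow(cls), n)
  expect_true(all(cls$label %in% c("SOMATIC", "GERMLINE_PATHOGENIC",
                                   "CANDIDATE_CH", "DISCORDANT_DISCARD",
                                   "FILTERED")))
  ch <- cls$label == "CANDIDATE_CH"
  if (any(ch)) {
    expect_true(all(obs$pbl_alt[ch] / obs$pbl_depth[ch] < 0.20))
    expect_true(all(obs$pbl_alt[ch] >= 2 & obs$cfdna_alt[ch] >= 2))
    expect_true(all(cls$p_value[ch] >= 0.05))
    expect_true(all(cls$odds_ratio[ch] > 0.5 & cls$odds_ratio[ch] < 1.5))
  }
  # determinism: identical inputs give identical output
  expect_identical(cls, classify_cohort(obs))
})

test_that("threshold monotonicity: stricter p grows no CH; wider OR window loses none", {
  set.seed(22)
  n <- 200
  obs <- make_obs(n, cfdna_depth = 1000,
                  cfdna_alt = rbinom(n, 1000, 0.02),
                  pbl_depth = 200, pbl_alt = rbinom(n, 200, 0.02))
  base <- classify_cohort(obs)
  stricter <- classify_cohort(obs, thresholds = ch_thresholds(ch_min_p = 0.10))
  wider <- classify_cohort(obs, thresholds = ch_thresholds(ch_or_low = 0.25,
                                                           ch_or_high = 4))
  ch_of <- function(cls) which(cls$label == "CANDIDATE_CH")
  expect_true(all(ch_of(stricter) %in% ch_of(base)))
  expect_true(all(ch_of(base) %in% ch_of(wider)))
})

test_that("classify_patient handles empty input and composes with prefilter", {
  empty <- make_obs(0)
  expect_equal(nrow(classify_patient(empty)), 0L)

  hdr <- paste(c("chrom", "pos", "ref", "alt", "gene", "consequence",
                 "maf_gnomad", "maf_exac", "in_dbsnp", "in_cosmic", "is_hla",
                 "in_blacklist", "clinvar"), collapse = "\t")
  f <- tempfile(fileext = ".tsv")
  writeLines(c(hdr, "chr1\t1\tA\tG\tX\tsynonymous\t\t\tFALSE\tFALSE\tFALSE\tFALSE\tnone"), f)
  ann <- read_annotations(f)
  obs <- make_obs(2)            # pos 1 annotated synonymous, pos 2 unannotated
  cls <- classify_patient(obs, ann)
  expect_equal(cls$label, c("FILTERED", "SOMATIC"))
  expect_equal(cls$reasons[1], "synonymous")
})
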