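# Synthetic-cohort generator: determinism, degenerate configs, the
# compartment model, and truth conservation.

test_that("empty cohorts and invalid configs are handled by name", {
  sim <- simulate_cohort(ch_sim_config(n_patients = 0), seed = 1)
  expect_equal(nrow(sim$patients), 0L)
  expect_equal(nrow(sim$observations), 0L)

  expect_error(ch_sim_config(error_rate = 2), "error_rate")
  expect_error(ch_sim_config(ch_vaf_range = c(0.5, 0.1)), "ch_vaf_range")
  expect_error(ch_sim_config(n_patients = -5), "n_patients")
  expect_error(ch_sim_config(age_range = c(90, 30)), "age_range")
})

test_that("a fixed seed reproduces the cohort byte for byte", {
  cfg <- ch_sim_config(n_patients = 60)
  a <- simulate_cohort(cfg, seed = 123)
  b <- simulate_cohort(cfg, seed = 123)
  expect_identical(a, b)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  c2 <- simulate_cohort(cfg, seed = 124)
  expect_false(identical(a$observations, c2$observations))
})

test_that("with zero error rate somatic variants are strictly cfDNA-only", {
  sim <- simulate_cohort(ch_sim_config(n_patients = 100, error_rate = 0), seed = 5)
  som_keys <- with(subset(sim$truth, true_class == "somatic"),
                   paste(patient_id, chrom, pos))
  obs_som <- sim$observations[paste(sim$observations$patient_id,
                                    sim$observations$chrom,
                                    sim$observations$pos) %in% som_keys, ]
  expect_true(all(is.na(obs_som$pbl_depth)))
})

test_that("germline and CH variants share one blood VAF; somatic PBL VAF is 0", {
  sim <- simulate_cohort(ch_sim_config(n_patients = 200), seed = 9)
  tr <- sim$truth
  expect_true(all(tr$vaf_pbl[tr$true_class %in% c("CH", "germline", "artifact")] ==
                    tr$vaf_cfdna[tr$true_class %in% c("CH", "germline", "artifact")]))
  expect_true(all(tr$vaf_pbl[tr$true_class == "somatic"] == 0))
  expect_true(all(tr$vaf_tumor[tr$true_class == "somatic"] > 0))
  expect_true(all(tr$vaf_tumor[tr$true_class != "somatic"] == 0))
  # planted artifact fraction of CH carriers matches the configured rate
  carriers <- length(unique(tr$patient_id[tr$true_class == "CH"]))
  per_art <- table(tr$pos[tr$true_class == "artifact"])
  expect_true(all(per_art == max(1, round(0.02 * carriers))))
})

test_that("every truth record maps to one classified record or one omission", {
  sim <- simulate_cohort(ch_sim_config(n_patients = 150), seed = 3)
  fit <- ch_pipeline(sim$observations, sim$patients, sim$annotations,
                     tumor_calls = sim$tumor_calls)
  tid <- with(sim$truth, paste(patient_id, chrom, pos, ref, alt))
  cid <- with(fit$classified, paste(patient_id, chrom, pos, ref, alt))
  expect_false(any(duplicated(tid)))
  matched <- tid %in% cid
  expect_true(all(matched | !sim$truth$in_cfdna_calls))
  ev <- evaluate_calls(sim$truth, fit)
  expect_equal(ev$omissions, sum(!sim$truth$in_cfdna_calls))
})

test_that("recovery scoring is exact on a hand-built result", {
  truth <- data.frame(patient_id = c("P1", "P2", "P3"),
                      chrom = "chr1", pos = 1:3, ref = "A", alt = "G",
                      gene = "TET2", true_class = c("CH", "germline", "somatic"),
                      vaf_cfdna = c(0.05, 0.5, 0.1), vaf_pbl = c(0.05, 0.5, 0),
                      vaf_tumor = c(0, 0, 0.5), in_cfdna_calls = TRUE)
  classified <- data.frame(patient_id = truth$patient_id, chrom = "chr1",
                           pos = 1:3, ref = "A", alt = "G", gene = "TET2",
                           label = c("CH", "GERMLINE_PATHOGENIC", "SOMATIC"),
                           reasons = "")
  result <- list(classified = classified,
                 funnel = list(removed_carrier_variants =
                                 data.frame(chrom = character(0), pos = integer(0),
                                            ref = character(0), alt = character(0))))
  ev <- evaluate_calls(truth, result)
  expect_equal(ev$ch_sensitivity, 1)
  expect_equal(ev$germline_to_ch, 0)
  expect_equal(ev$somatic_to_ch, 0)

  # empty call set: zero sensitivity, nothing leaks
  none <- result
  none$classified <- classified[0, ]
  expect_error(evaluate_calls(truth, none), NA)
  ev0 <- evaluate_calls(truth, none)
  expect_equal(ev0$ch_sensitivity, 0)
  expect_equal(ev0$omissions, 3L)
})

test_that("simulated age-prevalence trend is strongly positive", {
  sim <- simulate_cohort(ch_sim_config(n_patients = 4000), seed = 17)
  tr <- age_trend(sim$patients,
                  unique(sim$truth$patient_id[sim$truth$true_class == "CH"]))
  expect_gt(tr$r, 0.9)
})
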