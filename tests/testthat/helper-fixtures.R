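# Shared fixture builders; all data is generated in code at test time.

# one-row annotation with overridable fields (defaults = unannotated variant)
ann_row <- function(...) {
  ann <- annotation_for(data.frame(chrom = "chr1", pos = 1, ref = "A", alt = "C"))[1, ]
  over <- list(...)
  for (nm in names(over)) ann[[nm]] <- over[[nm]]
  ann
}

# wide observation rows with unique default keys
make_obs <- function(n, patient_id = sprintf("P%03d", seq_len(n)),
                     cfdna_depth = 1000, cfdna_alt = 10,
                     pbl_depth = NA, pbl_alt = NA, pos = NULL, gene = NULL) {
  df <- data.frame(patient_id = rep_len(patient_id, n), chrom = rep_len("chr1", n),
                   pos = if (is.null(pos)) seq_len(n) else rep_len(pos, n),
                   ref = rep_len("A", n), alt = rep_len("G", n),
                   cfdna_depth = rep_len(cfdna_depth, n),
                   cfdna_alt = rep_len(cfdna_alt, n),
                   pbl_depth = rep_len(pbl_depth, n), pbl_alt = rep_len(pbl_alt, n),
                   stringsAsFactors = FALSE)
  if (!is.null(gene)) df$gene <- gene
  df
}

# cells uniform on 0..100, so every margin is <= 200; never all-zero
random_table2x2 <- function() {
  repeat {
    t <- sample(0:100, 4, replace = TRUE)
    if (sum(t) > 0) return(t)
  }
}

# cached default-simulation pipeline fit (study-scale cohort), shared by tests
.fixture_env <- new.env()
cached_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    sim <- simulate_cohort(ch_sim_config(n_patients = 2000), seed = 7)
    fit <- ch_pipeline(sim$observations, sim$patients, sim$annotations,
                       tumor_calls = sim$tumor_calls, kb = sim$kb)
    .fixture_env$sim <- sim
    .fixture_env$fit <- fit
  }
  list(sim = .fixture_env$sim, fit = .fixture_env$fit)
}

# age-group prevalence counts of the reference pan-cancer cohort
# (published prevalence-by-age table; used as plain numeric input)
REF_AGE_CARRIERS <- c(179, 512, 1237, 1925, 1025, 217, 5)
REF_AGE_TOTALS <- c(684, 1685, 3207, 4015, 1795, 332, 7)
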