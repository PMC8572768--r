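# Synthetic paired-cohort generator with ground truth.
#
# The generator emulates the compartment model the paired exact test assumes:
# a variant has one true allele fraction per compartment; read depth is
# Poisson around the panel's mean depth, and alt-supporting reads are
# binomial at VAF + e*(1-VAF) where e is the per-base error rate. Germline
# and CH variants share one blood VAF across cfDNA and PBL (the test's null);
# somatic variants have true PBL VAF 0 and appear there only through error
# reads; recurrent artifacts are CH-like variants planted at a fixed key in a
# stated fraction of CH carriers. A variant with 0 alt reads in a compartment
# is omitted from that compartment's call table (the "not called" convention).

#' Simulation configuration
#'
#' Defaults encode the cohort conditions the pipeline was designed around:
#' ages uniform on 30--90 with CH prevalence logistic in age (~26% at <=40
#' rising to ~71% above 90), CH burden mostly one (60%) or two (25%)
#' mutations per carrier with a geometric tail, CH blood VAF log-uniform on
#' [0.005, 0.20), two germline variants per patient at VAF ~ Beta(50,50),
#' three somatic variants per patient with cfDNA VAF log-uniform on
#' [0.003, 0.30] (tumor VAF 10x, capped at 0.5), mean depths 200x (PBL) /
#' 1000x (cfDNA, tumor), and base error rate 0.001.
#'
#' @param n_patients Number of patients.
#' @param age_range Inclusive integer age range sampled uniformly.
#' @param prev_intercept,prev_slope Logistic coefficients of P(carrier | age).
#' @param ch_count_probs P(1 CH) and P(2 CH) per carrier; the remainder is a
#'   geometric tail (success 0.5) starting at 3.
#' @param ch_vaf_range Log-uniform range of the shared blood VAF of CH
#'   variants.
#' @param n_germline,germline_beta,germline_pathogenic_frac Germline variants
#'   per patient, Beta(a,b) VAF parameters, and fraction annotated ClinVar
#'   pathogenic.
#' @param n_somatic,somatic_vaf_range,tumor_vaf_mult,tumor_vaf_cap Somatic
#'   variants per patient, cfDNA VAF range (log-uniform), and the tumor-VAF
#'   multiplier/cap.
#' @param depth_pbl,depth_cfdna,depth_tumor Mean Poisson depths per
#'   compartment.
#' @param error_rate Per-base sequencing error rate e.
#' @param dispersion Beta-binomial overdispersion rho in [0,1); 0 (default)
#'   gives pure binomial counts.
#' @param compartment_shift Multiplicative shift of the cfDNA VAF relative to
#'   PBL for CH variants (0 = shared VAF, the exact-test null).
#' @param n_artifacts,artifact_frac,artifact_vaf_range Number of recurrent
#'   artifact variants, fraction of CH carriers each is planted in (must
#'   exceed the 0.25% carrier-ratio ceiling to be removable), and their VAF
#'   range.
#' @param tumor_fraction Fraction of patients with matched tumor data.
#' @param ch_pool_size Number of distinct CH variant sites to draw from.
#' @param hot_genes Named weights of CH-enriched genes (remaining mass is
#'   spread over `n_other_genes` generic genes).
#' @param n_other_genes Number of generic background genes.
#' @param n_kb Knowledge-base size: that many CH pool sites are marked
#'   actionable.
#' @return Validated list of class `ch_sim_config`.
#' @export
ch_sim_config <- function(n_patients = 2000,
                          age_range = c(30, 90),
                          prev_intercept = -2.23,
                          prev_slope = 0.0338,
                          ch_count_probs = c(0.60, 0.25),
                          ch_vaf_range = c(0.005, 0.20),
                          n_germline = 2,
                          germline_beta = c(50, 50),
                          germline_pathogenic_frac = 0.2,
                          n_somatic = 3,
                          somatic_vaf_range = c(0.003, 0.30),
                          tumor_vaf_mult = 10,
                          tumor_vaf_cap = 0.5,
                          depth_pbl = 200,
                          depth_cfdna = 1000,
                          depth_tumor = 1000,
                          error_rate = 0.001,
                          dispersion = 0,
                          compartment_shift = 0,
                          n_artifacts = 3,
                          artifact_frac = 0.02,
                          artifact_vaf_range = c(0.01, 0.10),
                          tumor_fraction = 0.5,
                          ch_pool_size = 500000,
                          hot_genes = c(DNMT3A = 0.30, TET2 = 0.12, ASXL1 = 0.05),
                          n_other_genes = 40,
                          n_kb = 20) {
  cfg <- mget(names(formals()))
  .stopifnot_scalar_number(cfg$n_patients, "n_patients", 0)
  if (length(cfg$age_range) != 2L || cfg$age_range[1] > cfg$age_range[2] ||
      any(cfg$age_range < 0))
    stop("invalid field 'age_range'")
  .stopifnot_scalar_number(cfg$prev_slope, "prev_slope")
  .stopifnot_scalar_number(cfg$prev_intercept, "prev_intercept")
  if (length(cfg$ch_count_probs) != 2L || any(cfg$ch_count_probs < 0) ||
      sum(cfg$ch_count_probs) > 1)
    stop("invalid field 'ch_count_probs'")
  for (f in c("ch_vaf_range", "somatic_vaf_range", "artifact_vaf_range")) {
    v <- cfg[[f]]
    if (length(v) != 2L || any(v <= 0) || any(v > 1) || v[1] > v[2])
      stop(sprintf("invalid field '%s'", f))
  }
  .stopifnot_scalar_number(cfg$n_germline, "n_germline", 0)
  .stopifnot_scalar_number(cfg$germline_pathogenic_frac, "germline_pathogenic_frac", 0, 1)
  .stopifnot_scalar_number(cfg$n_somatic, "n_somatic", 0)
  .stopifnot_scalar_number(cfg$error_rate, "error_rate", 0, 1)
  .stopifnot_scalar_number(cfg$dispersion, "dispersion", 0, 0.999)
  .stopifnot_scalar_number(cfg$tumor_fraction, "tumor_fraction", 0, 1)
  .stopifnot_scalar_number(cfg$artifact_frac, "artifact_frac", 0, 1)
  .stopifnot_scalar_number(cfg$n_artifacts, "n_artifacts", 0)
  .stopifnot_scalar_number(cfg$ch_pool_size, "ch_pool_size", 1)
  .stopifnot_scalar_number(cfg$n_kb, "n_kb", 0)
  for (f in c("depth_pbl", "depth_cfdna", "depth_tumor"))
    .stopifnot_scalar_number(cfg[[f]], f, 1)
  class(cfg) <- "ch_sim_config"
  cfg
}

# alt-read draw: binomial, or beta-binomial when rho > 0
.draw_alt <- function(depth, p_eff, rho) {
  if (rho > 0) {
    pos <- p_eff > 0 & p_eff < 1
    p <- p_eff
    if (any(pos)) {
      a <- p_eff[pos] * (1 - rho) / rho
      b <- (1 - p_eff[pos]) * (1 - rho) / rho
      p[pos] <- stats::rbeta(sum(pos), a, b)
    }
    stats::rbinom(length(depth), depth, p)
  } else {
    stats::rbinom(length(depth), depth, p_eff)
  }
}

.rloguniform <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Simulate a paired cfDNA/PBL/tumor cohort with ground truth
#'
#' @param config A [ch_sim_config()] object.
#' @param seed Integer seed; runs are reproducible byte-for-byte.
#' @return List of class `ch_sim` with elements `patients` (patient_id,
#'   cancer_type, age, has_tumor), `observations` (wide per-variant call
#'   table: cfDNA always called, PBL columns `NA` when not called there),
#'   `tumor_calls` (per-patient tumor somatic calls), `annotations`,
#'   `truth` (per planted variant: true class and per-compartment VAFs, plus
#'   whether it surfaced in the cfDNA call table), `kb` (actionable subset of
#'   the CH site pool), `config`, `seed`.
#' @export
simulate_cohort <- function(config = ch_sim_config(), seed = 1) {
  cfg <- config
  if (!inherits(cfg, "ch_sim_config")) stop("config must be a ch_sim_config")
  set.seed(seed)
  n <- cfg$n_patients

  genes <- c(names(cfg$hot_genes), sprintf("GENE%02d", seq_len(cfg$n_other_genes)))
  gene_w <- c(cfg$hot_genes,
              rep((1 - sum(cfg$hot_genes)) / cfg$n_other_genes, cfg$n_other_genes))

  empty_obs <- data.frame(patient_id = character(0), chrom = character(0),
                          pos = integer(0), ref = character(0), alt = character(0),
                          cfdna_depth = integer(0), cfdna_alt = integer(0),
                          pbl_depth = integer(0), pbl_alt = integer(0))
  if (n == 0L) {
    out <- list(patients = data.frame(patient_id = character(0),
                                      cancer_type = character(0), age = integer(0),
                                      has_tumor = logical(0)),
                observations = empty_obs,
                tumor_calls = empty_obs[, 1:5],
                annotations = data.frame(), truth = data.frame(),
                kb = data.frame(), config = cfg, seed = seed)
    class(out) <- "ch_sim"
    return(out)
  }

  bases <- c("A", "C", "G", "T")
  new_sites <- function(k, offset) {
    ref_i <- sample.int(4L, k, replace = TRUE)
    alt_i <- (ref_i + sample.int(3L, k, replace = TRUE) - 1L) %% 4L + 1L
    data.frame(chrom = paste0("chr", sample(1:22, k, replace = TRUE)),
               pos = offset + seq_len(k), ref = bases[ref_i], alt = bases[alt_i],
               stringsAsFactors = FALSE)
  }

  # CH site pool (gene-weighted) and fixed artifact sites
  pool <- new_sites(cfg$ch_pool_size, 1e7)
  pool$gene <- sample(genes, cfg$ch_pool_size, replace = TRUE, prob = gene_w)
  pool$consequence <- sample(c("missense", "nonsense", "splice"),
                             cfg$ch_pool_size, replace = TRUE,
                             prob = c(0.7, 0.2, 0.1))
  artifacts <- if (cfg$n_artifacts > 0) {
    a <- new_sites(cfg$n_artifacts, 4e7)
    a$gene <- sample(genes, cfg$n_artifacts, replace = TRUE, prob = gene_w)
    a$consequence <- "missense"
    a
  } else NULL

  patients <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    cancer_type = sample(c("LUAD", "COAD", "BRCA", "STAD", "LIHC", "ESCA"),
                         n, replace = TRUE),
    age = sample(cfg$age_range[1]:cfg$age_range[2], n, replace = TRUE),
    stringsAsFactors = FALSE)
  patients$has_tumor <- stats::runif(n) < cfg$tumor_fraction

  carrier <- stats::runif(n) < stats::plogis(cfg$prev_intercept +
                                             cfg$prev_slope * patients$age)

  plant <- list(); pi <- 0L
  add <- function(df) { pi <<- pi + 1L; plant[[pi]] <<- df }

  # CH variants
  carr_idx <- which(carrier)
  if (length(carr_idx) > 0L) {
    u <- stats::runif(length(carr_idx))
    k <- ifelse(u < cfg$ch_count_probs[1], 1L,
                ifelse(u < sum(cfg$ch_count_probs), 2L,
                       3L + stats::rgeom(length(carr_idx), 0.5)))
    rows <- unlist(lapply(seq_along(carr_idx),
                          function(i) sample.int(cfg$ch_pool_size, k[i])))
    ch <- pool[rows, ]
    ch$patient_id <- rep(patients$patient_id[carr_idx], k)
    ch$class <- "CH"
    ch$vaf <- .rloguniform(nrow(ch), cfg$ch_vaf_range)
    ch$clinvar <- "none"
    add(ch)
  }

  # recurrent artifacts planted in a fixed fraction of CH carriers
  if (!is.null(artifacts) && length(carr_idx) > 0L) {
    n_plant <- max(1L, round(cfg$artifact_frac * length(carr_idx)))
    for (j in seq_len(cfg$n_artifacts)) {
      tgt <- carr_idx[sample.int(length(carr_idx), min(n_plant, length(carr_idx)))]
      af <- artifacts[rep(j, length(tgt)), ]
      af$patient_id <- patients$patient_id[tgt]
      af$class <- "artifact"
      af$vaf <- .rloguniform(length(tgt), cfg$artifact_vaf_range)
      af$clinvar <- "none"
      add(af)
    }
  }

  # germline variants (unique per patient)
  if (cfg$n_germline > 0) {
    ng <- n * cfg$n_germline
    g <- new_sites(ng, 2e7)
    g$gene <- sample(genes, ng, replace = TRUE)
    g$consequence <- "missense"
    g$patient_id <- rep(patients$patient_id, each = cfg$n_germline)
    g$class <- "germline"
    g$vaf <- stats::rbeta(ng, cfg$germline_beta[1], cfg$germline_beta[2])
    g$clinvar <- ifelse(stats::runif(ng) < cfg$germline_pathogenic_frac,
                        "pathogenic", "none")
    add(g)
  }

  # somatic variants (unique per patient; true PBL VAF 0)
  if (cfg$n_somatic > 0) {
    ns <- n * cfg$n_somatic
    s <- new_sites(ns, 3e7)
    s$gene <- sample(genes, ns, replace = TRUE)
    s$consequence <- sample(c("missense", "nonsense"), ns, replace = TRUE,
                            prob = c(0.8, 0.2))
    s$patient_id <- rep(patients$patient_id, each = cfg$n_somatic)
    s$class <- "somatic"
    s$vaf <- .rloguniform(ns, cfg$somatic_vaf_range)
    s$clinvar <- "none"
    add(s)
  }

  tr <- .rbind_all(plant)
  e <- cfg$error_rate
  vaf_pbl <- ifelse(tr$class == "somatic", 0, tr$vaf)
  vaf_cf <- ifelse(tr$class == "somatic", tr$vaf,
                   pmin(tr$vaf * (1 + cfg$compartment_shift), 0.999))
  vaf_tum <- ifelse(tr$class == "somatic",
                    pmin(tr$vaf * cfg$tumor_vaf_mult, cfg$tumor_vaf_cap), 0)

  cf_depth <- stats::rpois(nrow(tr), cfg$depth_cfdna)
  pb_depth <- stats::rpois(nrow(tr), cfg$depth_pbl)
  cf_alt <- .draw_alt(cf_depth, vaf_cf + e * (1 - vaf_cf), cfg$dispersion)
  pb_alt <- .draw_alt(pb_depth, vaf_pbl + e * (1 - vaf_pbl), cfg$dispersion)

  truth <- data.frame(patient_id = tr$patient_id, chrom = tr$chrom, pos = tr$pos,
                      ref = tr$ref, alt = tr$alt, gene = tr$gene,
                      true_class = tr$class,
                      vaf_cfdna = vaf_cf, vaf_pbl = vaf_pbl, vaf_tumor = vaf_tum,
                      in_cfdna_calls = cf_alt > 0L,
                      stringsAsFactors = FALSE, row.names = NULL)

  called <- cf_alt > 0L
  observations <- data.frame(patient_id = tr$patient_id[called],
                             chrom = tr$chrom[called], pos = tr$pos[called],
                             ref = tr$ref[called], alt = tr$alt[called],
                             cfdna_depth = cf_depth[called],
                             cfdna_alt = cf_alt[called],
                             pbl_depth = ifelse(pb_alt[called] > 0L,
                                                pb_depth[called], NA_integer_),
                             pbl_alt = ifelse(pb_alt[called] > 0L,
                                              pb_alt[called], NA_integer_),
                             stringsAsFactors = FALSE, row.names = NULL)

  # matched-tumor somatic calls, for the fraction of patients with tumor data
  som <- tr$class == "somatic" &
    tr$patient_id %in% patients$patient_id[patients$has_tumor]
  tum_depth <- stats::rpois(sum(som), cfg$depth_tumor)
  tum_alt <- .draw_alt(tum_depth, vaf_tum[som] + e * (1 - vaf_tum[som]),
                       cfg$dispersion)
  tumor_calls <- data.frame(patient_id = tr$patient_id[som][tum_alt > 0L],
                            chrom = tr$chrom[som][tum_alt > 0L],
                            pos = tr$pos[som][tum_alt > 0L],
                            ref = tr$ref[som][tum_alt > 0L],
                            alt = tr$alt[som][tum_alt > 0L],
                            stringsAsFactors = FALSE, row.names = NULL)

  # annotation table: one row per distinct planted site
  ann_src <- tr[!duplicated(.df_key(tr)), c(KEY_COLS, "gene", "consequence", "clinvar")]
  annotations <- data.frame(ann_src[, KEY_COLS], gene = ann_src$gene,
                            consequence = ann_src$consequence,
                            maf_gnomad = NA_real_, maf_exac = NA_real_,
                            in_dbsnp = FALSE, in_cosmic = FALSE, is_hla = FALSE,
                            in_blacklist = FALSE, clinvar = ann_src$clinvar,
                            stringsAsFactors = FALSE, row.names = NULL)

  # knowledge base: actionable sites drawn among planted CH sites, so overlap
  # analytics on simulated cohorts have structure
  ch_sites <- tr[tr$class == "CH", KEY_COLS]
  ch_sites <- ch_sites[!duplicated(.df_key(ch_sites)), , drop = FALSE]
  kb_rows <- sample.int(max(nrow(ch_sites), 1L), min(cfg$n_kb, nrow(ch_sites)))
  kb <- merge(ch_sites[kb_rows, , drop = FALSE],
              tr[!duplicated(.df_key(tr)), c(KEY_COLS, "gene")], by = KEY_COLS)
  kb$assertion <- rep("actionable (synthetic knowledge base)", nrow(kb))
  row.names(kb) <- NULL

  out <- list(patients = patients, observations = observations,
              tumor_calls = tumor_calls, annotations = annotations,
              truth = truth, kb = kb, config = cfg, seed = seed)
  class(out) <- "ch_sim"
  out
}

#' @export
print.ch_sim <- function(x, ...) {
  cat(sprintf("Synthetic paired cohort: %d patients, %d called cfDNA variants, seed %d\n",
              nrow(x$patients), nrow(x$observations), x$seed))
  if (nrow(x$truth) > 0L) print(table(x$truth$true_class))
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' Emits `patients.tsv`, `calls.tsv` (wide observations), `tumor_calls.tsv`,
#' `annotations.tsv`, `truth.tsv`, `kb.tsv` and a JSON echo of the
#' configuration into `dir`.
#'
#' @param sim A `ch_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) utils::write.table(df, file.path(dir, name), sep = "\t",
                                              quote = FALSE, row.names = FALSE)
  wr(sim$patients, "patients.tsv")
  wr(sim$observations, "calls.tsv")
  wr(sim$tumor_calls, "tumor_calls.tsv")
  wr(sim$annotations, "annotations.tsv")
  wr(sim$truth, "truth.tsv")
  wr(sim$kb, "kb.tsv")
  cfg <- sim$config; class(cfg) <- NULL
  jsonlite::write_json(c(cfg, list(seed = sim$seed)),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Score pipeline recovery against simulator ground truth
#'
#' Joins the truth table to a pipeline result and reports the per-class
#' confusion matrix and the recovery metrics: CH sensitivity (overall and for
#' true blood VAF >= `vaf_cut`), germline-to-CH and somatic-to-CH leakage,
#' and the artifact removal rate (fraction of planted artifact variants
#' removed by the carrier-ratio filter). Truth records never surfacing in the
#' cfDNA call table are counted as documented omissions (and as misses for
#' sensitivity).
#'
#' @param truth Truth table from [simulate_cohort()].
#' @param result A [ch_pipeline()] object run on the same cohort.
#' @param vaf_cut VAF threshold for the high-VAF sensitivity stratum.
#' @return List with `confusion`, `ch_sensitivity`, `ch_sensitivity_highvaf`,
#'   `germline_to_ch`, `somatic_to_ch`, `artifact_removal_rate`, `omissions`.
#' @export
evaluate_calls <- function(truth, result, vaf_cut = 0.02) {
  classified <- result$classified
  # truth patients may be absent from the classified table (all their variants
  # omitted from the cfDNA calls); the reverse is a universe mismatch
  if (length(setdiff(unique(classified$patient_id),
                     unique(truth$patient_id))) > 0L)
    stop("patient-set mismatch between truth and classified tables")
  tid <- paste(truth$patient_id, .df_key(truth), sep = "|")
  cid <- paste(classified$patient_id, .df_key(classified), sep = "|")
  idx <- match(tid, cid)
  assigned <- ifelse(is.na(idx), "OMITTED", classified$label[idx])
  confusion <- table(true_class = truth$true_class, assigned = assigned)

  is_ch <- truth$true_class == "CH"
  called_ch <- assigned == "CH"
  hi <- truth$vaf_cfdna >= vaf_cut
  removed_keys <- .df_key(result$funnel$removed_carrier_variants)
  art_keys <- unique(.df_key(truth[truth$true_class == "artifact", , drop = FALSE]))

  list(confusion = confusion,
       ch_sensitivity = if (any(is_ch)) mean(called_ch[is_ch]) else NA_real_,
       ch_sensitivity_highvaf = if (any(is_ch & hi)) mean(called_ch[is_ch & hi])
                                else NA_real_,
       germline_to_ch = if (any(truth$true_class == "germline"))
         mean(called_ch[truth$true_class == "germline"]) else NA_real_,
       somatic_to_ch = if (any(truth$true_class == "somatic"))
         mean(called_ch[truth$true_class == "somatic"]) else NA_real_,
       artifact_removal_rate = if (length(art_keys) > 0)
         mean(art_keys %in% removed_keys) else NA_real_,
       omissions = sum(is.na(idx)))
}
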