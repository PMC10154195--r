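## Reproducible simulation studies: each function regenerates a synthetic
## cohort under the study conditions, runs the pipeline end to end and
## measures a calibration or recovery property. Problem sizes are the
## package's declared study conditions (see the methods vignette).

#' Type-I error and genomic inflation of the null burden scan
#'
#' Simulates a cohort with no gene effects, builds the proband outcome
#' through the ancestry and relatedness filters, qualifies PTVs and scans
#' every eligible gene, then reports the fraction of nominal rejections,
#' the genomic inflation factor and a Kolmogorov-Smirnov uniformity check
#' of the p-values.
#'
#' The default of 10,000 genes is set by the genomic inflation factor, not
#' the rejection rate: the median of n chi-squared statistics is noisy
#' (lambda has standard deviation ~0.074 at 1,000 genes but ~0.023 at
#' 10,000), so a 0.95-1.05 acceptance band needs the larger scan.
#'
#' @param n_genes Number of simulated null genes.
#' @param n_individuals Cohort size.
#' @param seed Integer seed.
#' @param alpha Nominal level for the rejection count.
#' @return List: `n_tested`, `type1`, `lambda`, `ks_p`, `results`.
#' @export
study_null_calibration <- function(n_genes = 10000, n_individuals = 6000,
                                   seed = 1, alpha = 0.05) {
  cfg <- sim_config(n_individuals = n_individuals, n_genes = n_genes,
                    carrier_freq_range = c(0.008, 0.01),
                    frac_somatic_genes = 0, age_range = c(55, 69),
                    repeat_assessment_rate = 0, seed = seed)
  models <- simulate_gene_models(cfg)
  vg <- simulate_variants_and_genotypes(models, cfg)
  raw <- simulate_survival(vg$genotypes, vg$truth, cfg)
  kin <- simulate_kinship(vg$genotypes$samples, cfg)
  anc <- apply_ancestry_filter(raw$sample_id, raw)
  unrel <- exclude_related(anc, kin, seed = substream_seed(seed, "unrel"))
  base <- raw[raw$sample_id %in% unrel, , drop = FALSE]
  outcome <- build_proband_survival(base)
  qset <- build_qualifying_set(vg$variants, vg$genotypes,
                               outcome$data$sample_id)
  scan <- burden_scan(qset, outcome, covariates = c("baseline_age", "sex"),
                      ph_test = FALSE)
  scan <- scan[scan$converged, , drop = FALSE]
  chi2 <- stats::qchisq(scan$p, df = 1, lower.tail = FALSE)
  list(n_tested = nrow(scan),
       type1 = mean(scan$p < alpha),
       lambda = genomic_lambda(chi2)$lambda,
       ks_p = stats::ks.test(scan$p, "punif")$p.value,
       results = scan)
}

#' Confidence-interval coverage for a planted hazard ratio
#'
#' Replicates a single-gene cohort with a known carrier hazard ratio,
#' runs PTV qualification, burden collapsing and the Cox fit on each
#' replicate, and reports how often the Wald 95% interval covers the truth.
#'
#' @param n_reps Number of replicates.
#' @param n_individuals Cohort size per replicate.
#' @param carrier_freq Qualifying-PTV carrier frequency.
#' @param hr True carrier hazard ratio.
#' @param seed Integer seed.
#' @return List: `coverage`, `mean_events_frac`, `mean_hr`, `n_reps`.
#' @export
study_hr_recovery <- function(n_reps = 200, n_individuals = 20000,
                              carrier_freq = 0.003, hr = 2.5, seed = 1) {
  hits <- logical(n_reps)
  evf <- numeric(n_reps)
  hrs <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(n_individuals = n_individuals, n_genes = 1,
                      carrier_freq_range = rep(carrier_freq, 2),
                      true_log_hr = c(G0001 = log(hr)),
                      frac_somatic_genes = 0, age_range = c(48, 68),
                      repeat_assessment_rate = 0,
                      ancestry_other_rate = 0, genotype_missing_rate = 0,
                      seed = substream_seed(seed, paste0("hr_rep", r)))
    models <- simulate_gene_models(cfg)
    vg <- simulate_variants_and_genotypes(models, cfg)
    raw <- simulate_survival(vg$genotypes, vg$truth, cfg)
    outcome <- build_proband_survival(raw)
    qset <- build_qualifying_set(vg$variants, vg$genotypes,
                                 outcome$data$sample_id)
    g <- collapse_gene(qset, "G0001", outcome$data$sample_id)
    des <- outcome_design(outcome, c("baseline_age", "sex"))
    fit <- fit_cox(outcome$data$time, outcome$data$event, g$g, des$Z)
    lo <- fit$beta - 1.96 * fit$se
    hi <- fit$beta + 1.96 * fit$se
    hits[r] <- fit$converged && lo <= log(hr) && log(hr) <= hi
    evf[r] <- mean(outcome$data$event)
    hrs[r] <- fit$hr
  }
  list(coverage = mean(hits), mean_events_frac = mean(evf),
       mean_hr = mean(hrs, na.rm = TRUE), n_reps = n_reps)
}

#' Confidence-interval coverage for a planted phenome odds ratio
#'
#' Replicates the phenome generator with a planted carrier odds ratio on a
#' rare binary trait and reports Wald 95% coverage of the logistic burden
#' estimate.
#'
#' @param n_reps Number of replicates.
#' @param n_individuals Cohort size per replicate.
#' @param prevalence Baseline trait prevalence.
#' @param or True carrier odds ratio.
#' @param carrier_freq Carrier frequency of the planted gene.
#' @param seed Integer seed.
#' @return List: `coverage`, `mean_or`, `n_reps`.
#' @export
study_or_recovery <- function(n_reps = 200, n_individuals = 50000,
                              prevalence = 0.01, or = 5,
                              carrier_freq = 0.005, seed = 1) {
  hits <- logical(n_reps)
  ors <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(n_individuals = n_individuals, n_genes = 1,
                      carrier_freq_range = rep(carrier_freq, 2),
                      frac_somatic_genes = 0,
                      phenome_params = list(n_binary = 2, n_quant = 3,
                                            planted_gene = "G0001",
                                            planted_or = or,
                                            planted_beta = -0.4,
                                            prevalence_planted = prevalence),
                      seed = substream_seed(seed, paste0("or_rep", r)))
    models <- simulate_gene_models(cfg)
    vg <- simulate_variants_and_genotypes(models, cfg)
    phen <- simulate_phenome(vg$genotypes, cfg, vg$truth)
    g <- as.integer(vg$genotypes$samples %in%
                      vg$truth$carriers$sample_id)
    res <- fit_logistic(phen$phenotypes$bin_planted, g)
    lo <- res$effect - 1.96 * res$se
    hi <- res$effect + 1.96 * res$se
    hits[r] <- res$converged && !res$separated &&
      lo <= log(or) && log(or) <= hi
    ors[r] <- exp(res$effect)
  }
  list(coverage = mean(hits), mean_or = mean(ors), n_reps = n_reps)
}

#' Germline versus somatic carrier VAF contrast
#'
#' Simulates a cohort with both germline and somatic genes at the given
#' read depth and summarises carrier variant allele fractions per origin.
#'
#' @param n_individuals Cohort size.
#' @param n_genes Number of genes (half somatic).
#' @param read_depth_mean Mean site depth.
#' @param seed Integer seed.
#' @return List: `germline_mean_vaf`, `somatic_mean_vaf`, carrier counts.
#' @export
study_vaf_contrast <- function(n_individuals = 8000, n_genes = 10,
                               read_depth_mean = 30, seed = 1) {
  cfg <- sim_config(n_individuals = n_individuals, n_genes = n_genes,
                    carrier_freq_range = c(0.006, 0.01),
                    frac_somatic_genes = 0.5,
                    read_depth_mean = read_depth_mean, seed = seed)
  models <- simulate_gene_models(cfg)
  vg <- simulate_variants_and_genotypes(models, cfg)
  qual <- vg$variants[vg$variants$qualifying_truth, c("variant_id", "gene")]
  obs <- dplyr::inner_join(vg$genotypes$calls, qual, by = "variant_id") |>
    dplyr::inner_join(vg$truth$genes[, c("gene", "origin")], by = "gene")
  vaf <- compute_vaf(obs$ad_alt, obs$dp - obs$ad_alt)
  list(germline_mean_vaf = mean(vaf[obs$origin == "germline"]),
       somatic_mean_vaf = mean(vaf[obs$origin == "somatic"]),
       n_germline = sum(obs$origin == "germline"),
       n_somatic = sum(obs$origin == "somatic"))
}

#' Phasing classification accuracy on simulated read pairs
#'
#' Simulates read-pair evidence for alternating germline and somatic
#' carriers and scores [classify_origin()] against the known origin.
#'
#' @param n_carriers Number of carriers (half of each origin).
#' @param n_fragments Informative fragments per carrier.
#' @param error_rate Flat substitution error rate.
#' @param true_vaf Somatic clone VAF.
#' @param seed Integer seed.
#' @return List: `accuracy_decided`, `frac_decided`, `n_carriers`.
#' @export
study_phasing_accuracy <- function(n_carriers = 40, n_fragments = 40,
                                   error_rate = 0, true_vaf = 0.3,
                                   seed = 1) {
  cfg <- sim_config(seed = seed, error_rate = error_rate)
  calls <- character(n_carriers)
  truth <- character(n_carriers)
  for (i in seq_len(n_carriers)) {
    origin <- if (i %% 2 == 0) "somatic" else "germline"
    truth[i] <- if (origin == "somatic") "somatic" else "germline_consistent"
    reads <- simulate_read_pairs(sprintf("C%04d", i), "ptv1", "snp1",
                                 origin, cfg, n_fragments = n_fragments,
                                 true_vaf = true_vaf)
    ev <- find_informative_pairs(reads, "ptv1", "snp1")
    calls[i] <- classify_origin(ev, min_support = 2,
                                error_rate = error_rate)$origin_call
  }
  decided <- calls != "inconclusive"
  list(accuracy_decided = if (any(decided)) {
         mean(calls[decided] == truth[decided])
       } else NA_real_,
       frac_decided = mean(decided), n_carriers = n_carriers)
}
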