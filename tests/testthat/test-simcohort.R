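test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(n_individuals = 300, n_genes = 10, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$models, b$models)
  expect_identical(a$variants, b$variants)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$raw_pheno, b$raw_pheno)
  expect_identical(a$phenome$phenotypes, b$phenome$phenotypes)
  # labeled substreams: regenerating one component alone gives the same draw
  expect_identical(simulate_gene_models(cfg), a$models)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(carrier_freq_range = c(0.001, 0.05)), "0.01")
  expect_error(sim_config(frac_somatic_genes = 1.2), "fraction")
  expect_error(sim_config(true_log_hr = 0.5), "named")
})

test_that("pLI flagging matches its binomial expectation", {
  cfg <- sim_config(n_individuals = 10, n_genes = 1000, pli_frac = 0.15,
                    seed = 5)
  models <- simulate_gene_models(cfg)
  n_flag <- sum(models$high_pli)
  expect_lt(abs(n_flag - 150), 3 * sqrt(1000 * 0.15 * 0.85) + 1)
})

test_that("carrier frequencies and VAF means match configuration", {
  cfg <- sim_config(n_individuals = 8000, n_genes = 12,
                    carrier_freq_range = c(0.004, 0.01),
                    frac_somatic_genes = 0.5, seed = 21)
  models <- simulate_gene_models(cfg)
  vg <- simulate_variants_and_genotypes(models, cfg)
  qual <- vg$variants$variant_id[vg$variants$qualifying_truth]
  by_gene <- vg$truth$carriers |> dplyr::count(gene)
  chk <- dplyr::inner_join(by_gene, vg$truth$genes, by = "gene")
  # empirical carrier counts within 3 binomial sd of the configured frequency
  expect_true(all(abs(chk$n - 8000 * chk$carrier_freq) <=
                    3 * sqrt(8000 * chk$carrier_freq *
                               (1 - chk$carrier_freq)) + 1))
  calls <- vg$genotypes$calls[vg$genotypes$calls$variant_id %in% qual, ]
  ann <- vg$variants[vg$variants$qualifying_truth, c("variant_id", "gene")]
  calls <- dplyr::inner_join(calls, ann, by = "variant_id") |>
    dplyr::inner_join(vg$truth$genes[, c("gene", "origin")], by = "gene")
  vaf <- calls$ad_alt / calls$dp
  m_germ <- mean(vaf[calls$origin == "germline"])
  m_som <- mean(vaf[calls$origin == "somatic"])
  expect_gt(sum(calls$origin == "germline"), 50)
  expect_true(m_germ > 0.48 && m_germ < 0.52)
  # somatic true VAF ~ Uniform(0.05, 0.40): mean 0.225
  expect_true(m_som > 0.18 && m_som < 0.27)
})

test_that("decoy variants land on the far side of every filter rule", {
  cfg <- sim_config(n_individuals = 2000, n_genes = 6, seed = 2)
  co <- simulate_cohort(cfg)
  v <- co$variants
  expect_true(any(v$consequence == "missense"))
  expect_true(any(v$consequence == "synonymous"))
  expect_true(any(v$consequence %in% c("stop_gained", "frameshift") &
                    v$distance_to_transcript_end < 50))
  expect_true(any(!v$canonical))
  # shared-position pair -> multi-allelic once written to VCF
  multi <- v |> dplyr::count(chrom, pos, ref) |> dplyr::filter(n > 1)
  expect_gte(nrow(multi), 1)
  # common decoy: MAF >= 1% in the full cohort
  mafs <- ptvsurv:::compute_maf_all(co$genotypes, co$genotypes$samples)
  common_ptv <- dplyr::inner_join(
    mafs, v[v$consequence %in% c("stop_gained", "frameshift") & v$canonical &
              !v$qualifying_truth & v$distance_to_transcript_end >= 50, ],
    by = "variant_id")
  expect_true(any(common_ptv$maf >= 0.01))
})

test_that("survival generator respects degenerate censoring and effects", {
  cfg <- sim_config(n_individuals = 400, n_genes = 2, seed = 9,
                    age_range = c(40, 41))
  models <- simulate_gene_models(cfg)
  vg <- simulate_variants_and_genotypes(models, cfg)
  raw <- simulate_survival(vg$genotypes, vg$truth, cfg)
  tr <- attr(raw, "truth")
  # censor age ~53 here; with median death near 80 nearly everyone is censored
  expect_lt(mean(!is.na(raw$death_age[raw$instance == 0])), 0.1)
  expect_true(all(tr$death_age > 0))
  # all-censored subset: KM curve stays at 1
  base <- raw[raw$instance == 0 & is.na(raw$death_age), ]
  out <- build_proband_survival(base)
  km <- km_estimate(out$data$time, out$data$event)
  expect_true(all(km$surv == 1))
})

test_that("parental transmission gives one carrier parent per germline carrier", {
  cfg <- sim_config(n_individuals = 3000, n_genes = 3, seed = 13,
                    frac_somatic_genes = 0,
                    true_log_hr = c(G0001 = log(3)),
                    carrier_freq_range = c(0.008, 0.01))
  co <- simulate_cohort(cfg)
  carriers <- co$truth$carriers$sample_id[co$truth$carriers$gene == "G0001"]
  base <- co$raw_pheno[co$raw_pheno$instance == 0, ]
  # carrier parents inherit the hazard: carriers' parents die younger on
  # average than non-carriers' (pooled father+mother reported death ages)
  dead_ages <- function(ids) {
    b <- base[base$sample_id %in% ids, ]
    c(b$father_age[b$father_status == "dead"],
      b$mother_age[b$mother_status == "dead"])
  }
  expect_lt(mean(dead_ages(carriers), na.rm = TRUE),
            mean(dead_ages(setdiff(base$sample_id, carriers)), na.rm = TRUE))
})

test_that("phenome contains both sides of the phenotype filters", {
  cfg <- sim_config(n_individuals = 1500, n_genes = 2, seed = 4)
  co <- simulate_cohort(cfg)
  ph <- co$phenome
  expect_equal(sum(ph$phenotypes$bin_rare99), 99)
  expect_equal(sum(!is.na(ph$phenotypes$quant_sparse499)), 499)
  x <- ph$phenotypes$quant_outlier
  expect_true(any(abs(x - mean(x)) > 5 * sd(x)))
  expect_true(all(c("primary", "secondary", "death") %in% ph$codes$source))
})
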