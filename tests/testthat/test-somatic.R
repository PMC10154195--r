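test_that("VAF is the alt-read fraction with zero-depth rejected", {
  expect_equal(compute_vaf(12, 12), 0.5)
  expect_equal(compute_vaf(6, 19), 0.24)
  expect_equal(compute_vaf(c(1, 3), c(3, 1)), c(0.25, 0.75))
  expect_error(compute_vaf(0, 0), "zero read depth")
})

test_that("gene VAF summaries separate germline from somatic carriers", {
  cfg <- sim_config(n_individuals = 6000, n_genes = 8,
                    carrier_freq_range = c(0.006, 0.01),
                    frac_somatic_genes = 0.5, read_depth_mean = 30,
                    seed = 19)
  models <- simulate_gene_models(cfg)
  vg <- simulate_variants_and_genotypes(models, cfg)
  qual <- vg$variants[vg$variants$qualifying_truth,
                      c("variant_id", "gene")]
  obs <- dplyr::inner_join(vg$genotypes$calls, qual, by = "variant_id")
  germ <- vg$truth$genes$gene[vg$truth$genes$origin == "germline"]
  som <- vg$truth$genes$gene[vg$truth$genes$origin == "somatic"]
  g_means <- vapply(germ, function(gn) {
    summarize_gene_vaf(obs, gn)$mean_vaf
  }, numeric(1))
  s_means <- vapply(som, function(gn) {
    summarize_gene_vaf(obs, gn)$mean_vaf
  }, numeric(1))
  expect_true(all(g_means > 0.45 & g_means < 0.55))
  expect_true(all(s_means < 0.35))
  one <- obs[1, ]
  expect_equal(summarize_gene_vaf(one, one$gene)$mean_vaf,
               one$ad_alt / one$dp)
  expect_error(summarize_gene_vaf(obs, "ABSENT"), "no VAF observations")
})

test_that("informative-pair extraction counts fragments once", {
  reads <- tibble::tibble(
    sample_id = c("A", "A", "A", "A", "B"),
    fragment_id = c("f1", "f1", "f2", "f3", "f1"),  # f1 = mate pair
    ptv = "ptv1",
    ptv_allele = c("alt", "alt", "ref", "alt", "ref"),
    snp = "snp1",
    snp_allele = c("ref", "ref", "alt", "ref", "alt"))
  ev <- find_informative_pairs(reads, "ptv1", "snp1")
  a <- ev[ev$sample_id == "A", ]
  expect_equal(a$n21, 2L)  # f1 once + f3
  expect_equal(a$n12, 1L)
  # conflicting mates are discarded
  reads2 <- tibble::tibble(sample_id = "C", fragment_id = c("f1", "f1"),
                           ptv = "ptv1", ptv_allele = c("alt", "ref"),
                           snp = "snp1", snp_allele = c("ref", "ref"))
  ev2 <- find_informative_pairs(reads2, "ptv1", "snp1")
  expect_equal(nrow(ev2), 0)
  # no spanning fragments -> empty evidence
  empty <- find_informative_pairs(reads, "ptv1", character(0))
  expect_equal(nrow(empty), 0)
  expect_s3_class(empty, "read_pair_evidence")
})

test_that("origin classification reproduces the phasing decision rule", {
  ev <- tibble::tibble(
    sample_id = c("a", "b", "c", "d", "e"),
    ptv = "p", snp = "s",
    n11 = c(10, 0, 1, 0, 5),
    n12 = c(8, 9, 0, 0, 0),
    n21 = c(5, 7, 1, 0, 0),
    n22 = c(0, 0, 1, 0, 4))
  out <- classify_origin(ev, min_support = 2)
  expect_equal(out$origin_call,
               c("somatic",               # (3) with (1)
                 "germline_consistent",   # clean opposite haplotypes
                 "inconclusive",          # below support
                 "inconclusive",          # no reads at all
                 "germline_consistent"))  # clean same-label haplotypes
  # invariance under swapping the SNP allele labels
  swapped <- dplyr::rename(ev, n11 = "n12", n12 = "n11",
                           n21 = "n22", n22 = "n21")
  out2 <- classify_origin(swapped, min_support = 2)
  expect_equal(out2$origin_call, out$origin_call)
  # exhaustive scan over small count patterns: the rule and only the rule
  grid <- expand.grid(n11 = 0:3, n12 = 0:3, n21 = 0:3, n22 = 0:3)
  grid$sample_id <- "x"
  res <- classify_origin(grid, min_support = 2)
  manual <- with(grid, ifelse((n21 >= 2 & n11 >= 2) | (n22 >= 2 & n12 >= 2),
                              "somatic", NA))
  expect_equal(res$origin_call == "somatic", !is.na(manual))
})

test_that("error-free simulated read pairs classify perfectly", {
  cfg <- sim_config(seed = 33, error_rate = 0)
  calls <- purrr::map_chr(1:25, function(i) {
    origin <- if (i %% 2 == 0) "somatic" else "germline"
    reads <- simulate_read_pairs(sprintf("S%02d", i), "ptv1", "snp1",
                                 origin, cfg, n_fragments = 40,
                                 true_vaf = 0.3)
    ev <- find_informative_pairs(reads, "ptv1", "snp1")
    classify_origin(ev, min_support = 2)$origin_call
  })
  truth <- ifelse(seq(1, 25) %% 2 == 0, "somatic", "germline_consistent")
  decided <- calls != "inconclusive"
  expect_true(all(calls[decided] == truth[decided]))
  expect_gt(mean(decided), 0.9)
  # voting across SNPs: somatic evidence wins
  cl <- tibble::tibble(sample_id = "A", ptv = "p",
                       origin_call = c("germline_consistent", "somatic"))
  expect_equal(combine_origin_calls(cl)$origin_call, "somatic")
})

test_that("noisy reads with minimal support stay under 1% misclassification", {
  cfg <- sim_config(seed = 101, error_rate = 0.005)
  n_wrong <- 0
  n_tot <- 200
  for (i in seq_len(n_tot)) {
    origin <- if (i %% 2 == 0) "somatic" else "germline"
    reads <- simulate_read_pairs(sprintf("N%03d", i), "ptv1", "snp1",
                                 origin, cfg, n_fragments = 40,
                                 true_vaf = 0.3)
    ev <- find_informative_pairs(reads, "ptv1", "snp1")
    call <- classify_origin(ev, min_support = 2,
                            error_rate = 0.005)$origin_call
    truth <- if (origin == "somatic") "somatic" else "germline_consistent"
    if (call != "inconclusive" && call != truth) n_wrong <- n_wrong + 1
  }
  expect_lt(n_wrong / n_tot, 0.01)
})
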