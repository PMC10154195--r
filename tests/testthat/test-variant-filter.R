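test_that("multi-allelic splitting preserves alleles and depths", {
  rec <- list(chrom = "1", pos = 100L, ref = "G", alt = c("A", "T"),
              genotypes = tibble::tibble(
                sample_id = c("S1", "S2", "S3", "S4"),
                gt = c("0/1", "1/2", "0/2", "./."),
                ad = c("10,5,0", "3,6,7", "12,0,9", "0,0,0")))
  out <- split_multiallelic(rec)
  expect_length(out, 2)
  # heterozygous-alt in each split record for the 1/2 sample
  expect_equal(out[[1]]$genotypes$gt[2], "0/1")
  expect_equal(out[[2]]$genotypes$gt[2], "0/1")
  expect_equal(out[[2]]$genotypes$gt[3], "0/1")
  expect_equal(out[[1]]$genotypes$gt[4], "./.")
  # alt-depth conservation: split alt depths equal original AD alt entries
  expect_equal(out[[1]]$genotypes$ad, c("10,5", "3,6", "12,0", "0,0"))
  expect_equal(out[[2]]$genotypes$ad, c("10,0", "3,7", "12,9", "0,0"))
  expect_equal(out[[1]]$variant_id, "1-100-G-A")
  # biallelic record passes through as a singleton list
  rec2 <- list(chrom = "2", pos = 5L, ref = "C", alt = "T",
               genotypes = tibble::tibble(sample_id = "S1", gt = "0/1",
                                          ad = "8,9"))
  one <- split_multiallelic(rec2)
  expect_length(one, 1)
  expect_equal(one[[1]]$genotypes$gt, "0/1")
  expect_equal(one[[1]]$genotypes$ad, "8,9")
  # three alts: per-record alt depths sum to the original alt entries
  rec3 <- list(chrom = "3", pos = 9L, ref = "A", alt = c("C", "G", "T"),
               genotypes = tibble::tibble(sample_id = "S1", gt = "1/3",
                                          ad = "2,4,0,6"))
  three <- split_multiallelic(rec3)
  alt_depths <- vapply(three, function(r) {
    as.numeric(strsplit(r$genotypes$ad, ",")[[1]][2])
  }, numeric(1))
  expect_equal(alt_depths, c(4, 0, 6))
  expect_error(split_multiallelic(list(chrom = "1", pos = 1L, ref = "A",
    alt = "T", genotypes = tibble::tibble(sample_id = "S1", gt = "0/1/1",
                                          ad = "1,1"))), "malformed")
})

test_that("PTV classification follows consequence and end-distance rules", {
  rules <- filter_rules()
  ann <- tibble::tibble(
    consequence = c("missense", "stop_gained", "splice_donor", "stop_gained",
                    "synonymous", "frameshift", "splice_acceptor"),
    distance_to_transcript_end = c(1000L, 49L, 5000L, 50L, 10L, 51L, 0L))
  out <- classify_ptv(ann, rules)
  expect_equal(out$ptv_class,
               c("not_ptv", "low_confidence", "high_confidence",
                 "high_confidence", "not_ptv", "high_confidence",
                 "low_confidence"))
  expect_error(classify_ptv(tibble::tibble(consequence = "weird",
                                           distance_to_transcript_end = 1L)),
               "unknown consequence")
})

test_that("MAF uses a folded complete-case denominator", {
  samples <- sprintf("S%03d", 1:1000)
  calls <- tibble::tibble(variant_id = "v1",
                          sample_id = samples[1:3],
                          allele_count = 1L, dp = 30L, ad_alt = 15L)
  gt <- genotype_calls(samples, calls)
  expect_equal(compute_maf(gt, "v1", samples), 3 / 2000)
  # folding above 0.5
  calls2 <- tibble::tibble(variant_id = "v2", sample_id = samples,
                           allele_count = 2L, dp = 30L, ad_alt = 30L)
  calls2$allele_count[1:10] <- 1L
  gt2 <- genotype_calls(samples, calls2)
  expect_equal(compute_maf(gt2, "v2", samples), 10 / 2000)
  # missing genotypes leave the denominator
  gt3 <- genotype_calls(samples, calls,
                        missing = tibble::tibble(variant_id = "v1",
                                                 sample_id = samples[4:503]))
  expect_equal(compute_maf(gt3, "v1", samples), 3 / (2 * 500))
  gt4 <- genotype_calls(samples, calls[0, ],
                        missing = tibble::tibble(variant_id = "v1",
                                                 sample_id = samples))
  expect_error(compute_maf(gt4, "v1", samples), "no non-missing")
  expect_error(compute_maf(gt, "v1", character(0)), "empty")
})

test_that("qualifying set keeps exactly the rare high-confidence canonical PTVs", {
  samples <- sprintf("S%03d", 1:200)
  ann <- tibble::tibble(
    variant_id = c("v_ok", "v_common", "v_missense", "v_nearend", "v_nocanon"),
    gene = "G1", transcript = "T1",
    canonical = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    consequence = c("stop_gained", "stop_gained", "missense", "frameshift",
                    "stop_gained"),
    distance_to_transcript_end = c(900L, 900L, 900L, 10L, 900L))
  calls <- dplyr::bind_rows(
    tibble::tibble(variant_id = "v_ok", sample_id = samples[1:2],
                   allele_count = 1L, dp = 30L, ad_alt = 15L),
    tibble::tibble(variant_id = "v_common", sample_id = samples[1:50],
                   allele_count = 1L, dp = 30L, ad_alt = 15L),
    tibble::tibble(variant_id = "v_missense", sample_id = samples[3],
                   allele_count = 1L, dp = 30L, ad_alt = 15L),
    tibble::tibble(variant_id = "v_nearend", sample_id = samples[4],
                   allele_count = 1L, dp = 30L, ad_alt = 15L),
    tibble::tibble(variant_id = "v_nocanon", sample_id = samples[5],
                   allele_count = 1L, dp = 30L, ad_alt = 15L))
  gt <- genotype_calls(samples, calls)
  qs <- build_qualifying_set(ann, gt, samples)
  expect_equal(qs$variants$variant_id, "v_ok")
  expect_false(qs$variants$singleton)
  expect_equal(qs$log$n_variants[qs$log$step == "no_canonical_annotation"], 1)
  expect_equal(qs$log$n_variants[qs$log$step == "maf_at_or_above_threshold"], 1)
  # full accounting: input = qualifying + each dropped class
  drops <- qs$log$n_variants[qs$log$step != "input"]
  expect_equal(sum(drops), qs$log$n_variants[qs$log$step == "input"])
  # per-sample exome counts: S001 carries v_ok only
  expect_equal(qs$sample_counts$n_ptv[qs$sample_counts$sample_id == "S001"], 1)
})

test_that("filter is monotone in the MAF threshold and order-invariant", {
  cfg <- sim_config(n_individuals = 1000, n_genes = 8, seed = 31)
  co <- simulate_cohort(cfg)
  samples <- co$genotypes$samples
  qs_loose <- build_qualifying_set(co$variants, co$genotypes, samples,
                                   filter_rules(maf_threshold = 0.01))
  qs_tight <- build_qualifying_set(co$variants, co$genotypes, samples,
                                   filter_rules(maf_threshold = 0.002))
  expect_true(all(qs_tight$variants$variant_id %in%
                    qs_loose$variants$variant_id))
  # permuting annotation row order never changes the set
  perm <- co$variants[sample(nrow(co$variants)), ]
  qs_perm <- build_qualifying_set(perm, co$genotypes, samples)
  expect_equal(qs_loose$variants, qs_perm$variants)
  # ground truth: every planted qualifying variant in, every decoy out
  planted <- co$variants$variant_id[co$variants$qualifying_truth]
  carried <- unique(co$genotypes$calls$variant_id)
  expect_true(all(qs_loose$variants$variant_id %in% planted))
  expect_setequal(
    qs_loose$variants$variant_id[qs_loose$variants$n_carriers > 0],
    intersect(planted, carried))
})
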