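#' Configuration for the synthetic biobank cohort generator
#'
#' Bundles every tunable of the synthetic-cohort modules into a single
#' validated object. The defaults emulate a middle-aged, exome-sequenced
#' population cohort: participants recruited at ages 40-69, censored roughly
#' twelve years later, Gompertz mortality with median death age near 80,
#' rare protein-truncating variants (PTVs) at 0.1-1% carrier frequency, and
#' self-reported parental lifespans with realistic rates of adoption,
#' non-response and early parental death.
#'
#' @param n_individuals Number of probands.
#' @param n_genes Number of simulated genes.
#' @param carrier_freq_range Range (pair of fractions, each in (0, 0.01]) from
#'   which each gene's qualifying-PTV carrier frequency is drawn.
#' @param frac_somatic_genes Fraction of genes whose PTV carriers are somatic
#'   (clonal hematopoiesis-like, sub-0.5 variant allele fraction) rather than
#'   germline heterozygotes.
#' @param pli_frac Fraction of genes flagged as highly loss-of-function
#'   intolerant (the pLI > 0.9 analogue).
#' @param true_log_hr Named numeric vector, gene id -> true log hazard ratio
#'   for PTV carriers. Genes not named have log HR 0.
#' @param baseline_hazard Gompertz baseline, `list(shape, rate)` with hazard
#'   `rate * exp(shape * age)` per year. The default
#'   (shape 0.09/yr, rate 4.5e-5/yr) puts the median death age at ~80 years.
#' @param sex_log_hr Additional log hazard for males (applied to probands and
#'   fathers), reflecting the male-female mortality gap.
#' @param age_range Recruitment (baseline) age range in years, uniform.
#' @param parental_params `list(report_missing_rate, adoption_rate,
#'   early_death_rate)`: rates of "do not know" parental answers, childhood
#'   adoption, and forced parental deaths before age 40.
#' @param repeat_assessment_rate Fraction of probands with a repeat assessment
#'   visit (parental answers updated at the later visit).
#' @param ancestry_other_rate Fraction of samples whose ancestry flags
#'   (genetic grouping / self-report) are not both set.
#' @param related_pair_rate Expected number of close-relative pairs per sample.
#' @param genotype_missing_rate Per-call genotype missingness.
#' @param read_depth_mean Mean sequencing depth at variant sites (Poisson).
#' @param error_rate Flat per-base substitution error rate used when
#'   simulating phasing read pairs.
#' @param phenome_params `list(n_binary, n_quant, planted_gene, planted_or,
#'   planted_beta, prevalence_planted)` controlling [simulate_phenome()].
#' @param seed Global integer seed. Every generator derives an independent
#'   substream from it by labeled hashing, so outputs are byte-identical for
#'   a fixed seed and adding a component never perturbs the others.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_individuals = 2000,
                       n_genes = 20,
                       carrier_freq_range = c(0.001, 0.01),
                       frac_somatic_genes = 0.1,
                       pli_frac = 0.15,
                       true_log_hr = numeric(0),
                       baseline_hazard = list(shape = 0.09, rate = 4.5e-5),
                       sex_log_hr = 0.45,
                       age_range = c(40, 69),
                       parental_params = list(report_missing_rate = 0.03,
                                              adoption_rate = 0.013,
                                              early_death_rate = 0.02),
                       repeat_assessment_rate = 0.1,
                       ancestry_other_rate = 0.05,
                       related_pair_rate = 0.005,
                       genotype_missing_rate = 0.001,
                       read_depth_mean = 30,
                       error_rate = 0,
                       phenome_params = list(n_binary = 8, n_quant = 6,
                                             planted_gene = NULL,
                                             planted_or = 5,
                                             planted_beta = -0.4,
                                             prevalence_planted = 0.01),
                       seed = 1L) {
  check_count(n_individuals, "n_individuals")
  check_count(n_genes, "n_genes")
  if (length(carrier_freq_range) != 2 || any(carrier_freq_range <= 0) ||
      any(carrier_freq_range > 0.01) ||
      carrier_freq_range[1] > carrier_freq_range[2]) {
    abort("`carrier_freq_range` must be an increasing pair within (0, 0.01].")
  }
  check_fraction(frac_somatic_genes, "frac_somatic_genes")
  check_fraction(pli_frac, "pli_frac")
  check_fraction(ancestry_other_rate, "ancestry_other_rate")
  check_fraction(genotype_missing_rate, "genotype_missing_rate")
  check_fraction(repeat_assessment_rate, "repeat_assessment_rate")
  check_fraction(error_rate, "error_rate")
  for (nm in c("report_missing_rate", "adoption_rate", "early_death_rate")) {
    check_fraction(parental_params[[nm]], paste0("parental_params$", nm))
  }
  if (!is.numeric(baseline_hazard$shape) || !is.numeric(baseline_hazard$rate) ||
      baseline_hazard$shape <= 0 || baseline_hazard$rate <= 0) {
    abort("`baseline_hazard` must have positive `shape` and `rate`.")
  }
  if (length(true_log_hr) && is.null(names(true_log_hr))) {
    abort("`true_log_hr` must be a named (gene -> log HR) vector.")
  }
  check_count(seed, "seed", positive = FALSE)
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_genes = as.integer(n_genes),
         carrier_freq_range = carrier_freq_range,
         frac_somatic_genes = frac_somatic_genes,
         pli_frac = pli_frac,
         true_log_hr = true_log_hr,
         baseline_hazard = baseline_hazard,
         sex_log_hr = sex_log_hr,
         age_range = age_range,
         parental_params = parental_params,
         repeat_assessment_rate = repeat_assessment_rate,
         ancestry_other_rate = ancestry_other_rate,
         related_pair_rate = related_pair_rate,
         genotype_missing_rate = genotype_missing_rate,
         read_depth_mean = read_depth_mean,
         error_rate = error_rate,
         phenome_params = phenome_params,
         seed = as.integer(seed)),
    class = "sim_config")
}

sample_ids <- function(n) sprintf("S%06d", seq_len(n))
gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate gene models
#'
#' Generates one canonical transcript per gene with a genomic interval,
#' coding length and a high loss-of-function-intolerance flag on a
#' configurable fraction of genes.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `gene`, `transcript`, `chrom`, `tx_start`,
#'   `tx_end`, `coding_length`, `high_pli`.
#' @export
simulate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  with_substream(config$seed, "gene_models", {
    coding_length <- as.integer(round(runif(n, 900, 6000) / 3) * 3)
    tx_start <- as.integer(sample.int(1e8, n, replace = TRUE))
    tibble::tibble(
      gene = gene_ids(n),
      transcript = sprintf("T%04d.1", seq_len(n)),
      chrom = as.character(sample(1:22, n, replace = TRUE)),
      tx_start = tx_start,
      tx_end = tx_start + coding_length - 1L,
      coding_length = coding_length,
      high_pli = runif(n) < config$pli_frac)
  })
}

# Inverse-CDF draw from a proportional-hazards Gompertz model:
# hazard rate * exp(shape * t) * exp(lp).
rgompertz_ph <- function(n, shape, rate, lp = 0) {
  e <- rexp(n)
  log1p(shape * e / (rate * exp(lp))) / shape
}

#' Simulate variants, genotypes and ground truth
#'
#' For every gene emits a set of qualifying rare PTVs (stop-gained,
#' frameshift, essential splice) plus decoy variants sitting on the far side
#' of every downstream filter rule: missense and synonymous variants, a
#' stop-gained variant too close to the transcript end (low confidence), a
#' common (MAF >= 1%) PTV on a subset of genes, a non-canonical-transcript
#' annotation, and paired records at a shared position (multi-allelic once
#' written to VCF). Carrier allelic depths are drawn as total depth ~
#' Poisson(`read_depth_mean`) and alt count ~ Binomial(depth, true VAF),
#' with germline carriers at VAF 0.5 and somatic carriers at
#' VAF ~ Uniform(0.05, 0.40).
#'
#' @param models Output of [simulate_gene_models()].
#' @param config A [sim_config()].
#' @return A list with elements `variants` (annotation table: one row per
#'   variant-transcript), `genotypes` (a `genotype_calls` object), and
#'   `truth` (`genes` and `carriers` tibbles recording true origin, hazard
#'   ratios and VAFs).
#' @export
simulate_variants_and_genotypes <- function(models, config) {
  stopifnot(inherits(config, "sim_config"))
  n_ind <- config$n_individuals
  ids <- sample_ids(n_ind)
  with_substream(config$seed, "variants_genotypes", {
    n_genes <- nrow(models)
    origin <- ifelse(runif(n_genes) < config$frac_somatic_genes,
                     "somatic", "germline")
    true_hr <- exp(ifelse(models$gene %in% names(config$true_log_hr),
                          config$true_log_hr[models$gene], 0))
    freq <- runif(n_genes, config$carrier_freq_range[1],
                  config$carrier_freq_range[2])
    truth_genes <- tibble::tibble(gene = models$gene, origin = origin,
                                  true_hr = unname(true_hr),
                                  carrier_freq = freq)

    var_rows <- list()
    call_rows <- list()
    carrier_rows <- list()
    vid <- 0L
    new_variant <- function(g, consequence, pos_frac, canonical = TRUE,
                            transcript = NULL, qualifying = FALSE,
                            shared_pos = NA_integer_) {
      vid <<- vid + 1L
      pos <- if (!is.na(shared_pos)) shared_pos else
        as.integer(g$tx_start + floor(pos_frac * (g$coding_length - 1)))
      ref <- sample(c("A", "C", "G", "T"), 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      if (consequence == "frameshift") alt <- paste0(ref, alt)
      is_canonical <- is.null(transcript)
      data.frame(
        variant_id = sprintf("%s-%d-%s-%s", g$chrom, pos, ref, alt),
        chrom = g$chrom, pos = pos, ref = ref, alt = alt,
        gene = g$gene,
        transcript = transcript %||% g$transcript,
        canonical = is_canonical,
        consequence = consequence,
        distance_to_transcript_end = as.integer(g$tx_end - pos),
        qualifying_truth = qualifying)
    }
    add_calls <- function(variant_id, carriers, vaf) {
      if (!length(carriers)) return(invisible(NULL))
      dp <- pmax(1L, rpois(length(carriers), config$read_depth_mean))
      ad_alt <- rbinom(length(carriers), dp, vaf)
      call_rows[[length(call_rows) + 1L]] <<- data.frame(
        variant_id = variant_id, sample_id = carriers,
        allele_count = 1L, dp = dp, ad_alt = ad_alt)
      invisible(NULL)
    }

    for (k in seq_len(n_genes)) {
      g <- models[k, ]
      n_carriers <- rbinom(1, n_ind, freq[k])
      carriers <- sample(ids, n_carriers)
      vafs <- if (origin[k] == "somatic") runif(n_carriers, 0.05, 0.40)
              else rep(0.5, n_carriers)
      carrier_rows[[k]] <- data.frame(gene = rep(g$gene, n_carriers),
                                      sample_id = carriers,
                                      true_vaf = vafs)
      # qualifying PTVs: split carriers over 1-3 variants, keep >=1 singleton
      n_q <- min(max(1L, n_carriers), 1L + rpois(1, 1))
      csq_pool <- c("stop_gained", "frameshift", "splice_acceptor",
                    "splice_donor")
      assign_v <- if (n_carriers > 0) {
        sample.int(n_q, n_carriers, replace = TRUE)
      } else integer(0)
      for (j in seq_len(n_q)) {
        v <- new_variant(g, sample(csq_pool, 1), runif(1, 0.05, 0.9),
                         qualifying = TRUE)
        var_rows[[length(var_rows) + 1L]] <- v
        cj <- carriers[assign_v == j]
        if (length(cj)) {
          vv <- vafs[assign_v == j]
          dp <- pmax(1L, rpois(length(cj), config$read_depth_mean))
          ad_alt <- rbinom(length(cj), dp, vv)
          call_rows[[length(call_rows) + 1L]] <- data.frame(
            variant_id = v$variant_id, sample_id = cj,
            allele_count = 1L, dp = dp, ad_alt = ad_alt)
        }
      }
      # decoys: missense + synonymous (rare), low-confidence near-end PTV
      for (csq in c("missense", "synonymous")) {
        v <- new_variant(g, csq, runif(1, 0.05, 0.9))
        var_rows[[length(var_rows) + 1L]] <- v
        dec_car <- sample(ids, rbinom(1, n_ind, freq[k]))
        add_calls(v$variant_id, dec_car, 0.5)
      }
      v_low <- new_variant(g, "stop_gained",
                           1 - runif(1, 0, 45) / g$coding_length)
      # force within the 50 bp end-of-transcript window
      v_low$distance_to_transcript_end <- sample.int(49L, 1L) - 1L
      var_rows[[length(var_rows) + 1L]] <- v_low
      add_calls(v_low$variant_id, sample(ids, rbinom(1, n_ind, freq[k])), 0.5)
    }
    # common (MAF >= 1%) PTV decoys on up to 3 genes
    for (k in seq_len(min(3L, n_genes))) {
      g <- models[k, ]
      v <- new_variant(g, "stop_gained", runif(1, 0.05, 0.7))
      var_rows[[length(var_rows) + 1L]] <- v
      add_calls(v$variant_id, sample(ids, rbinom(1, n_ind, 0.05)), 0.5)
    }
    # a non-canonical-transcript-only annotation (dropped downstream)
    g <- models[min(2L, n_genes), ]
    v_nc <- new_variant(g, "stop_gained", 0.4,
                        transcript = paste0(g$transcript, "_alt"))
    var_rows[[length(var_rows) + 1L]] <- v_nc
    add_calls(v_nc$variant_id, sample(ids, max(1L, rbinom(1, n_ind, 0.002))),
              0.5)
    # two alt alleles at one shared position -> multi-allelic site in VCF
    g <- models[1, ]
    mpos <- as.integer(g$tx_start + 10L)
    for (alt_csq in c("missense", "synonymous")) {
      v <- new_variant(g, alt_csq, NA, shared_pos = mpos)
      var_rows[[length(var_rows) + 1L]] <- v
      add_calls(v$variant_id, sample(ids, max(1L, rbinom(1, n_ind, 0.002))),
                0.5)
    }

    variants <- dplyr::bind_rows(var_rows)
    # de-duplicate accidental id collisions (same pos/ref/alt draw)
    variants <- dplyr::distinct(variants, .data$variant_id, .data$transcript,
                                .keep_all = TRUE)
    calls <- dplyr::bind_rows(call_rows)
    calls <- dplyr::distinct(calls, .data$variant_id, .data$sample_id,
                             .keep_all = TRUE)
    missing <- if (config$genotype_missing_rate > 0) {
      n_miss <- rbinom(1, n_ind * nrow(variants),
                       config$genotype_missing_rate)
      n_miss <- min(n_miss, 5000L)
      tibble::tibble(
        variant_id = sample(variants$variant_id, n_miss, replace = TRUE),
        sample_id = sample(ids, n_miss, replace = TRUE))
    } else tibble::tibble(variant_id = character(), sample_id = character())
    missing <- dplyr::anti_join(missing, calls,
                                by = c("variant_id", "sample_id"))
    genotypes <- genotype_calls(samples = ids, calls = calls,
                                missing = missing)
    list(variants = variants, genotypes = genotypes,
         truth = list(genes = truth_genes,
                      carriers = dplyr::bind_rows(carrier_rows)))
  })
}

#' Per-sample genotype calls container
#'
#' Sparse representation of biallelic genotype calls: samples absent from
#' `calls` and `missing` for a variant are homozygous reference.
#'
#' @param samples Character vector of sample ids (the genotyped set).
#' @param calls Tibble `variant_id, sample_id, allele_count (1 or 2), dp,
#'   ad_alt`.
#' @param missing Tibble `variant_id, sample_id` of no-call genotypes.
#' @return A `genotype_calls` object.
#' @export
genotype_calls <- function(samples, calls,
                           missing = tibble::tibble(variant_id = character(),
                                                    sample_id = character())) {
  stopifnot(all(c("variant_id", "sample_id", "allele_count") %in%
                  names(calls)))
  if (!all(calls$sample_id %in% samples)) {
    abort("`calls` reference samples outside `samples`.")
  }
  structure(list(samples = samples, calls = tibble::as_tibble(calls),
                 missing = tibble::as_tibble(missing)),
            class = "genotype_calls")
}

#' @export
print.genotype_calls <- function(x, ...) {
  cat(sprintf("<genotype_calls> %d samples, %d non-reference calls, %d missing\n",
              length(x$samples), nrow(x$calls), nrow(x$missing)))
  invisible(x)
}

carrier_matrix <- function(genotypes, variants_by_gene) {
  # per-sample, per-gene carrier indicator from qualifying-truth variants
  qual <- variants_by_gene
  dplyr::inner_join(genotypes$calls, qual, by = "variant_id") |>
    dplyr::distinct(.data$gene, .data$sample_id)
}

#' Simulate censored survival and parental-lifespan records
#'
#' Draws proband death ages from the Gompertz baseline scaled by
#' `exp(beta * g)` for gene carriers (and a male hazard term), censors at the
#' age attained on the censoring date (June 2020), and simulates parental
#' genotypes explicitly — a germline heterozygous proband has exactly one
#' carrier parent, chosen at random — so the power loss of parental-lifespan
#' proxy phenotypes emerges from transmission rather than from an ad hoc
#' attenuation. Parents of somatic-origin carriers are non-carriers. The raw
#' table carries one row per assessment instance with sex, baseline age, 10
#' synthetic PC columns, adoption flags, "do not know" parental responses,
#' parental deaths before age 40 and ancestry flags at the configured rates.
#'
#' @param genotypes A `genotype_calls` object.
#' @param truth Truth list from [simulate_variants_and_genotypes()].
#' @param config A [sim_config()].
#' @param variants Variant annotation table (used to find qualifying variants
#'   per gene; defaults to all truth carriers).
#' @return A raw phenotype tibble, one row per sample per assessment
#'   instance, with a `truth` attribute carrying per-sample carrier status.
#' @export
simulate_survival <- function(genotypes, truth, config, variants = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ids <- genotypes$samples
  n <- length(ids)
  bh <- config$baseline_hazard
  with_substream(config$seed, "survival", {
    sex <- ifelse(runif(n) < 0.5, "M", "F")
    baseline_age <- runif(n, config$age_range[1], config$age_range[2])
    assess_year <- 2008
    birth_dec <- assess_year - baseline_age
    censor_age <- 2020.5 - birth_dec
    pcs <- matrix(rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("pc", 1:10)))

    # proband linear predictor: gene effects + sex
    hr_genes <- truth$genes[truth$genes$true_hr != 1, , drop = FALSE]
    lp <- ifelse(sex == "M", config$sex_log_hr, 0)
    carr <- dplyr::left_join(truth$carriers, truth$genes[, c("gene", "true_hr")],
                             by = "gene")
    if (nrow(carr)) {
      per_sample <- carr |>
        dplyr::group_by(.data$sample_id) |>
        dplyr::summarise(lp = sum(log(.data$true_hr)), .groups = "drop")
      m <- match(per_sample$sample_id, ids)
      lp[m] <- lp[m] + per_sample$lp
    }
    death_age <- rgompertz_ph(n, bh$shape, bh$rate, lp)
    dead <- death_age <= censor_age

    # parental transmission: one carrier parent per germline carrier proband
    germ_genes <- truth$genes$gene[truth$genes$origin == "germline"]
    gc <- truth$carriers[truth$carriers$gene %in% germ_genes, , drop = FALSE]
    gc <- dplyr::left_join(gc, truth$genes[, c("gene", "true_hr")], by = "gene")
    gc$to_father <- runif(nrow(gc)) < 0.5
    father_lp <- rep(config$sex_log_hr, n)
    mother_lp <- rep(0, n)
    if (nrow(gc)) {
      fa <- gc[gc$to_father, ] |>
        dplyr::group_by(.data$sample_id) |>
        dplyr::summarise(lp = sum(log(.data$true_hr)), .groups = "drop")
      mo <- gc[!gc$to_father, ] |>
        dplyr::group_by(.data$sample_id) |>
        dplyr::summarise(lp = sum(log(.data$true_hr)), .groups = "drop")
      father_lp[match(fa$sample_id, ids)] <-
        father_lp[match(fa$sample_id, ids)] + fa$lp
      mother_lp[match(mo$sample_id, ids)] <-
        mother_lp[match(mo$sample_id, ids)] + mo$lp
    }
    parent_offset_f <- runif(n, 22, 38)
    parent_offset_m <- runif(n, 20, 36)
    father_death <- rgompertz_ph(n, bh$shape, bh$rate, father_lp)
    mother_death <- rgompertz_ph(n, bh$shape, bh$rate, mother_lp)
    pp <- config$parental_params
    early_f <- runif(n) < pp$early_death_rate
    early_m <- runif(n) < pp$early_death_rate
    father_death[early_f] <- runif(sum(early_f), 20, 39.9)
    mother_death[early_m] <- runif(sum(early_m), 20, 39.9)

    adopted <- runif(n) < pp$adoption_rate
    unknown_f <- runif(n) < pp$report_missing_rate
    unknown_m <- runif(n) < pp$report_missing_rate
    anc_other <- runif(n) < config$ancestry_other_rate
    anc_genetic <- !anc_other | runif(n) < 0.5
    anc_self <- !(anc_other & anc_genetic)

    make_instance <- function(instance, visit_year) {
      fage_now <- baseline_age + parent_offset_f + (visit_year - assess_year)
      mage_now <- baseline_age + parent_offset_m + (visit_year - assess_year)
      f_dead <- father_death <= fage_now
      m_dead <- mother_death <= mage_now
      tibble::tibble(
        sample_id = ids, instance = instance, visit_year = visit_year,
        sex = sex, baseline_age = baseline_age,
        birth_year = floor(birth_dec),
        birth_month = pmax(1L, pmin(12L,
          as.integer(round((birth_dec - floor(birth_dec)) * 12 + 0.5)))),
        death_age = ifelse(dead, death_age, NA_real_),
        adopted = adopted,
        father_status = dplyr::case_when(unknown_f ~ "unknown",
                                         f_dead ~ "dead",
                                         TRUE ~ "alive"),
        father_age = ifelse(unknown_f, NA_real_,
                            ifelse(f_dead, father_death, fage_now)),
        mother_status = dplyr::case_when(unknown_m ~ "unknown",
                                         m_dead ~ "dead",
                                         TRUE ~ "alive"),
        mother_age = ifelse(unknown_m, NA_real_,
                            ifelse(m_dead, mother_death, mage_now)),
        genetic_caucasian = anc_genetic,
        self_white_british = anc_self) |>
        dplyr::bind_cols(tibble::as_tibble(pcs))
    }
    raw <- make_instance(0L, assess_year)
    has_repeat <- runif(n) < config$repeat_assessment_rate
    if (any(has_repeat)) {
      rep_rows <- make_instance(1L, assess_year + 5)[has_repeat, ]
      # some repeat answers missing -> latest-non-missing selection matters
      drop_ans <- runif(nrow(rep_rows)) < 0.2
      rep_rows$father_status[drop_ans] <- NA_character_
      rep_rows$father_age[drop_ans] <- NA_real_
      raw <- dplyr::bind_rows(raw, rep_rows)
    }
    attr(raw, "truth") <- list(lp = lp, death_age = death_age,
                               censor_age = censor_age)
    raw
  })
}

#' Simulate a kinship pair table
#'
#' Random close-relative pairs among the cohort at the configured rate, with
#' degrees 1-3 (third-degree pairs are retained by downstream filtering).
#'
#' @param samples Character vector of sample ids.
#' @param config A [sim_config()].
#' @return Tibble `sample_a, sample_b, degree`.
#' @export
simulate_kinship <- function(samples, config) {
  with_substream(config$seed, "kinship", {
    n_pairs <- rbinom(1, length(samples), config$related_pair_rate)
    n_pairs <- max(n_pairs, min(2L, floor(length(samples) / 2)))
    picked <- matrix(sample(samples, 2 * n_pairs), ncol = 2)
    tibble::tibble(sample_a = picked[, 1], sample_b = picked[, 2],
                   degree = sample(1:3, n_pairs, replace = TRUE,
                                   prob = c(0.3, 0.4, 0.3)))
  })
}

#' Simulate a phenome with planted gene effects
#'
#' Binary traits with configurable prevalence (one trait is forced to have
#' exactly 99 cases, one side of the case-count filter), a binary trait with
#' a planted odds ratio for carriers of a designated gene, quantitative
#' traits with heavy-tailed (t, 4 df) noise, one with a planted standardized
#' carrier effect, one with planted > 5 s.d. outliers, one with exactly 499
#' non-missing observations, plus a coded-events table (primary / secondary /
#' death source columns) for ICD-style aggregation tests.
#'
#' @param genotypes A `genotype_calls` object.
#' @param config A [sim_config()].
#' @param truth Truth list (supplies carrier sets for planted effects).
#' @return A list: `phenotypes` (wide tibble, `sample_id` + one column per
#'   trait), `types` (tibble `phenotype, type`), `codes` (events tibble
#'   `sample_id, code, source`).
#' @export
simulate_phenome <- function(genotypes, config, truth) {
  stopifnot(inherits(config, "sim_config"))
  ids <- genotypes$samples
  n <- length(ids)
  pp <- config$phenome_params
  planted_gene <- pp$planted_gene %||% truth$genes$gene[1]
  g <- as.integer(ids %in%
                    truth$carriers$sample_id[truth$carriers$gene == planted_gene])
  with_substream(config$seed, "phenome", {
    out <- list(sample_id = ids)
    types <- list()
    # planted-OR binary trait
    p0 <- pp$prevalence_planted
    pr <- stats::plogis(log(p0 / (1 - p0)) + log(pp$planted_or) * g)
    out$bin_planted <- rbinom(n, 1, pr)
    types$bin_planted <- "binary"
    # exactly-99-cases boundary trait
    b99 <- integer(n)
    b99[sample.int(n, min(99L, n))] <- 1L
    out$bin_rare99 <- b99
    types$bin_rare99 <- "binary"
    for (j in seq_len(max(0L, pp$n_binary - 2L))) {
      prev <- exp(runif(1, log(0.005), log(0.2)))
      nm <- sprintf("bin_null%02d", j)
      out[[nm]] <- rbinom(n, 1, prev)
      types[[nm]] <- "binary"
    }
    # quantitative traits
    tnoise <- function(n) stats::rt(n, df = 4) / sqrt(2)  # unit-ish variance
    out$quant_planted <- pp$planted_beta * g + tnoise(n)
    types$quant_planted <- "quantitative"
    qo <- rnorm(n)
    k <- min(5L, n)
    qo[sample.int(n, k)] <- mean(qo) + 8 * sd(qo)
    out$quant_outlier <- qo
    types$quant_outlier <- "quantitative"
    qs <- rnorm(n)
    if (n > 499) qs[sample.int(n, n - 499L)] <- NA_real_
    out$quant_sparse499 <- qs
    types$quant_sparse499 <- "quantitative"
    for (j in seq_len(max(0L, pp$n_quant - 3L))) {
      nm <- sprintf("quant_null%02d", j)
      out[[nm]] <- tnoise(n)
      types[[nm]] <- "quantitative"
    }
    # coded events: same code can appear in primary, secondary or death source
    n_ev <- rbinom(1, n, 0.15) + 5L
    codes <- tibble::tibble(
      sample_id = sample(ids, n_ev, replace = TRUE),
      code = sample(c("C50", "C56", "E11", "I21"), n_ev, replace = TRUE,
                    prob = c(0.3, 0.2, 0.3, 0.2)),
      source = sample(c("primary", "secondary", "death"), n_ev,
                      replace = TRUE, prob = c(0.5, 0.35, 0.15)))
    codes <- dplyr::distinct(codes)
    list(phenotypes = tibble::as_tibble(out),
         types = tibble::tibble(phenotype = names(types),
                                type = unlist(types, use.names = FALSE)),
         codes = codes)
  })
}

#' Simulate phasing read pairs for one carrier
#'
#' Generates fragment-level observations spanning a PTV and a nearby
#' heterozygous common SNP. A germline PTV sits on exactly one of the two
#' SNP haplotypes, so error-free fragments show only two allele
#' combinations. A somatic PTV arose once, on one haplotype, in a clonal
#' subpopulation of cells: fragments from non-mutant cells show PTV-ref with
#' both SNP alleles, and mutant-cell fragments add PTV-alt on a single SNP
#' haplotype. A flat substitution error rate (`config$error_rate`) flips each
#' observed allele independently.
#'
#' @param carrier Sample id.
#' @param ptv,snp Variant ids.
#' @param origin `"germline"` or `"somatic"`.
#' @param config A [sim_config()].
#' @param n_fragments Number of informative fragments.
#' @param true_vaf Somatic variant allele fraction (cell clone fraction / 2);
#'   drawn Uniform(0.05, 0.40) when `NULL`. Ignored for germline.
#' @return Tibble `sample_id, fragment_id, ptv, ptv_allele, snp, snp_allele`.
#' @export
simulate_read_pairs <- function(carrier, ptv, snp, origin, config,
                                n_fragments = 40, true_vaf = NULL) {
  origin <- match.arg(origin, c("germline", "somatic"))
  with_substream(config$seed, paste("read_pairs", carrier, ptv, snp), {
    hap <- sample(c("ref", "alt"), n_fragments, replace = TRUE)  # SNP allele
    if (origin == "germline") {
      ptv_hap <- sample(c("ref", "alt"), 1)  # SNP allele in phase with PTV
      ptv_allele <- ifelse(hap == ptv_hap, "alt", "ref")
    } else {
      vaf <- true_vaf %||% runif(1, 0.05, 0.40)
      mut_hap <- sample(c("ref", "alt"), 1)
      mutant <- hap == mut_hap & runif(n_fragments) < 2 * vaf
      ptv_allele <- ifelse(mutant, "alt", "ref")
    }
    snp_allele <- hap
    if (config$error_rate > 0) {
      flip1 <- runif(n_fragments) < config$error_rate
      flip2 <- runif(n_fragments) < config$error_rate
      ptv_allele[flip1] <- ifelse(ptv_allele[flip1] == "alt", "ref", "alt")
      snp_allele[flip2] <- ifelse(snp_allele[flip2] == "alt", "ref", "alt")
    }
    tibble::tibble(sample_id = carrier,
                   fragment_id = sprintf("frag%04d", seq_len(n_fragments)),
                   ptv = ptv, ptv_allele = ptv_allele,
                   snp = snp, snp_allele = snp_allele)
  })
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper running every generator under one config: gene models,
#' variants and genotypes with truth, raw phenotype records, kinship pairs
#' and a phenome.
#'
#' @param config A [sim_config()].
#' @return Named list `models, variants, genotypes, truth, raw_pheno,
#'   kinship, phenome, config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  models <- simulate_gene_models(config)
  vg <- simulate_variants_and_genotypes(models, config)
  raw <- simulate_survival(vg$genotypes, vg$truth, config)
  kin <- simulate_kinship(vg$genotypes$samples, config)
  phen <- simulate_phenome(vg$genotypes, config, vg$truth)
  list(models = models, variants = vg$variants, genotypes = vg$genotypes,
       truth = vg$truth, raw_pheno = raw, kinship = kin, phenome = phen,
       config = config)
}
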