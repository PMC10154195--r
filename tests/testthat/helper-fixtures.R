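# Shared fixture builders and independent oracles, kept deliberately naive
# and separate from the package implementation.

# Direct double-loop Efron log partial likelihood for a single covariate —
# the brute-force oracle for the Newton fitter.
naive_efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (ut in sort(unique(time[event == 1]))) {
    D <- which(time == ut & event == 1)
    R <- which(time >= ut)
    d <- length(D)
    sD <- sum(exp(beta * x[D]))
    sR <- sum(exp(beta * x[R]))
    ll <- ll + sum(beta * x[D])
    for (l in seq_len(d) - 1) ll <- ll - log(sR - (l / d) * sD)
  }
  ll
}

oracle_efron_beta <- function(time, event, x, interval = c(-8, 8)) {
  stats::optimize(naive_efron_loglik, interval, time = time, event = event,
                  x = x, maximum = TRUE, tol = 1e-9)$maximum
}

# Penalized (Jeffreys) logistic log-likelihood for a 2-column design —
# oracle for the Firth fitter via grid search.
naive_firth_loglik <- function(b0, b1, y, g) {
  X <- cbind(1, g)
  eta <- b0 + b1 * g
  mu <- stats::plogis(eta)
  I <- crossprod(X * (mu * (1 - mu)), X)
  sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(I)$modulus
}

# a small qualifying set built by hand: two genes, three variants
tiny_qset <- function() {
  samples <- sprintf("S%02d", 1:10)
  ann <- tibble::tibble(
    variant_id = c("1-100-A-T", "1-200-G-C", "2-500-C-A"),
    gene = c("GA", "GA", "GB"),
    transcript = c("TA", "TA", "TB"),
    canonical = TRUE,
    consequence = c("stop_gained", "frameshift", "splice_donor"),
    distance_to_transcript_end = c(500L, 800L, 900L))
  calls <- tibble::tibble(
    variant_id = c("1-100-A-T", "1-100-A-T", "1-200-G-C", "2-500-C-A"),
    sample_id = c("S01", "S02", "S01", "S03"),
    allele_count = 1L, dp = 30L, ad_alt = 15L)
  gt <- genotype_calls(samples, calls)
  # tiny cohort: a permissive MAF cut so the 1-2 carriers stay rare enough
  build_qualifying_set(ann, gt, samples, filter_rules(maf_threshold = 0.2))
}

# one-row-per-sample raw phenotype records with every exclusion reason
raw_pheno_fixture <- function() {
  tibble::tibble(
    sample_id = sprintf("P%02d", 1:10),
    instance = 0L, visit_year = 2008,
    sex = rep(c("F", "M"), 5),
    baseline_age = c(45, 55, seq(49, 63, by = 2)),
    birth_year = 2008L - as.integer(c(45, 55, seq(49, 63, by = 2))),
    birth_month = 6L,
    death_age = c(NA, 63.2, NA, NA, NA, NA, NA, NA, NA, NA),
    adopted = c(FALSE, FALSE, TRUE, rep(FALSE, 7)),
    father_status = c("dead", "alive", "alive", "unknown", "dead",
                      "alive", "dead", "alive", "dead", "alive"),
    father_age = c(80, 81, 70, NA, 39, 75, 82, 77, 130, 74),
    mother_status = c("dead", "alive", "alive", "alive", "alive",
                      "unknown", "dead", "alive", "alive", "alive"),
    mother_age = c(79, 75, 72, 74, 70, NA, 85, 78, 76, 72),
    genetic_caucasian = c(rep(TRUE, 9), FALSE),
    self_white_british = c(rep(TRUE, 8), FALSE, TRUE)) |>
    dplyr::bind_cols(tibble::as_tibble(
      matrix(0, 10, 10, dimnames = list(NULL, paste0("pc", 1:10)))))
}
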