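#' Genomic inflation factor from association chi-squared statistics
#'
#' `lambda = median(chi2) / c`, with `c` the null median of a 1-df
#' chi-squared statistic. The printed convention `c = 0.456` is the default;
#' `constant = "exact"` uses the analytic value `qchisq(0.5, 1) = 0.4549`.
#'
#' @param chi2_stats Numeric vector of per-gene chi-squared statistics.
#' @param constant `"printed"` (0.456) or `"exact"`.
#' @return A tibble `lambda, n_tests, constant`.
#' @export
genomic_lambda <- function(chi2_stats, constant = c("printed", "exact")) {
  constant <- match.arg(constant)
  if (!length(chi2_stats)) abort("no statistics supplied")
  c0 <- if (constant == "printed") 0.456 else stats::qchisq(0.5, 1)
  tibble::tibble(lambda = median(chi2_stats) / c0,
                 n_tests = length(chi2_stats), constant = c0)
}

#' Bonferroni significance threshold over genes and outcomes
#'
#' `alpha / n_genes / n_outcomes`; with the conventional 20,000 genes and 6
#' survival outcomes this gives the exome-wide threshold 4.17e-7.
#'
#' @param alpha Family-wise error rate.
#' @param n_genes Number of units tested (genes, pathways or phenotypes).
#' @param n_outcomes Number of outcomes tested per unit.
#' @return A probability.
#' @export
significance_threshold <- function(alpha = 0.05, n_genes = 20000,
                                   n_outcomes = 6) {
  check_count(n_genes, "n_genes")
  check_count(n_outcomes, "n_outcomes")
  check_fraction(alpha, "alpha")
  if (alpha <= 0) abort("`alpha` must be positive.")
  alpha / n_genes / n_outcomes
}

outcome_design <- function(outcome, covariates = NULL) {
  data <- if (inherits(outcome, "survival_phenotype")) outcome$data else outcome
  covs <- covariates %||% intersect(c("baseline_age", "sex",
                                      grep("^pc[0-9]+$", names(data),
                                           value = TRUE)), names(data))
  Z <- if (length(covs)) data[, covs, drop = FALSE] else NULL
  if (!is.null(Z) && "sex" %in% names(Z)) {
    Z$sex <- as.numeric(Z$sex == "M")
  }
  list(data = data, Z = Z)
}

#' Exome-wide gene burden survival scan
#'
#' For every eligible gene (at least `min_events_ptv` carrier-events),
#' collapses qualifying PTVs to the carrier indicator and fits the Cox model
#' with the outcome's covariates, reporting the hazard ratio, Wald p-value
#' and the proportional-hazards (Schoenfeld slope) p-value for the burden
#' term.
#'
#' @param qset A `qualifying_set`.
#' @param outcome A `survival_phenotype`.
#' @param covariates Covariate column names in the outcome data (default:
#'   baseline age, sex if present, and all `pc*` columns).
#' @param min_events_ptv Gene-eligibility threshold (default 10
#'   carrier-events).
#' @param ties Tie correction for [fit_cox()].
#' @param ph_test Also run the Schoenfeld slope test per gene.
#' @return An association tibble, one row per gene, sorted by p:
#'   `gene, outcome, n_carriers, n_ptvs, hr, beta, se, p, converged, ph_p`.
#' @export
burden_scan <- function(qset, outcome, covariates = NULL,
                        min_events_ptv = 10, ties = "efron", ph_test = TRUE) {
  des <- outcome_design(outcome, covariates)
  data <- des$data
  genes <- eligible_genes(qset, outcome, min_events_ptv)
  # one pass over the carrier table instead of a scan per gene
  in_scope <- qset$carriers$sample_id %in% data$sample_id
  carrier_split <- split(qset$carriers$sample_id[in_scope],
                         qset$carriers$gene[in_scope])
  n_ptv_by_gene <- table(qset$variants$gene)
  rows <- purrr::map(genes, function(gn) {
    g <- as.integer(data$sample_id %in% carrier_split[[gn]])
    sc <- list(g = g)
    fit <- fit_cox(data$time, data$event, g, des$Z, ties = ties)
    if (fit$degenerate) return(NULL)
    ph_p <- NA_real_
    if (ph_test && fit$converged) {
      ph <- tryCatch(
        schoenfeld_ph_test(fit, data$time, data$event, sc$g, des$Z),
        error = function(e) NULL)
      if (!is.null(ph)) ph_p <- ph$p[ph$term == "g"]
    }
    tibble::tibble(
      gene = gn,
      outcome = if (inherits(outcome, "survival_phenotype")) outcome$outcome
                else "outcome",
      n_carriers = sum(sc$g > 0),
      n_ptvs = as.integer(n_ptv_by_gene[[gn]]),
      hr = fit$hr, beta = fit$beta, se = fit$se, p = fit$p,
      converged = fit$converged, ph_p = ph_p)
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$p)
}

#' Gene-set (pathway) burden survival scan
#'
#' @param qset A `qualifying_set`.
#' @param gene_sets Tibble from [read_gmt()].
#' @param outcome A `survival_phenotype`.
#' @param covariates,ties See [burden_scan()].
#' @param exclude_genes Genes dropped from every set before collapsing
#'   (sensitivity analysis removing known drivers).
#' @param min_events_ptv Minimum carrier-events for a set to be tested.
#' @return Association tibble, one row per gene set.
#' @export
geneset_scan <- function(qset, gene_sets, outcome, covariates = NULL,
                         exclude_genes = NULL, min_events_ptv = 10,
                         ties = "efron") {
  des <- outcome_design(outcome, covariates)
  data <- des$data
  dead <- data$sample_id[data$event == 1]
  rows <- purrr::pmap(gene_sets, function(set_name, member_genes, ...) {
    sc <- tryCatch(
      collapse_gene_set(qset, list(set_name = set_name,
                                   member_genes = member_genes),
                        samples = data$sample_id,
                        exclude_genes = exclude_genes),
      ptvsurv_empty_score = function(e) NULL)
    if (is.null(sc)) return(NULL)
    if (sum(sc$g == 1 & data$sample_id %in% dead) < min_events_ptv) {
      return(NULL)
    }
    fit <- fit_cox(data$time, data$event, sc$g, des$Z, ties = ties)
    if (fit$degenerate) return(NULL)
    tibble::tibble(set_name = set_name, n_carriers = sum(sc$g > 0),
                   hr = fit$hr, beta = fit$beta, se = fit$se, p = fit$p,
                   converged = fit$converged)
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$p)
}

#' Single-variant Cox survival scan
#'
#' One Cox fit per variant with the per-sample minor-allele count as
#' predictor and the same covariates as the burden tests. Monomorphic
#' variants are skipped and logged.
#'
#' @param dosages Long tibble `variant_id, sample_id, dosage` (samples
#'   absent for a variant have dosage 0).
#' @param outcome A `survival_phenotype`.
#' @param covariates,ties See [burden_scan()].
#' @return Association tibble, one row per tested variant; skipped variant
#'   ids in attribute `"skipped"`.
#' @export
single_variant_scan <- function(dosages, outcome, covariates = NULL,
                                ties = "efron") {
  des <- outcome_design(outcome, covariates)
  data <- des$data
  skipped <- character(0)
  rows <- purrr::map(unique(dosages$variant_id), function(v) {
    dv <- dosages[dosages$variant_id == v, , drop = FALSE]
    g <- numeric(nrow(data))
    m <- match(dv$sample_id, data$sample_id)
    g[m[!is.na(m)]] <- dv$dosage[!is.na(m)]
    if (sd(g) == 0) {
      skipped <<- c(skipped, v)
      return(NULL)
    }
    fit <- fit_cox(data$time, data$event, g, des$Z, ties = ties)
    tibble::tibble(variant_id = v, n_carriers = sum(g > 0), hr = fit$hr,
                   beta = fit$beta, se = fit$se, p = fit$p,
                   converged = fit$converged)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

#' Uncensored linear-regression comparison on ages at death
#'
#' Ordinary least squares of age at death (deceased individuals only) on the
#' burden predictor and covariates; the effect is in years of lifespan.
#' The censored Cox analysis uses all samples, so this comparison shows the
#' power cost of discarding censored observations.
#'
#' @param ages_at_death Ages at death of the deceased subset.
#' @param g Burden predictor for the same subset.
#' @param Z Optional covariate data frame / matrix for the same subset.
#' @return Tibble `beta_years, se, p, n`.
#' @export
linear_lifespan <- function(ages_at_death, g, Z = NULL) {
  if (inherits(g, "burden_score") || is.data.frame(g)) g <- g$g
  n <- length(ages_at_death)
  if (n == 0) abort("no uncensored samples")
  df <- data.frame(y = ages_at_death, g = as.numeric(g))
  Zm <- cox_design(Z, n)
  if (ncol(Zm)) df <- cbind(df, as.data.frame(Zm))
  if (n <= ncol(df) + 1) abort("fewer samples than parameters")
  sm <- summary(lm(y ~ ., data = df))$coefficients
  tibble::tibble(beta_years = sm["g", 1], se = sm["g", 2], p = sm["g", 4],
                 n = n)
}
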