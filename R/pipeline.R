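#' Discovery plus pooled-replication burden scan
#'
#' Runs the gene burden scan on the discovery samples; genes reaching the
#' nominal discovery threshold (default p < 1e-4) are re-tested on the
#' pooled discovery + replication set, and both sets of estimates are
#' reported side by side.
#'
#' @param qset A `qualifying_set` built on the full sample set.
#' @param outcome A `survival_phenotype` covering all samples.
#' @param discovery_samples,replication_samples Disjoint sample id vectors.
#' @param nominal_p Discovery threshold for taking a gene forward.
#' @param covariates,min_events_ptv,ties Passed to [burden_scan()].
#' @return Tibble with discovery columns (`hr, p, ...`) and, for genes
#'   taken forward, `hr_combined`, `p_combined`, `n_carriers_combined`.
#' @export
run_discovery_replication <- function(qset, outcome, discovery_samples,
                                      replication_samples, nominal_p = 1e-4,
                                      covariates = NULL, min_events_ptv = 10,
                                      ties = "efron") {
  if (!length(replication_samples)) abort("empty replication sample set")
  if (length(intersect(discovery_samples, replication_samples))) {
    abort("discovery and replication sample sets overlap")
  }
  data <- outcome$data
  subset_outcome <- function(ids) {
    new_survival_phenotype(data[data$sample_id %in% ids, , drop = FALSE],
                           outcome$outcome, outcome$exclusions)
  }
  disc <- burden_scan(qset, subset_outcome(discovery_samples),
                      covariates = covariates,
                      min_events_ptv = min_events_ptv, ties = ties,
                      ph_test = FALSE)
  forward <- disc$gene[!is.na(disc$p) & disc$p < nominal_p]
  if (length(forward)) {
    pooled <- subset_outcome(union(discovery_samples, replication_samples))
    comb <- purrr::map_dfr(forward, function(gn) {
      sc <- collapse_gene(qset, gn, samples = pooled$data$sample_id)
      des <- outcome_design(pooled, covariates)
      fit <- fit_cox(pooled$data$time, pooled$data$event, sc$g, des$Z,
                     ties = ties)
      tibble::tibble(gene = gn, n_carriers_combined = sum(sc$g > 0),
                     hr_combined = fit$hr, p_combined = fit$p)
    })
    disc <- dplyr::left_join(disc, comb, by = "gene")
  } else {
    disc$n_carriers_combined <- NA_integer_
    disc$hr_combined <- NA_real_
    disc$p_combined <- NA_real_
  }
  disc
}

#' Export QQ and Manhattan plot tables
#'
#' Per-gene Manhattan coordinates (position index, -log10 p, significance
#' flag at the supplied threshold) and QQ coordinates (expected vs observed
#' -log10 p under the uniform null), with the genomic inflation factor
#' attached.
#'
#' @param results Association tibble with `gene` (or `set_name`) and `p`.
#' @param threshold Significance threshold to flag (default the exome-wide
#'   `0.05/20000/6`).
#' @return List `manhattan`, `qq` (tibbles) and `lambda` (tibble).
#' @export
export_qq_manhattan <- function(results,
                                threshold = significance_threshold()) {
  if (!nrow(results)) abort("empty results table")
  unit <- if ("gene" %in% names(results)) "gene" else "set_name"
  res <- results[!is.na(results$p), , drop = FALSE]
  man <- tibble::tibble(unit = res[[unit]],
                        index = seq_len(nrow(res)),
                        p = res$p,
                        neg_log10_p = -log10(res$p),
                        significant = res$p < threshold)
  obs <- sort(res$p)
  qq <- tibble::tibble(
    expected = -log10((seq_along(obs) - 0.5) / length(obs)),
    observed = -log10(obs))
  chi2 <- stats::qchisq(res$p, df = 1, lower.tail = FALSE)
  list(manhattan = man, qq = qq, lambda = genomic_lambda(chi2))
}

#' Manhattan plot of a burden scan
#'
#' @param results Association tibble with `p`.
#' @param threshold Dashed significance line.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, threshold = significance_threshold()) {
  tabs <- export_qq_manhattan(results, threshold)
  ggplot2::ggplot(tabs$manhattan,
                  ggplot2::aes(x = .data$index, y = .data$neg_log10_p,
                               colour = .data$significant)) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "Gene", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' QQ plot of a burden scan
#'
#' @param results Association tibble with `p`.
#' @return A ggplot object annotated with the genomic inflation factor.
#' @export
plot_qq <- function(results) {
  tabs <- export_qq_manhattan(results)
  ggplot2::ggplot(tabs$qq, ggplot2::aes(x = .data$expected,
                                        y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  subtitle = sprintf("lambda = %.3f", tabs$lambda$lambda)) +
    ggplot2::theme_minimal()
}
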