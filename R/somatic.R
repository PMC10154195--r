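#' Variant allele fraction
#'
#' Reads supporting the alternative allele over reads supporting either
#' allele. After multi-allelic splitting only the high-confidence
#' loss-of-function allele's depths should be supplied.
#'
#' @param alt_reads,ref_reads Non-negative read counts (vectorised).
#' @return Fractions in `[0, 1]`.
#' @export
compute_vaf <- function(alt_reads, ref_reads) {
  if (any(alt_reads + ref_reads <= 0)) abort("zero read depth")
  alt_reads / (alt_reads + ref_reads)
}

#' Summarise carrier VAFs for a gene
#'
#' Germline heterozygous carriers are expected to centre near 0.5; a
#' carrier-level mean well below 0.5 is the signature of somatic (clonal
#' hematopoiesis-like) variation.
#'
#' @param observations Tibble `sample_id, variant_id, gene, ad_alt, dp` (or
#'   `ad_ref` instead of `dp`).
#' @param gene Gene id to summarise.
#' @return List `mean_vaf, n_carriers, vafs` (per-observation tibble, the
#'   distribution export for plotting).
#' @export
summarize_gene_vaf <- function(observations, gene) {
  obs <- observations[observations$gene == gene, , drop = FALSE]
  if (!nrow(obs)) abort(sprintf("no VAF observations for gene '%s'", gene))
  ref <- if ("ad_ref" %in% names(obs)) obs$ad_ref else obs$dp - obs$ad_alt
  vaf <- compute_vaf(obs$ad_alt, ref)
  vafs <- tibble::tibble(sample_id = obs$sample_id,
                         variant_id = obs$variant_id, vaf = vaf)
  list(mean_vaf = mean(vaf), n_carriers = dplyr::n_distinct(obs$sample_id),
       vafs = vafs)
}

#' Count PTV-SNP allele co-occurrence patterns on spanning fragments
#'
#' For each (carrier, PTV, heterozygous common SNP) combination with at
#' least one sequencing fragment observing both sites, counts the four
#' allele patterns: n11 PTV-ref/SNP-ref, n12 PTV-ref/SNP-alt, n21
#' PTV-alt/SNP-ref, n22 PTV-alt/SNP-alt. Each fragment is counted once —
#' mate pairs sharing a fragment id collapse to a single observation, and
#' fragments whose mates disagree on an allele are discarded as ambiguous.
#'
#' @param reads Fragment-level tibble `sample_id, fragment_id, ptv,
#'   ptv_allele, snp, snp_allele` (alleles `"ref"`/`"alt"`).
#' @param ptv PTV variant id to extract.
#' @param het_snps SNP ids heterozygous in the carrier (MAF > 1% sites).
#' @return A `read_pair_evidence` tibble: one row per (sample, ptv, snp)
#'   with columns `n11, n12, n21, n22`; zero rows when no fragment spans
#'   both sites.
#' @export
find_informative_pairs <- function(reads, ptv, het_snps) {
  rr <- reads[reads$ptv == ptv & reads$snp %in% het_snps, , drop = FALSE]
  if (!nrow(rr)) {
    return(structure(tibble::tibble(sample_id = character(),
                                    ptv = character(), snp = character(),
                                    n11 = integer(), n12 = integer(),
                                    n21 = integer(), n22 = integer()),
                     class = c("read_pair_evidence", "tbl_df", "tbl",
                               "data.frame")))
  }
  frag <- rr |>
    dplyr::group_by(.data$sample_id, .data$ptv, .data$snp,
                    .data$fragment_id) |>
    dplyr::summarise(
      ptv_allele = if (dplyr::n_distinct(.data$ptv_allele) == 1)
        .data$ptv_allele[1] else NA_character_,
      snp_allele = if (dplyr::n_distinct(.data$snp_allele) == 1)
        .data$snp_allele[1] else NA_character_,
      .groups = "drop") |>
    dplyr::filter(!is.na(.data$ptv_allele), !is.na(.data$snp_allele))
  out <- frag |>
    dplyr::group_by(.data$sample_id, .data$ptv, .data$snp) |>
    dplyr::summarise(
      n11 = sum(.data$ptv_allele == "ref" & .data$snp_allele == "ref"),
      n12 = sum(.data$ptv_allele == "ref" & .data$snp_allele == "alt"),
      n21 = sum(.data$ptv_allele == "alt" & .data$snp_allele == "ref"),
      n22 = sum(.data$ptv_allele == "alt" & .data$snp_allele == "alt"),
      .groups = "drop")
  class(out) <- c("read_pair_evidence", class(out))
  out
}

#' Classify PTV origin from phasing evidence
#'
#' A germline heterozygous PTV lies on exactly one of the two SNP
#' haplotypes, so error-free fragments show two clean patterns: PTV-alt with
#' a single SNP allele and PTV-ref only with the other. A somatic PTV arose
#' in a cell subpopulation: fragments from unmutated cells show PTV-ref on
#' *both* SNP haplotypes, plus PTV-alt on one. The decision rule: somatic
#' iff pattern (3) PTV-alt/SNP-ref co-occurs with (1) PTV-ref/SNP-ref, or
#' (4) PTV-alt/SNP-alt co-occurs with (2) PTV-ref/SNP-alt, each with at
#' least `min_support` fragments; germline-consistent iff the PTV-alt
#' fragments occupy exactly one SNP haplotype and PTV-ref fragments only the
#' other (both patterns at `min_support`); otherwise inconclusive. The call
#' is invariant to swapping the SNP's ref/alt labels.
#'
#' A pattern counts as *present* when its fragment count reaches
#' `min_support`; if a sequencing error rate is supplied, the floor is
#' raised to exceed the 99.9% binomial quantile of the fragments a flat
#' substitution error alone would put in a pattern, so a handful of
#' error fragments on the wrong haplotype cannot simulate a somatic
#' signature. With `error_rate = 0` (the default) the call is exactly the
#' count rule above.
#'
#' @param ev A `read_pair_evidence` tibble (columns `n11, n12, n21, n22`).
#' @param min_support Minimum fragments per required pattern (default 2).
#' @param error_rate Assumed flat per-site substitution error rate used to
#'   raise the presence floor (default 0: no adjustment).
#' @return The input with an `origin_call` column
#'   (`somatic` / `germline_consistent` / `inconclusive`).
#' @export
classify_origin <- function(ev, min_support = 2, error_rate = 0) {
  m <- min_support
  n_tot <- ev$n11 + ev$n12 + ev$n21 + ev$n22
  # an error at either site moves a fragment into an adjacent pattern
  floor_err <- if (error_rate > 0) {
    stats::qbinom(0.999, n_tot, 2 * error_rate) + 1L
  } else 0L
  thr <- pmax(m, floor_err)
  p11 <- ev$n11 >= thr
  p12 <- ev$n12 >= thr
  p21 <- ev$n21 >= thr
  p22 <- ev$n22 >= thr
  a11 <- ev$n11 < m
  a12 <- ev$n12 < m
  a21 <- ev$n21 < m
  a22 <- ev$n22 < m
  somatic <- (p21 & p11) | (p22 & p12)
  germline <- (p21 & p12 & a22 & a11) | (p22 & p11 & a21 & a12)
  dplyr::mutate(tibble::as_tibble(ev),
                origin_call = dplyr::case_when(somatic ~ "somatic",
                                               germline ~ "germline_consistent",
                                               TRUE ~ "inconclusive"))
}

#' Combine per-SNP origin calls for one PTV carrier
#'
#' Evidence from several SNPs is combined by voting: any somatic call wins
#' (somatic phasing is positive evidence; a germline-consistent pattern at
#' another SNP is only absence of it), then germline-consistent, else
#' inconclusive.
#'
#' @param calls Output of [classify_origin()].
#' @return Tibble `sample_id, ptv, origin_call`, one row per carrier-PTV.
#' @export
combine_origin_calls <- function(calls) {
  calls |>
    dplyr::group_by(.data$sample_id, .data$ptv) |>
    dplyr::summarise(origin_call = dplyr::case_when(
      any(.data$origin_call == "somatic") ~ "somatic",
      any(.data$origin_call == "germline_consistent") ~ "germline_consistent",
      TRUE ~ "inconclusive"), .groups = "drop")
}
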