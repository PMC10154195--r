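#' PTV qualification rules
#'
#' @param maf_threshold Variants with minor allele frequency at or above this
#'   value (computed within the designated ancestry subset) do not qualify.
#' @param end_trunc_distance Stop-gained and frameshift candidates closer
#'   than this many base pairs to the end of the canonical transcript are
#'   demoted to low confidence (the annotation-confidence convention for
#'   truncations likely to escape nonsense-mediated decay). Default 50 bp;
#'   any distance, e.g. 50000, may be configured.
#' @return A `filter_rules` object.
#' @export
filter_rules <- function(maf_threshold = 0.01, end_trunc_distance = 50) {
  check_fraction(maf_threshold, "maf_threshold")
  if (!is.numeric(end_trunc_distance) || end_trunc_distance < 0) {
    abort("`end_trunc_distance` must be non-negative.")
  }
  structure(list(maf_threshold = maf_threshold,
                 end_trunc_distance = end_trunc_distance),
            class = "filter_rules")
}

ptv_consequences <- c("stop_gained", "frameshift", "splice_acceptor",
                      "splice_donor")
known_consequences <- c(ptv_consequences, "missense", "synonymous", "other")

#' Split a multi-allelic variant record into biallelic records
#'
#' One output record per alternative allele. Per-sample genotype allele codes
#' matching the extracted alt become 1; the reference and all other alt
#' alleles become 0. Allelic depths are reassigned as (original ref depth,
#' this alt's depth). Positions are passed through unchanged (no left
#' normalisation).
#'
#' @param record A list with `chrom`, `pos`, `ref`, `alt` (character vector
#'   of one or more alternative alleles) and `genotypes`, a tibble with
#'   columns `sample_id`, `gt` (e.g. `"0/1"`, `"1/2"`, `"./."`) and `ad`
#'   (comma-separated depths, ref first, one per allele).
#' @return A list of biallelic records of the same shape, each with a single
#'   `alt` and a `variant_id`.
#' @export
split_multiallelic <- function(record) {
  alts <- record$alt
  gt <- record$genotypes
  gt$gt[is.na(gt$gt)] <- "./."   # VCF readers surface '.' genotypes as NA
  gt$ad[is.na(gt$ad)] <- paste(rep("0", length(alts) + 1), collapse = ",")
  alleles <- stringr::str_split(gt$gt, "[/|]")
  if (any(lengths(alleles) != 2)) abort("malformed GT field (not diploid)")
  ad <- stringr::str_split(gt$ad, ",")
  if (any(lengths(ad) != length(alts) + 1)) {
    abort("malformed AD field (wrong allele count)")
  }
  ad <- lapply(ad, as.numeric)
  purrr::map(seq_along(alts), function(j) {
    code <- as.character(j)
    a1 <- purrr::map_chr(alleles, 1)
    a2 <- purrr::map_chr(alleles, 2)
    recode <- function(a) dplyr::case_when(a == "." ~ ".",
                                           a == code ~ "1",
                                           TRUE ~ "0")
    r1 <- recode(a1)
    r2 <- recode(a2)
    new_gt <- paste(pmin(r1, r2), pmax(r1, r2), sep = "/")  # 1/0 -> 0/1
    new_gt[a1 == "." & a2 == "."] <- "./."
    new_ad <- purrr::map_chr(ad, function(d) {
      paste(c(d[1], d[j + 1]), collapse = ",")
    })
    list(chrom = record$chrom, pos = record$pos, ref = record$ref,
         alt = alts[j],
         variant_id = sprintf("%s-%d-%s-%s", record$chrom, record$pos,
                              record$ref, alts[j]),
         genotypes = tibble::tibble(sample_id = gt$sample_id, gt = new_gt,
                                    ad = new_ad))
  })
}

#' Classify variants as high/low-confidence PTVs or non-PTVs
#'
#' Stop-gained, frameshift and essential splice (acceptor/donor) consequences
#' are PTV candidates; candidates with `distance_to_transcript_end` below
#' `rules$end_trunc_distance` are demoted to `low_confidence`; all other
#' consequence classes are `not_ptv`.
#'
#' @param annotations Tibble with at least `consequence` and
#'   `distance_to_transcript_end` columns (one row per variant-transcript).
#' @param rules A [filter_rules()].
#' @return The input with a `ptv_class` column
#'   (`high_confidence`/`low_confidence`/`not_ptv`).
#' @export
classify_ptv <- function(annotations, rules = filter_rules()) {
  bad <- setdiff(unique(annotations$consequence), known_consequences)
  if (length(bad)) {
    abort(paste0("unknown consequence label(s): ", paste(bad, collapse = ", ")))
  }
  annotations |>
    dplyr::mutate(ptv_class = dplyr::case_when(
      !.data$consequence %in% ptv_consequences ~ "not_ptv",
      .data$distance_to_transcript_end < rules$end_trunc_distance ~
        "low_confidence",
      TRUE ~ "high_confidence"))
}

#' Minor allele frequency within a sample subset
#'
#' `MAF = min(f, 1 - f)` with `f` the alternative-allele count over twice the
#' number of non-missing genotyped subset samples (complete-case
#' denominator).
#'
#' @param genotypes A `genotype_calls` object.
#' @param variant A variant id.
#' @param subset Character vector of sample ids.
#' @return A fraction.
#' @export
compute_maf <- function(genotypes, variant, subset) {
  if (!length(subset)) abort("empty sample subset")
  calls <- genotypes$calls[genotypes$calls$variant_id == variant &
                             genotypes$calls$sample_id %in% subset, ]
  n_missing <- sum(genotypes$missing$variant_id == variant &
                     genotypes$missing$sample_id %in% subset)
  n_typed <- length(subset) - n_missing
  if (n_typed == 0) abort("no non-missing genotypes for variant")
  f <- sum(calls$allele_count) / (2 * n_typed)
  min(f, 1 - f)
}

# vectorised MAF for all variants at once
compute_maf_all <- function(genotypes, subset) {
  calls <- genotypes$calls[genotypes$calls$sample_id %in% subset, ]
  ac <- calls |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(alt_count = sum(.data$allele_count),
                     n_carriers = dplyr::n(), .groups = "drop")
  miss <- genotypes$missing[genotypes$missing$sample_id %in% subset, ] |>
    dplyr::count(.data$variant_id, name = "n_missing")
  ac |>
    dplyr::left_join(miss, by = "variant_id") |>
    dplyr::mutate(n_missing = dplyr::coalesce(.data$n_missing, 0L),
                  n_typed = length(subset) - .data$n_missing,
                  f = .data$alt_count / (2 * .data$n_typed),
                  maf = pmin(.data$f, 1 - .data$f))
}

#' Build the qualifying PTV set
#'
#' Retains exactly the variants that are (a) annotated on the canonical
#' transcript, (b) classified `high_confidence` PTVs, and (c) rarer than the
#' MAF threshold within the designated sample subset. Variants without a
#' canonical-transcript annotation are dropped and counted, not errored.
#'
#' @param annotations Variant-transcript annotation tibble (`variant_id`,
#'   `gene`, `transcript`, `canonical`, `consequence`,
#'   `distance_to_transcript_end`).
#' @param genotypes A `genotype_calls` object.
#' @param subset Analysis sample subset (character vector); carriers outside
#'   it are ignored everywhere downstream.
#' @param rules A [filter_rules()].
#' @return A `qualifying_set`: list with `variants` (gene, variant_id, maf,
#'   n_carriers, singleton), `carriers` (gene, variant_id, sample_id,
#'   allele_count, dp, ad_alt), `sample_counts` (per-sample total PTV count
#'   over the subset), `subset`, and a `log` tibble of filter counters.
#' @export
build_qualifying_set <- function(annotations, genotypes, subset,
                                 rules = filter_rules()) {
  n_in <- dplyr::n_distinct(annotations$variant_id)
  canon <- annotations[annotations$canonical, , drop = FALSE]
  n_no_canon <- n_in - dplyr::n_distinct(canon$variant_id)
  cls <- classify_ptv(canon, rules)
  hc <- cls[cls$ptv_class == "high_confidence", , drop = FALSE]
  n_not_hc <- dplyr::n_distinct(canon$variant_id) -
    dplyr::n_distinct(hc$variant_id)
  mafs <- compute_maf_all(genotypes, subset)
  hc <- dplyr::left_join(hc, mafs[, c("variant_id", "maf")], by = "variant_id")
  hc$maf <- dplyr::coalesce(hc$maf, 0)  # no carriers in subset -> MAF 0
  keep <- hc[hc$maf < rules$maf_threshold, , drop = FALSE]
  n_common <- nrow(hc) - nrow(keep)

  carriers <- genotypes$calls |>
    dplyr::filter(.data$sample_id %in% subset) |>
    dplyr::inner_join(keep[, c("variant_id", "gene")], by = "variant_id")
  per_var <- carriers |>
    dplyr::group_by(.data$variant_id) |>
    dplyr::summarise(n_carriers = dplyr::n(), .groups = "drop")
  variants <- keep |>
    dplyr::left_join(per_var, by = "variant_id") |>
    dplyr::mutate(n_carriers = dplyr::coalesce(.data$n_carriers, 0L),
                  singleton = .data$n_carriers == 1L) |>
    dplyr::select("gene", "variant_id", "maf", "n_carriers", "singleton") |>
    dplyr::arrange(.data$gene, .data$variant_id)
  sample_counts <- carriers |>
    dplyr::count(.data$sample_id, name = "n_ptv") |>
    dplyr::right_join(tibble::tibble(sample_id = subset), by = "sample_id") |>
    dplyr::mutate(n_ptv = dplyr::coalesce(.data$n_ptv, 0L))
  log <- tibble::tibble(
    step = c("input", "no_canonical_annotation", "not_high_confidence",
             "maf_at_or_above_threshold", "qualifying"),
    n_variants = c(n_in, n_no_canon, n_not_hc, n_common, nrow(variants)))
  structure(list(variants = variants,
                 carriers = dplyr::arrange(carriers, .data$gene,
                                           .data$variant_id, .data$sample_id),
                 sample_counts = sample_counts,
                 subset = subset, rules = rules, log = log),
            class = "qualifying_set")
}

#' @export
print.qualifying_set <- function(x, ...) {
  cat(sprintf(
    "<qualifying_set> %d variants in %d genes, %d carrier calls, %d samples\n",
    nrow(x$variants), dplyr::n_distinct(x$variants$gene), nrow(x$carriers),
    length(x$subset)))
  print(x$log)
  invisible(x)
}
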