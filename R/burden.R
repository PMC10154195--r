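new_burden_score <- function(data, unit, mode) {
  structure(data, unit = unit, mode = mode,
            class = c("burden_score", class(data)))
}

#' Per-gene carrier-indicator burden score
#'
#' Collapses all qualifying PTVs in one gene into a 0/1 predictor: `g = 1`
#' if the sample carries at least one qualifying PTV in the gene, else 0.
#' Carriers outside `samples` are not counted.
#'
#' @param qset A `qualifying_set`.
#' @param gene Gene id.
#' @param samples Sample ids to score (default: the qualifying set's subset).
#' @return A `burden_score` tibble `sample_id, g`.
#' @export
collapse_gene <- function(qset, gene, samples = qset$subset) {
  if (!gene %in% qset$variants$gene) {
    abort(sprintf("gene '%s' has no qualifying variants", gene),
          class = "ptvsurv_empty_score")
  }
  carriers <- unique(
    qset$carriers$sample_id[qset$carriers$gene == gene &
                              qset$carriers$sample_id %in% samples])
  new_burden_score(
    tibble::tibble(sample_id = samples,
                   g = as.integer(samples %in% carriers)),
    unit = gene, mode = "carrier_indicator")
}

#' Gene-set (pathway) burden score
#'
#' Union collapsing: `g = 1` iff the sample carries a qualifying PTV in any
#' member gene. A leave-genes-out variant (for sensitivity analyses removing
#' known drivers) excludes the listed genes from the union.
#'
#' @param qset A `qualifying_set`.
#' @param set_def List or tibble with `set_name` and `member_genes`.
#' @param samples Sample ids to score.
#' @param exclude_genes Genes removed from the union before scoring.
#' @return A `burden_score` tibble `sample_id, g`.
#' @export
collapse_gene_set <- function(qset, set_def, samples = qset$subset,
                              exclude_genes = NULL) {
  members <- setdiff(set_def$member_genes, exclude_genes)
  members <- intersect(members, unique(qset$variants$gene))
  if (!length(members)) {
    abort(sprintf("gene set '%s' has no member gene with qualifying variants",
                  set_def$set_name),
          class = "ptvsurv_empty_score")
  }
  carriers <- unique(
    qset$carriers$sample_id[qset$carriers$gene %in% members &
                              qset$carriers$sample_id %in% samples])
  new_burden_score(
    tibble::tibble(sample_id = samples,
                   g = as.integer(samples %in% carriers)),
    unit = set_def$set_name, mode = "carrier_indicator")
}

#' Exome-wide PTV count score
#'
#' Per-sample total number of qualifying PTV sites carried across all genes,
#' optionally restricted to highly loss-of-function-intolerant genes.
#'
#' @param qset A `qualifying_set`.
#' @param samples Sample ids to score.
#' @param pli_genes When non-NULL, only PTVs in these genes are counted.
#' @return A `burden_score` tibble `sample_id, g` (mode `"count"`).
#' @export
exome_wide_count <- function(qset, samples = qset$subset, pli_genes = NULL) {
  carriers <- qset$carriers[qset$carriers$sample_id %in% samples, ,
                            drop = FALSE]
  if (!is.null(pli_genes)) {
    carriers <- carriers[carriers$gene %in% pli_genes, , drop = FALSE]
  }
  counts <- carriers |> dplyr::count(.data$sample_id, name = "g")
  g <- integer(length(samples))
  g[match(counts$sample_id, samples)] <- counts$g
  new_burden_score(tibble::tibble(sample_id = samples, g = g),
                   unit = if (is.null(pli_genes)) "exome" else "exome_pLI",
                   mode = "count")
}

#' Genes eligible for burden testing
#'
#' A gene is tested only when at least `min_events_ptv` of its qualifying-PTV
#' carriers are noncensored (event = 1) in the outcome — too few observed
#' events make the partial-likelihood test unreliable.
#'
#' @param qset A `qualifying_set`.
#' @param outcome A `survival_phenotype` (or tibble with `sample_id`,
#'   `event`).
#' @param min_events_ptv Minimum carrier-event count (default 10).
#' @return Character vector of eligible gene ids.
#' @export
eligible_genes <- function(qset, outcome, min_events_ptv = 10) {
  data <- if (inherits(outcome, "survival_phenotype")) outcome$data else outcome
  dead <- data$sample_id[data$event == 1]
  qset$carriers |>
    dplyr::filter(.data$sample_id %in% dead) |>
    dplyr::distinct(.data$gene, .data$sample_id) |>
    dplyr::count(.data$gene) |>
    dplyr::filter(.data$n >= min_events_ptv) |>
    dplyr::pull(.data$gene)
}

#' Read a GMT gene-set file
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   member genes).
#' @return Tibble `set_name, description, member_genes` (list column).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- stringr::str_split(lines, "\t")
  bad <- lengths(parts) < 3
  if (any(bad)) abort("GMT lines must have at least 3 tab-separated fields")
  tibble::tibble(
    set_name = purrr::map_chr(parts, 1),
    description = purrr::map_chr(parts, 2),
    member_genes = purrr::map(parts, ~ .x[-(1:2)][nzchar(.x[-(1:2)])]))
}

#' Write a GMT gene-set file
#'
#' @param sets Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(sets, function(set_name, description,
                                          member_genes, ...) {
    paste(c(set_name, description, member_genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}
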