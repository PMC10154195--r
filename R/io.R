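#' Write variants and genotypes to a VCF file
#'
#' Emits a minimal VCF 4.2 with GT and AD per-sample fields. Biallelic
#' records sharing chromosome, position and reference allele are merged
#' into one multi-allelic record (exercising downstream splitting).
#'
#' @param variants Variant tibble (`variant_id, chrom, pos, ref, alt`).
#' @param genotypes A `genotype_calls` object.
#' @param path Output path.
#' @export
write_cohort_vcf <- function(variants, genotypes, path) {
  samples <- genotypes$samples
  vars <- dplyr::distinct(variants, .data$variant_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt)
  sites <- vars |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref) |>
    dplyr::summarise(alts = list(.data$alt),
                     vids = list(.data$variant_id), .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$pos)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  calls <- genotypes$calls
  miss <- genotypes$missing
  for (i in seq_len(nrow(sites))) {
    alts <- sites$alts[[i]]
    vids <- sites$vids[[i]]
    gt <- rep("0/0", length(samples))
    ad <- matrix(0L, length(samples), length(alts) + 1L)
    ad[, 1] <- 25L  # nominal reference depth for non-carriers
    for (j in seq_along(vids)) {
      cc <- calls[calls$variant_id == vids[j], , drop = FALSE]
      m <- match(cc$sample_id, samples)
      gt[m] <- ifelse(cc$allele_count == 2, paste0(j, "/", j),
                      paste0("0/", j))
      ad[m, j + 1L] <- cc$ad_alt
      ad[m, 1L] <- cc$dp - cc$ad_alt
    }
    mm <- miss[miss$variant_id %in% vids, , drop = FALSE]
    if (nrow(mm)) {
      m <- match(unique(mm$sample_id), samples)
      gt[m] <- "./."
      ad[m, ] <- 0L
    }
    fmt <- paste0(gt, ":", apply(ad, 1, paste, collapse = ","))
    writeLines(paste(c(sites$chrom[i], sites$pos[i],
                       paste(vids, collapse = ";"), sites$ref[i],
                       paste(alts, collapse = ","), ".", "PASS", ".",
                       "GT:AD", fmt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a cohort VCF into variant records
#'
#' Parses sites and per-sample GT/AD fields (via vcfR) into the record
#' format consumed by [split_multiallelic()].
#'
#' @param path VCF path.
#' @return List of records (`chrom, pos, ref, alt` vector, `genotypes`
#'   tibble).
#' @export
read_cohort_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  fix <- vcfR::getFIX(v)
  purrr::map(seq_len(nrow(fix)), function(i) {
    list(chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
         ref = fix[i, "REF"],
         alt = strsplit(fix[i, "ALT"], ",")[[1]],
         genotypes = tibble::tibble(sample_id = colnames(gt),
                                    gt = unname(gt[i, ]),
                                    ad = unname(ad[i, ])))
  })
}

#' Convert split biallelic records to a `genotype_calls` object
#'
#' @param records List of biallelic records from [split_multiallelic()].
#' @param samples Sample universe (defaults to the samples of the first
#'   record).
#' @return A `genotype_calls` object.
#' @export
records_to_calls <- function(records, samples = NULL) {
  samples <- samples %||% records[[1]]$genotypes$sample_id
  calls <- purrr::map_dfr(records, function(rec) {
    gt <- rec$genotypes
    alle <- stringr::str_split(gt$gt, "[/|]")
    ac <- purrr::map_int(alle, ~ sum(.x == "1"))
    missing <- purrr::map_lgl(alle, ~ all(.x == "."))
    ad <- stringr::str_split(gt$ad, ",")
    ad_ref <- purrr::map_dbl(ad, ~ as.numeric(.x[1]))
    ad_alt <- purrr::map_dbl(ad, ~ as.numeric(.x[2]))
    tibble::tibble(variant_id = rec$variant_id, sample_id = gt$sample_id,
                   allele_count = ac, dp = ad_ref + ad_alt, ad_alt = ad_alt,
                   missing = missing)
  })
  genotype_calls(samples = samples,
                 calls = dplyr::select(calls[calls$allele_count > 0 &
                                               !calls$missing, ], -"missing"),
                 missing = calls[calls$missing, c("variant_id", "sample_id")])
}

#' Write a tab-separated table
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path Input path.
#' @return A tibble.
#' @export
read_tsv_table <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}

#' Write a run manifest
#'
#' Records configuration keys and the seed as `key=value` lines so any
#' stage can be re-run byte-identically from its persisted inputs.
#'
#' @param config Named list of scalar settings.
#' @param path Output path.
#' @export
write_manifest <- function(config, path) {
  flat <- unlist(config)
  writeLines(paste0(names(flat), "=", unname(flat)), path)
  invisible(path)
}

#' Read a run manifest
#'
#' @param path Manifest path.
#' @return Named character vector.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  kv <- stringr::str_split_fixed(lines, "=", 2)
  setNames(kv[, 2], kv[, 1])
}
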