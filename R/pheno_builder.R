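#' Select each sample's most recent assessment answers
#'
#' Collapses a multi-instance raw phenotype table to one row per sample,
#' taking parental answers from the latest assessment visit at which they
#' were not missing; all other fields come from the latest row.
#'
#' @param records Raw phenotype tibble with `sample_id`, `instance`,
#'   `visit_year` and parental answer columns (`father_status`, `father_age`,
#'   `mother_status`, `mother_age`).
#' @return One row per sample.
#' @export
select_latest_assessment <- function(records) {
  records |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      ord <- order(df$instance)
      out <- df[ord[length(ord)], , drop = FALSE]
      # parental answers fall back to the latest instance that answered
      if (any(!is.na(df$father_status[ord]))) {
        i <- ord[max(which(!is.na(df$father_status[ord])))]
        out$father_status <- df$father_status[i]
        out$father_age <- df$father_age[i]
      }
      if (any(!is.na(df$mother_status[ord]))) {
        i <- ord[max(which(!is.na(df$mother_status[ord])))]
        out$mother_status <- df$mother_status[i]
        out$mother_age <- df$mother_age[i]
      }
      out
    }) |>
    dplyr::ungroup()
}

new_survival_phenotype <- function(data, outcome_name, exclusions) {
  structure(list(outcome = outcome_name,
                 data = data,
                 exclusions = exclusions),
            class = "survival_phenotype")
}

#' @export
print.survival_phenotype <- function(x, ...) {
  cat(sprintf("<survival_phenotype> %s: %d samples, %d events, %d excluded\n",
              x$outcome, nrow(x$data), sum(x$data$event), nrow(x$exclusions)))
  invisible(x)
}

covariate_cols <- function(records) {
  pcs <- grep("^pc[0-9]+$", names(records), value = TRUE)
  c("baseline_age", "sex", pcs)
}

#' Build the proband survival outcome
#'
#' Deceased probands contribute their age at death with an event; everyone
#' else is assumed alive on the censoring date, contributing the fractional
#' age attained then (censoring date minus year-month of birth) without an
#' event. Optionally restricted to one sex (the sex covariate is then
#' dropped).
#'
#' @param records One-row-per-sample raw phenotype tibble (see
#'   [select_latest_assessment()]).
#' @param censor_date Decimal censoring date in years (default June 2020).
#' @param sex_restrict `NULL`, `"M"` or `"F"`.
#' @return A `survival_phenotype`: tibble `sample_id, time, event` plus
#'   covariates, and an exclusion log.
#' @export
build_proband_survival <- function(records, censor_date = 2020 + 5.5 / 12,
                                   sex_restrict = NULL) {
  excl <- list()
  df <- records
  if (!is.null(sex_restrict)) {
    dropped <- df[df$sex != sex_restrict, "sample_id"]
    if (nrow(dropped)) {
      excl[[length(excl) + 1L]] <-
        tibble::tibble(sample_id = dropped$sample_id, reason = "other_sex")
    }
    df <- df[df$sex == sex_restrict, , drop = FALSE]
  }
  bad_birth <- is.na(df$birth_year) | is.na(df$birth_month)
  if (any(bad_birth)) {
    excl[[length(excl) + 1L]] <- tibble::tibble(
      sample_id = df$sample_id[bad_birth], reason = "missing_birth_date")
    df <- df[!bad_birth, , drop = FALSE]
  }
  censor_age <- censor_date - (df$birth_year + (df$birth_month - 0.5) / 12)
  over <- !is.na(df$death_age) & df$death_age > censor_age + 1
  if (any(over)) {
    abort(sprintf("%d death ages exceed the censor-implied age", sum(over)))
  }
  time <- ifelse(is.na(df$death_age), censor_age, df$death_age)
  event <- as.integer(!is.na(df$death_age))
  covs <- covariate_cols(records)
  if (!is.null(sex_restrict)) covs <- setdiff(covs, "sex")
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = df$sample_id, time = time, event = event),
    df[, covs, drop = FALSE])
  name <- if (is.null(sex_restrict)) "proband"
          else paste0("proband_", ifelse(sex_restrict == "M", "male", "female"))
  new_survival_phenotype(out, name, dplyr::bind_rows(excl))
}

parent_exclusions <- function(df, parent, adopted_excluded = TRUE) {
  status <- df[[paste0(parent, "_status")]]
  age <- df[[paste0(parent, "_age")]]
  reason <- rep(NA_character_, nrow(df))
  if (adopted_excluded) reason[df$adopted] <- "adopted"
  unknown <- is.na(reason) & (is.na(status) | status == "unknown" | is.na(age))
  reason[unknown] <- "unknown_answer"
  early <- is.na(reason) & status == "dead" & age < 40
  reason[early] <- "early_parent_death"
  absurd <- is.na(reason) & (age < 0 | age > 120)
  reason[absurd] <- "implausible_age"
  reason
}

#' Build a parental-lifespan proxy survival outcome
#'
#' A dead parent contributes their reported age at death with an event; a
#' living parent contributes their reported current age, censored. Probands
#' are excluded — each with a logged reason — if adopted, if they did not
#' know / did not answer the parental questions, if the parent died before
#' age 40, or if the reported age is implausible (negative or > 120).
#' Covariates are the proband's baseline age, sex and PCs (parents are not
#' genotyped; the burden predictor downstream is still the proband's).
#'
#' @param records One-row-per-sample raw phenotype tibble.
#' @param parent `"father"` or `"mother"`.
#' @return A `survival_phenotype`.
#' @export
build_parent_survival <- function(records, parent = c("father", "mother")) {
  parent <- match.arg(parent)
  reason <- parent_exclusions(records, parent)
  excl <- tibble::tibble(sample_id = records$sample_id[!is.na(reason)],
                         reason = reason[!is.na(reason)])
  df <- records[is.na(reason), , drop = FALSE]
  status <- df[[paste0(parent, "_status")]]
  age <- df[[paste0(parent, "_age")]]
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = df$sample_id, time = age,
                   event = as.integer(status == "dead")),
    df[, covariate_cols(records), drop = FALSE])
  new_survival_phenotype(out, parent, excl)
}

#' Build the combined-parent survival outcome
#'
#' Time is the sum of the father's and mother's reported ages; the event
#' fires only when both parents have died. A proband excluded from either
#' single-parent outcome is excluded here, with the same reason.
#'
#' @param records One-row-per-sample raw phenotype tibble.
#' @return A `survival_phenotype`.
#' @export
build_combined_parent <- function(records) {
  rf <- parent_exclusions(records, "father")
  rm_ <- parent_exclusions(records, "mother")
  reason <- dplyr::coalesce(rf, rm_)
  excl <- tibble::tibble(sample_id = records$sample_id[!is.na(reason)],
                         reason = reason[!is.na(reason)])
  df <- records[is.na(reason), , drop = FALSE]
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = df$sample_id,
                   time = df$father_age + df$mother_age,
                   event = as.integer(df$father_status == "dead" &
                                        df$mother_status == "dead")),
    df[, covariate_cols(records), drop = FALSE])
  new_survival_phenotype(out, "combined_parents", excl)
}

#' Remove one member of each close-relative pair
#'
#' Repeatedly removes one member, chosen uniformly at random under the seed,
#' from every remaining pair of relatives of second degree or closer, until
#' the retained set contains no such pair. Third-degree-or-more pairs are
#' untouched. Deterministic given the seed, and idempotent.
#'
#' @param samples Character vector of sample ids.
#' @param pairs Kinship tibble `sample_a, sample_b, degree`.
#' @param seed Integer seed for the random member choice.
#' @return The retained sample ids, with attribute `removed`.
#' @export
exclude_related <- function(samples, pairs, seed = 1L) {
  close <- pairs[pairs$degree <= 2 &
                   pairs$sample_a %in% samples &
                   pairs$sample_b %in% samples, , drop = FALSE]
  removed <- character(0)
  with_substream(seed, "exclude_related", {
    while (nrow(close)) {
      pair <- close[1, ]
      drop <- if (runif(1) < 0.5) pair$sample_a else pair$sample_b
      removed <- c(removed, drop)
      close <- close[close$sample_a != drop & close$sample_b != drop, ,
                     drop = FALSE]
    }
  })
  out <- setdiff(samples, removed)
  # independent verification: no retained close pair
  left <- pairs[pairs$degree <= 2 & pairs$sample_a %in% out &
                  pairs$sample_b %in% out, ]
  stopifnot(nrow(left) == 0)
  attr(out, "removed") <- removed
  out
}

#' Restrict to the designated ancestry subset
#'
#' Keeps samples whose genetically inferred grouping flag and self-reported
#' background flag are both set; samples with a missing flag are excluded
#' with a logged reason.
#'
#' @param samples Candidate sample ids.
#' @param records One-row-per-sample raw phenotype tibble with
#'   `genetic_caucasian` and `self_white_british` logical columns.
#' @return Retained sample ids, with attribute `exclusions` (tibble
#'   `sample_id, reason`).
#' @export
apply_ancestry_filter <- function(samples, records) {
  df <- records[match(samples, records$sample_id), , drop = FALSE]
  miss <- is.na(df$genetic_caucasian) | is.na(df$self_white_british)
  fail <- !miss & !(df$genetic_caucasian & df$self_white_british)
  excl <- tibble::tibble(
    sample_id = c(samples[miss], samples[fail]),
    reason = c(rep("missing_ancestry_flag", sum(miss)),
               rep("ancestry_flags_not_both_set", sum(fail))))
  out <- samples[!miss & !fail]
  attr(out, "exclusions") <- excl
  out
}

#' Build all six survival outcomes
#'
#' Applies ancestry and relatedness exclusions (in that order), then builds
#' proband, sex-stratified proband, father, mother and combined-parent
#' outcomes from the latest-assessment records.
#'
#' @param records Raw multi-instance phenotype tibble.
#' @param kinship Kinship pair tibble.
#' @param censor_date Decimal censoring date.
#' @param seed Seed for the random relative removal.
#' @return Named list of six `survival_phenotype` objects, with attribute
#'   `sample_filter` recording the ancestry/relatedness exclusions.
#' @export
build_all_outcomes <- function(records, kinship, censor_date = 2020 + 5.5 / 12,
                               seed = 1L) {
  latest <- select_latest_assessment(records)
  anc <- apply_ancestry_filter(latest$sample_id, latest)
  unrel <- exclude_related(anc, kinship, seed = seed)
  base <- latest[latest$sample_id %in% unrel, , drop = FALSE]
  out <- list(
    proband = build_proband_survival(base, censor_date),
    proband_male = build_proband_survival(base, censor_date, "M"),
    proband_female = build_proband_survival(base, censor_date, "F"),
    father = build_parent_survival(base, "father"),
    mother = build_parent_survival(base, "mother"),
    combined_parents = build_combined_parent(base))
  attr(out, "sample_filter") <- list(
    ancestry_excluded = attr(anc, "exclusions"),
    related_removed = attr(unrel, "removed"))
  out
}
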