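#' Aggregate coded events into binary phenotypes
#'
#' A sample is a case for a code iff that code appears in any source column
#' (e.g. primary diagnosis, secondary diagnosis, cause of death — or the
#' three family-history questionnaires); the union is idempotent, so a code
#' recorded in several sources counts once.
#'
#' @param records Events tibble `sample_id, code, source`.
#' @param samples All sample ids (controls are samples without the code).
#' @param sources Source columns to union (default: all present).
#' @return Wide binary tibble: `sample_id` plus one 0/1 column per code.
#' @export
aggregate_codes <- function(records, samples, sources = NULL) {
  if (!is.null(sources)) {
    records <- records[records$source %in% sources, , drop = FALSE]
  }
  cases <- dplyr::distinct(records, .data$sample_id, .data$code)
  out <- tibble::tibble(sample_id = samples)
  for (cd in sort(unique(cases$code))) {
    out[[cd]] <- as.integer(samples %in% cases$sample_id[cases$code == cd])
  }
  out
}

phenome_types <- function(phenome) {
  stopifnot(all(c("phenotypes", "types") %in% names(phenome)))
  phenome
}

#' Drop binary phenotypes with too few cases
#'
#' @param phenome List with `phenotypes` (wide tibble) and `types`.
#' @param min_cases Phenotypes with fewer cases than this are removed
#'   (default 100; missing values are not cases).
#' @return The filtered phenome, with a `dropped` tibble recording removals.
#' @export
filter_binary <- function(phenome, min_cases = 100) {
  phenome <- phenome_types(phenome)
  bin <- phenome$types$phenotype[phenome$types$type == "binary"]
  n_cases <- vapply(bin, function(ph) {
    sum(phenome$phenotypes[[ph]] == 1, na.rm = TRUE)
  }, numeric(1))
  drop <- bin[n_cases < min_cases]
  phenome$phenotypes <- phenome$phenotypes[,
    setdiff(names(phenome$phenotypes), drop), drop = FALSE]
  phenome$types <- phenome$types[!phenome$types$phenotype %in% drop, ]
  phenome$dropped <- dplyr::bind_rows(
    phenome$dropped,
    tibble::tibble(phenotype = drop, reason = "fewer_cases_than_minimum",
                   n = n_cases[n_cases < min_cases]))
  phenome
}

#' Filter quantitative phenotypes and mask outliers
#'
#' Phenotypes with fewer non-missing observations than `min_obs` are
#' dropped; within each retained phenotype, values strictly further than
#' `sd_cut` standard deviations from the mean (both computed once, from the
#' original values) are set missing. Zero-variance phenotypes are retained
#' and flagged.
#'
#' @param phenome List with `phenotypes` and `types`.
#' @param min_obs Minimum non-missing observations (default 500).
#' @param sd_cut Outlier cut in standard deviations (default 5, strict `>`).
#' @return The filtered phenome with `dropped` and `flagged` records and a
#'   per-phenotype `outliers_masked` count.
#' @export
filter_quantitative <- function(phenome, min_obs = 500, sd_cut = 5) {
  phenome <- phenome_types(phenome)
  qn <- phenome$types$phenotype[phenome$types$type == "quantitative"]
  n_obs <- vapply(qn, function(ph) {
    sum(!is.na(phenome$phenotypes[[ph]]))
  }, numeric(1))
  drop <- qn[n_obs < min_obs]
  masked <- integer(0)
  flagged <- character(0)
  for (ph in setdiff(qn, drop)) {
    x <- phenome$phenotypes[[ph]]
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      flagged <- c(flagged, ph)
      masked[ph] <- 0L
      next
    }
    out <- !is.na(x) & abs(x - mean(x, na.rm = TRUE)) > sd_cut * s
    x[out] <- NA_real_
    phenome$phenotypes[[ph]] <- x
    masked[ph] <- sum(out)
  }
  phenome$phenotypes <- phenome$phenotypes[,
    setdiff(names(phenome$phenotypes), drop), drop = FALSE]
  phenome$types <- phenome$types[!phenome$types$phenotype %in% drop, ]
  phenome$dropped <- dplyr::bind_rows(
    phenome$dropped,
    tibble::tibble(phenotype = drop, reason = "fewer_obs_than_minimum",
                   n = n_obs[n_obs < min_obs]))
  phenome$flagged_zero_variance <- flagged
  phenome$outliers_masked <- masked
  phenome
}

#' Inverse rank normal transform
#'
#' Maps values to standard-normal quantiles by rank:
#' `qnorm((r - 3/8) / (n + 1/4))` (Blom offset). Ties share their average
#' rank; missing values propagate.
#'
#' @param values Numeric vector.
#' @param offset Rank offset (default 3/8).
#' @return Transformed vector of the same length.
#' @export
irnt <- function(values, offset = 3 / 8) {
  ok <- !is.na(values)
  if (sum(ok) < 2) abort("need at least 2 non-missing values")
  r <- rank(values[ok], ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- qnorm((r - offset) / (sum(ok) + 1 - 2 * offset))
  out
}

logistic_design <- function(g, Z, n) {
  cbind(`(Intercept)` = 1, g = as.numeric(g), cox_design(Z, n))
}

#' Maximum-likelihood logistic regression for a burden predictor
#'
#' Plain logistic fit (iteratively reweighted least squares via `glm`).
#' Separation — carrier status perfectly predicting case status — is
#' detected from exploding estimates or fitted probabilities at the
#' boundary and flagged; flagged fits should be superseded by [fit_firth()].
#'
#' @param y 0/1 outcome vector (missing values dropped pairwise).
#' @param g Burden predictor.
#' @param Z Optional covariate data frame / matrix.
#' @return One-row tibble `model, effect, se, p, n, n_cases, converged,
#'   separated` (`effect` is the log-odds ratio for `g`).
#' @export
fit_logistic <- function(y, g, Z = NULL) {
  if (inherits(g, "burden_score") || is.data.frame(g)) g <- g$g
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]
  g <- g[keep]
  X <- cox_design(Z, length(keep))[keep, , drop = FALSE]
  if (length(unique(y)) < 2) abort("outcome has a single class")
  df <- data.frame(y = y, g = g)
  if (ncol(X)) df <- cbind(df, as.data.frame(X))
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  sm <- summary(fit)$coefficients
  eff <- sm["g", 1]
  se <- sm["g", 2]
  mu <- fit$fitted.values
  separated <- !fit$converged || abs(eff) > 15 || se > 100 ||
    any(mu[g != 0] > 1 - 1e-8) && all(y[g != 0] == 1) ||
    any(mu[g != 0] < 1e-8) && all(y[g != 0] == 0)
  tibble::tibble(model = "logistic", effect = eff, se = se, p = sm["g", 4],
                 n = length(y), n_cases = sum(y == 1),
                 converged = fit$converged, separated = separated)
}

firth_engine <- function(y, X, max_iter = 100, tol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  pen_ll <- function(b) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    I <- crossprod(X * W, X)
    ll <- sum(y * eta - log1p(exp(eta)))
    ld <- determinant(I, logarithm = TRUE)$modulus
    ll + 0.5 * as.numeric(ld)
  }
  cur <- pen_ll(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    XW <- X * W
    I <- crossprod(XW, X)
    Iinv <- solve(I)
    # hat diagonal of the weighted design
    H <- rowSums((X %*% Iinv) * XW)
    U <- crossprod(X, y - mu + H * (0.5 - mu))
    delta <- drop(Iinv %*% U)
    step <- 1
    for (h in 0:12) {
      cand <- beta + step * delta
      new <- pen_ll(cand)
      if (is.finite(new) && new >= cur - 1e-12) break
      step <- step / 2
    }
    conv <- max(abs(cand - beta)) < tol || abs(new - cur) < 1e-12
    beta <- cand
    cur <- new
    if (conv) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  W <- stats::plogis(eta) * (1 - stats::plogis(eta))
  V <- solve(crossprod(X * W, X))
  list(beta = setNames(beta, colnames(X)), var = V, pen_loglik = cur,
       converged = converged, iterations = it)
}

#' Firth penalized-likelihood logistic regression
#'
#' Adds the Jeffreys-prior penalty (half the log-determinant of the Fisher
#' information) to the logistic log-likelihood, guaranteeing finite
#' estimates under separation. Fitting is Newton iteration with
#' step-halving; the p-value for the burden coefficient is a penalized
#' likelihood-ratio test against a Firth refit without that column (Wald
#' optional).
#'
#' @param y 0/1 outcome vector.
#' @param g Burden predictor.
#' @param Z Optional covariate data frame / matrix.
#' @param p_method `"plrt"` (default) or `"wald"`.
#' @return One-row tibble with the [fit_logistic()] schema, `model =
#'   "firth_logistic"`.
#' @export
fit_firth <- function(y, g, Z = NULL, p_method = c("plrt", "wald")) {
  p_method <- match.arg(p_method)
  if (inherits(g, "burden_score") || is.data.frame(g)) g <- g$g
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]
  g <- g[keep]
  Xz <- cox_design(Z, length(keep))[keep, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1, g = as.numeric(g), Xz)
  full <- firth_engine(y, X)
  se <- sqrt(diag(full$var))[2]
  eff <- full$beta[2]
  if (p_method == "wald") {
    pv <- 2 * pnorm(-abs(eff / se))
  } else {
    red <- firth_engine(y, X[, -2, drop = FALSE])
    pv <- pchisq(2 * (full$pen_loglik - red$pen_loglik), df = 1,
                 lower.tail = FALSE)
  }
  tibble::tibble(model = "firth_logistic", effect = unname(eff),
                 se = unname(se), p = pv, n = length(y),
                 n_cases = sum(y == 1), converged = full$converged,
                 separated = NA)
}

#' Phenome-wide burden association scan
#'
#' Tests a gene's burden score against every phenotype in a filtered
#' phenome, in all samples and per-sex strata. Binary phenotypes use
#' logistic regression with a Firth refit whenever the plain-logistic
#' burden p-value is below `firth_refit_p` (the refit row replaces the
#' plain one and is flagged); quantitative phenotypes are tested by linear
#' regression on both the raw and the inverse-rank-normal scales. Within a
#' sex stratum the sex covariate is dropped and binary case counts are
#' re-checked against `min_cases`.
#'
#' @param burden A `burden_score` tibble (`sample_id, g`).
#' @param phenome Filtered phenome (see [filter_binary()],
#'   [filter_quantitative()]).
#' @param covariates Tibble `sample_id` + covariate columns (baseline age,
#'   sex, PCs).
#' @param strata Subset of `c("all", "male", "female")`.
#' @param n_phenome Denominator of the Bonferroni threshold; defaults to the
#'   configured phenome size (number of phenotype columns passed in).
#' @param min_cases Per-stratum binary case minimum (default 100).
#' @param firth_refit_p Plain-logistic p below which the Firth refit is run.
#' @return List: `results` tibble (`phenotype, stratum, model, effect, se,
#'   p, n, n_cases, refit_firth`), `threshold`, `skipped` log tibble.
#' @export
run_phewas <- function(burden, phenome, covariates,
                       strata = c("all", "male", "female"),
                       n_phenome = NULL, min_cases = 100,
                       firth_refit_p = 0.05) {
  phenome <- phenome_types(phenome)
  phenos <- setdiff(names(phenome$phenotypes), "sample_id")
  n_phenome <- n_phenome %||% length(phenos)
  threshold <- significance_threshold(0.05, n_phenome, 1)
  base <- dplyr::inner_join(burden, covariates, by = "sample_id") |>
    dplyr::inner_join(phenome$phenotypes, by = "sample_id")
  skipped <- list()
  rows <- list()
  for (st in strata) {
    df <- switch(st, all = base,
                 male = base[base$sex == "M", , drop = FALSE],
                 female = base[base$sex == "F", , drop = FALSE])
    covs <- setdiff(names(covariates), c("sample_id",
                                         if (st != "all") "sex"))
    Z <- df[, covs, drop = FALSE]
    if ("sex" %in% names(Z)) Z$sex <- as.numeric(Z$sex == "M")
    for (ph in phenos) {
      type <- phenome$types$type[phenome$types$phenotype == ph]
      y <- df[[ph]]
      if (type == "binary") {
        n_cases <- sum(y == 1, na.rm = TRUE)
        if (n_cases < min_cases || sum(y == 0, na.rm = TRUE) == 0) {
          skipped[[length(skipped) + 1L]] <- tibble::tibble(
            phenotype = ph, stratum = st, reason = "too_few_cases_in_stratum")
          next
        }
        res <- tryCatch(fit_logistic(y, df$g, Z), error = function(e) NULL)
        if (is.null(res)) {
          skipped[[length(skipped) + 1L]] <- tibble::tibble(
            phenotype = ph, stratum = st, reason = "logistic_failed")
          next
        }
        refit <- !is.na(res$p) && (res$p < firth_refit_p ||
                                     isTRUE(res$separated))
        if (refit) {
          res <- fit_firth(y, df$g, Z)
        }
        rows[[length(rows) + 1L]] <- dplyr::mutate(
          res, phenotype = ph, stratum = st, refit_firth = refit)
      } else {
        for (scale_ in c("linear", "linear_irnt")) {
          yy <- if (scale_ == "linear_irnt") irnt(y) else y
          ok <- !is.na(yy)
          if (sum(ok) < ncol(Z) + 3 || sd(yy[ok]) == 0) {
            skipped[[length(skipped) + 1L]] <- tibble::tibble(
              phenotype = ph, stratum = st, reason = "degenerate_quantitative")
            next
          }
          dfit <- data.frame(y = yy, g = df$g)
          if (ncol(Z)) dfit <- cbind(dfit, Z)
          sm <- summary(lm(y ~ ., data = dfit[ok, ]))$coefficients
          rows[[length(rows) + 1L]] <- tibble::tibble(
            model = scale_, effect = sm["g", 1], se = sm["g", 2],
            p = sm["g", 4], n = sum(ok), n_cases = NA_integer_,
            converged = TRUE, separated = NA, phenotype = ph, stratum = st,
            refit_firth = FALSE)
        }
      }
    }
  }
  results <- dplyr::bind_rows(rows) |>
    dplyr::select("phenotype", "stratum", "model", "effect", "se", "p",
                  "n", "n_cases", "refit_firth", "converged") |>
    dplyr::arrange(.data$p)
  list(results = results, threshold = threshold,
       skipped = dplyr::bind_rows(skipped))
}
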