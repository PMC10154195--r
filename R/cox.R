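## Cox proportional-hazards fitting by damped Newton maximisation of the
## partial likelihood, with Efron or Breslow handling of tied event times.
## The implementation works on time-sorted arrays with reverse cumulative
## sums over risk sets; only blocks of tied events need an inner loop.

revcs <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    if (n == 1L) return(x)
    idx <- n:1
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- cumsum(x[idx, j])[idx]
    out
  } else {
    rev(cumsum(rev(x)))
  }
}

fold_sym <- function(v, p, pairs) {
  M <- matrix(0, p, p)
  M[cbind(pairs[, 1], pairs[, 2])] <- v
  M[cbind(pairs[, 2], pairs[, 1])] <- v
  M
}

# log partial likelihood, score and information at beta
cox_lgi <- function(beta, Xs, XX, ev, evb, blk, bs_ev, d_k, sumX_D, ties,
                    pairs, p) {
  eta <- drop(Xs %*% beta)
  m <- max(eta)
  r <- exp(eta - m)
  S0 <- revcs(r)
  S1 <- revcs(r * Xs)
  S2 <- revcs(r * XX)
  S0k <- S0[bs_ev]
  S1k <- S1[bs_ev, , drop = FALSE]
  S2k <- S2[bs_ev, , drop = FALSE]
  # Efron: one base denominator term per block here, the remaining d-1 terms
  # per tied block below; Breslow: all d terms at once with weight d_k. Each
  # death contributes one eta and one log-denominator, so the max-shift m
  # cancels between the two sums.
  w0 <- if (ties == "efron") rep(1, length(S0k)) else d_k
  mu0 <- S1k / S0k
  ll <- sum(eta[ev] - m) - sum(w0 * log(S0k))
  grad <- colSums(sumX_D) - colSums(w0 * mu0)
  info <- fold_sym(colSums(w0 * S2k / S0k), p, pairs) -
    crossprod(sqrt(w0) * mu0)
  if (ties == "efron" && any(d_k > 1)) {
    rX <- r * Xs
    rXX <- r * XX
    sd0 <- as.numeric(rowsum(r[ev], evb))
    sd1 <- rowsum(rX[ev, , drop = FALSE], evb)
    sd2 <- rowsum(rXX[ev, , drop = FALSE], evb)
    for (kk in which(d_k > 1)) {
      d <- d_k[kk]
      for (l in seq_len(d - 1)) {
        a <- l / d
        den <- S0k[kk] - a * sd0[kk]
        mu <- (S1k[kk, ] - a * sd1[kk, ]) / den
        ll <- ll - log(den)
        grad <- grad - mu
        info <- info + fold_sym((S2k[kk, ] - a * sd2[kk, ]) / den, p, pairs) -
          tcrossprod(mu)
      }
    }
  }
  list(ll = ll, grad = grad, info = info)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the log partial likelihood of
#' `h(x) = h0(x) exp(beta * g + gamma' Z)` by damped Newton iteration
#' (step-halving on likelihood decrease, up to 10 halvings), with the Efron
#' (default) or Breslow correction for tied event times. The burden
#' predictor `g` is always the first coefficient; Wald z and two-sided
#' normal p-values are reported. Monotone-likelihood escape (|beta| growing
#' without bound, as happens when all carrier events precede all others) is
#' detected and flagged.
#'
#' @param time Follow-up times (age scale), positive.
#' @param event 0/1 event indicators.
#' @param g Burden predictor (numeric vector, or a `burden_score` tibble
#'   aligned by position).
#' @param Z Optional covariate matrix or data frame (factors are expanded).
#' @param ties `"efron"` or `"breslow"`.
#' @param max_iter,tol_grad,tol_rel Newton controls: iteration cap, gradient
#'   max-norm tolerance, relative log-likelihood change tolerance.
#' @return A `cox_fit` object: coefficients (`g` first), standard errors,
#'   `beta`, `se`, `hr`, `z`, `p` for the burden term, `gamma` for
#'   covariates, `loglik`, `loglik_null`, `n`, `n_events`, `converged`,
#'   `iterations`, flags `degenerate` and `monotone`, and the inverse
#'   information `var`.
#' @export
fit_cox <- function(time, event, g, Z = NULL, ties = c("efron", "breslow"),
                    max_iter = 25, tol_grad = 1e-6, tol_rel = 1e-9) {
  ties <- match.arg(ties)
  if (inherits(g, "burden_score") || is.data.frame(g)) g <- g$g
  n <- length(time)
  stopifnot(length(event) == n, length(g) == n, all(time > 0),
            all(event %in% c(0, 1)))
  if (sum(event) == 0) abort("no events: cannot fit a Cox model")
  X <- cbind(g = as.numeric(g), cox_design(Z, n))
  if (sd(X[, 1]) == 0) {
    fit <- empty_cox_fit(colnames(X), n, sum(event), ties)
    fit$degenerate <- TRUE
    return(fit)
  }
  keep <- apply(X, 2, function(col) sd(col) > 0)
  keep[1] <- TRUE
  X <- X[, keep, drop = FALSE]
  p <- ncol(X)
  o <- order(time)
  ts <- time[o]
  evs <- event[o]
  Xs <- X[o, , drop = FALSE]
  blk <- cumsum(!duplicated(ts))
  bstart <- which(!duplicated(ts))
  ev <- which(evs == 1)
  evb <- blk[ev]
  ub <- sort(unique(evb))
  bs_ev <- bstart[ub]
  d_k <- as.integer(rowsum(rep(1L, length(ev)), evb))
  sumX_D <- rowsum(Xs[ev, , drop = FALSE], evb)
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  XX <- Xs[, pairs[, 1], drop = FALSE] * Xs[, pairs[, 2], drop = FALSE]

  beta <- numeric(p)
  cur <- cox_lgi(beta, Xs, XX, ev, evb, blk, bs_ev, d_k, sumX_D, ties,
                 pairs, p)
  loglik_null <- cur$ll
  converged <- FALSE
  monotone <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    delta <- tryCatch(solve(cur$info, cur$grad), error = function(e) {
      solve(cur$info + diag(1e-8, p), cur$grad)
    })
    step <- 1
    for (h in 0:10) {
      cand <- beta + step * delta
      new <- cox_lgi(cand, Xs, XX, ev, evb, blk, bs_ev, d_k, sumX_D, ties,
                     pairs, p)
      if (is.finite(new$ll) && new$ll >= cur$ll - 1e-12) break
      step <- step / 2
    }
    rel <- abs(new$ll - cur$ll) / (abs(cur$ll) + 1e-12)
    beta <- cand
    cur <- new
    if (max(abs(beta)) > 15) {
      monotone <- TRUE
      break
    }
    if (max(abs(cur$grad)) < tol_grad || rel < tol_rel) {
      converged <- TRUE
      break
    }
  }
  # likelihood plateaued while an estimate keeps escaping: infinite MLE
  if (converged && max(abs(beta)) > 10 && max(abs(cur$grad)) > tol_grad) {
    monotone <- TRUE
  }
  V <- tryCatch(solve(cur$info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(diag(V))
  z <- beta / se
  pv <- 2 * pnorm(-abs(z))
  structure(list(
    coefficients = setNames(beta, colnames(X)),
    se_all = setNames(se, colnames(X)),
    beta = beta[1], se = se[1], hr = exp(beta[1]), z = z[1],
    p = max(pv[1], .Machine$double.xmin),
    gamma = if (p > 1) setNames(beta[-1], colnames(X)[-1]) else numeric(0),
    loglik = cur$ll, loglik_null = loglik_null,
    n = n, n_events = sum(event),
    converged = converged && !monotone, iterations = iter,
    degenerate = FALSE, monotone = monotone, ties = ties, var = V),
    class = "cox_fit")
}

cox_design <- function(Z, n) {
  if (is.null(Z)) return(matrix(numeric(0), n, 0))
  if (is.data.frame(Z)) {
    Z <- stats::model.matrix(~., data = Z)[, -1, drop = FALSE]
  }
  as.matrix(Z)
}

empty_cox_fit <- function(nms, n, n_events, ties) {
  structure(list(coefficients = setNames(rep(NA_real_, length(nms)), nms),
                 se_all = setNames(rep(NA_real_, length(nms)), nms),
                 beta = NA_real_, se = NA_real_, hr = NA_real_, z = NA_real_,
                 p = NA_real_, gamma = numeric(0),
                 loglik = NA_real_, loglik_null = NA_real_,
                 n = n, n_events = n_events, converged = FALSE,
                 iterations = 0L, degenerate = FALSE, monotone = FALSE,
                 ties = ties, var = NULL),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<cox_fit> degenerate: burden predictor is constant, no fit\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<cox_fit> n=%d, events=%d, ties=%s | HR=%.3f (beta=%.4f, se=%.4f), p=%.3g%s\n",
    x$n, x$n_events, x$ties, x$hr, x$beta, x$se, x$p,
    if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Cox fit into one row per coefficient
#'
#' @param x A `cox_fit`.
#' @param conf.int Add Wald 95% confidence limits for the hazard-ratio scale.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (log scale), `std.error`,
#'   `statistic`, `p.value` (and `conf.low`/`conf.high` on the HR scale).
#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, conf.int = FALSE, ...) {
  out <- tibble::tibble(term = names(x$coefficients),
                        estimate = unname(x$coefficients),
                        std.error = unname(x$se_all),
                        statistic = unname(x$coefficients / x$se_all),
                        p.value = 2 * pnorm(-abs(
                          unname(x$coefficients / x$se_all))))
  if (conf.int) {
    out$conf.low <- exp(out$estimate - 1.96 * out$std.error)
    out$conf.high <- exp(out$estimate + 1.96 * out$std.error)
  }
  out
}

#' One-row model summary of a Cox fit
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return A one-row tibble: n, events, log-likelihoods, convergence.
#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, logLik = x$loglik,
                 logLik_null = x$loglik_null, iterations = x$iterations,
                 converged = x$converged, monotone = x$monotone,
                 degenerate = x$degenerate, ties = x$ties)
}

#' Schoenfeld-residual test of proportional hazards
#'
#' Computes Schoenfeld residuals (observed minus risk-set-weighted mean
#' covariate) at each event time and tests, per coefficient, for a nonzero
#' slope of residual against event time in a linear model — a nonzero slope
#' indicates a hazard ratio drifting with age.
#'
#' @param fit A converged `cox_fit`.
#' @param time,event,g,Z The data the model was fitted to.
#' @return A tibble `term, slope, p`, with the residual table (one row per
#'   event) attached as attribute `"residuals"` for plotting.
#' @export
schoenfeld_ph_test <- function(fit, time, event, g, Z = NULL) {
  if (inherits(g, "burden_score") || is.data.frame(g)) g <- g$g
  if (sum(event) < 2) abort("need at least 2 events for the Schoenfeld test")
  X <- cbind(g = as.numeric(g), cox_design(Z, length(time)))
  X <- X[, names(fit$coefficients), drop = FALSE]
  o <- order(time)
  ts <- time[o]
  evs <- event[o]
  Xs <- X[o, , drop = FALSE]
  eta <- drop(Xs %*% fit$coefficients)
  r <- exp(eta - max(eta))
  S0 <- revcs(r)
  S1 <- revcs(r * Xs)
  blk <- cumsum(!duplicated(ts))
  bstart <- which(!duplicated(ts))
  ev <- which(evs == 1)
  xbar <- S1[bstart[blk[ev]], , drop = FALSE] / S0[bstart[blk[ev]]]
  res <- Xs[ev, , drop = FALSE] - xbar
  t_ev <- ts[ev]
  out <- purrr::map_dfr(seq_len(ncol(res)), function(j) {
    if (sd(res[, j]) == 0 || length(t_ev) < 3) {
      return(tibble::tibble(term = colnames(res)[j], slope = NA_real_,
                            p = NA_real_))
    }
    sm <- summary(lm(res[, j] ~ t_ev))$coefficients
    tibble::tibble(term = colnames(res)[j], slope = sm[2, 1], p = sm[2, 4])
  })
  resid_tbl <- tibble::as_tibble(as.data.frame(res))
  resid_tbl$time <- t_ev
  attr(out, "residuals") <- resid_tbl
  out
}
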