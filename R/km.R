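#' Kaplan–Meier product-limit survival estimate
#'
#' Survival is stepped down at each distinct event time by
#' `(1 - d/n)`; the 95% confidence band uses the Greenwood variance on the
#' log-survival scale, clipped to `[0, 1]`. Rows are emitted at every
#' distinct observed time so that right-censored observations can be marked.
#'
#' @param time Follow-up times.
#' @param event 0/1 event indicators.
#' @param group Optional grouping vector (e.g. carrier status); one curve
#'   per level.
#' @param conf_level Confidence level of the Greenwood band.
#' @return A `km_curve` tibble: `group, time, n_risk, n_event, n_censor,
#'   surv, se, ci_low, ci_high`.
#' @export
km_estimate <- function(time, event, group = NULL, conf_level = 0.95) {
  stopifnot(length(time) >= 1, length(event) == length(time))
  if (is.null(group)) group <- rep("all", length(time))
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- purrr::map_dfr(split(seq_along(time), group), function(idx) {
    t_g <- time[idx]
    e_g <- event[idx]
    ut <- sort(unique(t_g))
    n_risk <- vapply(ut, function(u) sum(t_g >= u), numeric(1))
    n_event <- vapply(ut, function(u) sum(t_g == u & e_g == 1), numeric(1))
    n_censor <- vapply(ut, function(u) sum(t_g == u & e_g == 0), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    gw <- cumsum(ifelse(n_risk > n_event,
                        n_event / (n_risk * (n_risk - n_event)), 0))
    se_log <- sqrt(gw)
    ci_low <- ifelse(surv > 0, pmax(0, exp(log(surv) - z * se_log)), 0)
    ci_high <- ifelse(surv > 0, pmin(1, exp(log(surv) + z * se_log)), 0)
    tibble::tibble(group = group[idx[1]], time = ut, n_risk = n_risk,
                   n_event = n_event, n_censor = n_censor, surv = surv,
                   se = surv * se_log, ci_low = ci_low, ci_high = ci_high)
  })
  class(out) <- c("km_curve", class(out))
  out
}

#' Plot Kaplan–Meier curves
#'
#' Step curves with a shaded Greenwood 95% band; each cross marks a
#' right-censored observation.
#'
#' @param object A `km_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  cens <- object[object$n_censor > 0, , drop = FALSE]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$surv,
                                       colour = .data$group,
                                       fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cens, shape = 3, size = 1.5,
                        show.legend = FALSE) +
    ggplot2::labs(x = "Age (years)", y = "Survival probability") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
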