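#' @importFrom rlang .data abort
#' @importFrom stats rbinom rpois runif rnorm rexp median pnorm qnorm pchisq
#'   lm glm binomial setNames sd
NULL

# Deterministic substream seed from (seed, label): polynomial string hash mod
# 2^31 - 1, combined additively. Pure integer arithmetic kept below 2^53 so the
# result is identical on every platform.
substream_seed <- function(seed, label) {
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h) %% 2147483647)
}

with_substream <- function(seed, label, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  force(code)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a fraction in [0, 1].", name))
  }
  invisible(x)
}

check_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x) ||
      (positive && x < 1) || (!positive && x < 0)) {
    abort(sprintf("`%s` must be a %s integer.", name,
                  if (positive) "positive" else "non-negative"))
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
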