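test_that("code aggregation unions sources idempotently", {
  records <- tibble::tibble(
    sample_id = c("A", "A", "B", "C"),
    code = c("C50", "C50", "C50", "E11"),
    source = c("primary", "secondary", "death", "primary"))
  samples <- c("A", "B", "C", "D")
  agg <- aggregate_codes(records, samples)
  expect_equal(agg$C50, c(1L, 1L, 0L, 0L))   # A counted once, B via death
  expect_equal(agg$C50[2], 1L)
  expect_equal(agg$E11, c(0L, 0L, 1L, 0L))
  expect_equal(agg$C50[agg$sample_id == "D"], 0L)
})

test_that("binary and quantitative filters sit exactly at their boundaries", {
  n <- 1200
  ph <- list(
    phenotypes = tibble::tibble(
      sample_id = sprintf("S%04d", 1:n),
      b99 = c(rep(1L, 99), rep(0L, n - 99)),
      b100 = c(rep(1L, 100), rep(0L, n - 100)),
      b_na = c(rep(1L, 99), NA, rep(0L, n - 100)),
      q499 = c(rnorm(499), rep(NA_real_, n - 499)),
      q500 = c(rnorm(500), rep(NA_real_, n - 500)),
      q_out = rnorm(n),
      q_flat = rep(1, n)),
    types = tibble::tibble(
      phenotype = c("b99", "b100", "b_na", "q499", "q500", "q_out", "q_flat"),
      type = c(rep("binary", 3), rep("quantitative", 4))))
  # plant one clear outlier and one value at exactly 5 sd
  x <- ph$phenotypes$q_out
  x[1] <- mean(x[-1])
  m <- mean(x)
  s <- sd(x)
  x[2] <- m + 6 * s
  ph$phenotypes$q_out <- x
  fb <- filter_binary(ph, min_cases = 100)
  expect_false("b99" %in% names(fb$phenotypes))
  expect_true("b100" %in% names(fb$phenotypes))
  expect_false("b_na" %in% names(fb$phenotypes))  # NA is not a case
  fq <- filter_quantitative(fb, min_obs = 500, sd_cut = 5)
  expect_false("q499" %in% names(fq$phenotypes))
  expect_true("q500" %in% names(fq$phenotypes))
  expect_true(is.na(fq$phenotypes$q_out[2]))      # > 5 sd masked
  expect_gte(fq$outliers_masked[["q_out"]], 1)
  expect_true("q_flat" %in% names(fq$phenotypes)) # zero variance retained
  expect_true("q_flat" %in% fq$flagged_zero_variance)
  # accounting: dropped + retained = input phenotypes
  expect_equal(nrow(fq$types) + nrow(fq$dropped), 7)
})

test_that("a value at exactly the sd cut survives the strict inequality", {
  # c(-1, 0 x 49, 1): mean 0, sd 0.2, so both extremes sit at exactly 5 s.d.
  x <- c(-1, rep(0, 49), 1)
  ph <- list(phenotypes = tibble::tibble(sample_id = seq_along(x), q = x),
             types = tibble::tibble(phenotype = "q", type = "quantitative"))
  fq <- filter_quantitative(ph, min_obs = 10, sd_cut = 5)
  expect_false(any(is.na(fq$phenotypes$q)))
  expect_equal(fq$outliers_masked[["q"]], 0L)
})

test_that("IRNT is a rank map to standard normal quantiles", {
  x <- c(3, 1, 2)
  out <- irnt(x)
  expect_equal(out[3], 0)                       # middle of odd length -> 0
  expect_equal(order(out), order(x))
  expect_equal(irnt(exp(x)), out)               # monotone-invariant
  big <- irnt(rnorm(10000))
  expect_lt(abs(mean(big)), 0.01)
  expect_lt(abs(sd(big) - 1), 0.02)
  y <- c(1, NA, 2)
  expect_true(is.na(irnt(y)[2]))
  expect_error(irnt(c(NA, NA, 1)), "at least 2")
})

test_that("Firth matches a grid search of the penalized likelihood under separation", {
  # 2x2 perfectly separated table
  y <- c(rep(1, 10), rep(0, 10))
  g <- y
  plain <- fit_logistic(y, g)
  expect_true(plain$separated)
  fir <- fit_firth(y, g)
  expect_true(fir$converged)
  expect_true(is.finite(fir$effect))
  # independent grid search of the penalized likelihood
  grid <- expand.grid(b0 = seq(-4, 4, by = 0.02), b1 = seq(0, 8, by = 0.02))
  ll <- mapply(naive_firth_loglik, grid$b0, grid$b1,
               MoreArgs = list(y = y, g = g))
  best <- grid[which.max(ll), ]
  expect_lt(abs(fir$effect - best$b1), 1e-3 + 0.02)
})

test_that("Firth and plain logistic agree on well-separated balanced data", {
  set.seed(21)
  n <- 10000
  g <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, stats::plogis(-0.2 + log(1.5) * g))
  a <- fit_logistic(y, g)
  b <- fit_firth(y, g)
  expect_false(a$separated)
  expect_lt(abs(a$effect - b$effect), 1e-3)
})

test_that("phewas runs all strata with Firth refits and the configured threshold", {
  cfg <- sim_config(n_individuals = 4000, n_genes = 2, seed = 8,
                    carrier_freq_range = c(0.008, 0.01),
                    phenome_params = list(n_binary = 4, n_quant = 4,
                                          planted_gene = NULL, planted_or = 8,
                                          planted_beta = -0.4,
                                          prevalence_planted = 0.05))
  co <- simulate_cohort(cfg)
  base <- co$raw_pheno[co$raw_pheno$instance == 0, ]
  covars <- base[, c("sample_id", "baseline_age", "sex")]
  burden <- tibble::tibble(
    sample_id = co$genotypes$samples,
    g = as.integer(co$genotypes$samples %in%
                     co$truth$carriers$sample_id[co$truth$carriers$gene ==
                                                   "G0001"]))
  phen <- filter_quantitative(filter_binary(co$phenome))
  res <- run_phewas(burden, phen, covars, n_phenome = 4130)
  expect_equal(res$threshold, 0.05 / 4130)
  r <- res$results
  # quantitative phenotypes appear on raw and IRNT scales
  expect_true(all(c("linear", "linear_irnt") %in%
                    r$model[r$phenotype == "quant_planted"]))
  # every significant binary fit carries the Firth refit
  sig_bin <- r[r$model %in% c("logistic", "firth_logistic") & r$p < 0.05, ]
  expect_true(all(sig_bin$refit_firth))
  expect_true(all(sig_bin$model == "firth_logistic"))
  # the planted association is recovered where it was planted
  planted <- r[r$phenotype == "bin_planted" & r$stratum == "all", ]
  expect_gt(planted$effect, 0)
  expect_lt(planted$p, 0.05)
  # sex strata drop the sex covariate silently (no error) and re-filter
  expect_true(all(res$results$stratum %in% c("all", "male", "female")))
})
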