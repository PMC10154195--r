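test_that("proband survival uses death age or censor-date age", {
  raw <- raw_pheno_fixture()
  out <- build_proband_survival(raw)
  d <- out$data
  # born 1963-06, alive, censored June 2020 -> age 57.0 (to the month)
  expect_equal(d$time[d$sample_id == "P01"], 2020 + 5.5 / 12 - 1963.458,
               tolerance = 0.1)
  expect_equal(d$event[d$sample_id == "P01"], 0L)
  expect_equal(d$time[d$sample_id == "P02"], 63.2)
  expect_equal(d$event[d$sample_id == "P02"], 1L)
  # sex-restricted outcomes drop the sex covariate and log the other sex
  m <- build_proband_survival(raw, sex_restrict = "M")
  expect_false("sex" %in% names(m$data))
  expect_true(all(m$exclusions$reason == "other_sex"))
  expect_equal(nrow(m$data) + nrow(m$exclusions), nrow(raw))
})

test_that("parental outcomes apply every stated exclusion with full accounting", {
  raw <- raw_pheno_fixture()
  fa <- build_parent_survival(raw, "father")
  expect_equal(fa$exclusions$reason[fa$exclusions$sample_id == "P03"],
               "adopted")
  expect_equal(fa$exclusions$reason[fa$exclusions$sample_id == "P04"],
               "unknown_answer")
  expect_equal(fa$exclusions$reason[fa$exclusions$sample_id == "P05"],
               "early_parent_death")
  expect_equal(fa$exclusions$reason[fa$exclusions$sample_id == "P09"],
               "implausible_age")
  expect_equal(nrow(fa$data) + nrow(fa$exclusions), nrow(raw))
  # alive father at 81 -> censored at 81
  expect_equal(fa$data$time[fa$data$sample_id == "P02"], 81)
  expect_equal(fa$data$event[fa$data$sample_id == "P02"], 0L)
  # dead father at 80 -> event at 80
  expect_equal(fa$data$time[fa$data$sample_id == "P01"], 80)
  expect_equal(fa$data$event[fa$data$sample_id == "P01"], 1L)
})

test_that("combined-parent time sums ages and fires only on double death", {
  raw <- raw_pheno_fixture()
  cp <- build_combined_parent(raw)
  d <- cp$data
  # father dead 80 + mother dead 79 -> 159, event
  expect_equal(d$time[d$sample_id == "P01"], 159)
  expect_equal(d$event[d$sample_id == "P01"], 1L)
  # father alive 81 + mother alive 75 -> censored at 156
  expect_equal(d$time[d$sample_id == "P02"], 156)
  expect_equal(d$event[d$sample_id == "P02"], 0L)
  # either parent excluded -> sample excluded (mother unknown for P06)
  expect_true("P06" %in% cp$exclusions$sample_id)
  expect_equal(nrow(d) + nrow(cp$exclusions), nrow(raw))
})

test_that("latest assessment wins, falling back when the repeat is silent", {
  raw <- raw_pheno_fixture()[1:2, ]
  rep1 <- raw[1, ]
  rep1$instance <- 1L
  rep1$visit_year <- 2013
  rep1$father_status <- "dead"
  rep1$father_age <- 84
  rep2 <- raw[2, ]
  rep2$instance <- 1L
  rep2$father_status <- NA_character_
  rep2$father_age <- NA_real_
  sel <- select_latest_assessment(dplyr::bind_rows(raw, rep1, rep2))
  expect_equal(nrow(sel), 2)
  # updated answer used
  expect_equal(sel$father_age[sel$sample_id == "P01"], 84)
  expect_equal(sel$father_status[sel$sample_id == "P01"], "dead")
  # silent repeat falls back to baseline
  expect_equal(sel$father_age[sel$sample_id == "P02"], 81)
  # single assessment is the identity
  single <- select_latest_assessment(raw)
  expect_equal(single$father_age, raw$father_age)
})

test_that("relatedness exclusion breaks all close pairs and no more", {
  pairs <- tibble::tibble(sample_a = c("A", "B", "C", "D"),
                          sample_b = c("B", "C", "A", "E"),
                          degree = c(2L, 2L, 2L, 3L))
  samples <- c("A", "B", "C", "D", "E")
  kept <- exclude_related(samples, pairs, seed = 4)
  # triangle of close pairs: at least two removed, output pair-free
  expect_lte(length(intersect(kept, c("A", "B", "C"))), 1)
  # third-degree pair untouched
  expect_true(all(c("D", "E") %in% kept))
  # independent scan + idempotence
  left <- pairs[pairs$degree <= 2 & pairs$sample_a %in% kept &
                  pairs$sample_b %in% kept, ]
  expect_equal(nrow(left), 0)
  expect_setequal(exclude_related(kept, pairs, seed = 4), kept)
  # determinism; single pair removes exactly one member
  one <- tibble::tibble(sample_a = "X", sample_b = "Y", degree = 1L)
  k1 <- exclude_related(c("X", "Y"), one, seed = 7)
  expect_length(k1, 1)
  expect_identical(k1, exclude_related(c("X", "Y"), one, seed = 7))
})

test_that("exhaustive check on small graphs: output always pair-free", {
  set.seed(42)
  for (i in 1:20) {
    n <- 6
    ids <- LETTERS[1:n]
    m <- matrix(runif(n * n) < 0.3, n, n)
    pairs <- which(upper.tri(m) & m, arr.ind = TRUE)
    if (!nrow(pairs)) next
    tbl <- tibble::tibble(sample_a = ids[pairs[, 1]],
                          sample_b = ids[pairs[, 2]],
                          degree = sample(1:2, nrow(pairs), replace = TRUE))
    kept <- exclude_related(ids, tbl, seed = i)
    # brute force over all subsets: kept must be one of the pair-free sets
    pair_free <- function(cand) {
      nrow(tbl[tbl$sample_a %in% cand & tbl$sample_b %in% cand, ]) == 0
    }
    expect_true(pair_free(kept))
    # and every removed sample had at least one close pair (no over-removal
    # of isolated samples)
    removed <- setdiff(ids, kept)
    expect_true(all(removed %in% c(tbl$sample_a, tbl$sample_b)))
  }
})

test_that("ancestry filter is a strict conjunction with logged missing flags", {
  raw <- raw_pheno_fixture()
  raw$genetic_caucasian[1] <- NA
  kept <- apply_ancestry_filter(raw$sample_id, raw)
  excl <- attr(kept, "exclusions")
  expect_false("P01" %in% kept)   # missing flag
  expect_false("P09" %in% kept)   # self-report FALSE
  expect_false("P10" %in% kept)   # genetic flag FALSE
  expect_true("P02" %in% kept)
  expect_equal(excl$reason[excl$sample_id == "P01"], "missing_ancestry_flag")
  expect_equal(length(kept) + nrow(excl), nrow(raw))
})
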