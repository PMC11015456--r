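test_that("an empty cohort is valid and a missing seed is not", {
  p <- cohort_params(n = 0)
  cohort <- generate_cohort(p, seed = 1)
  expect_s3_class(cohort, "synthetic_cohort")
  expect_equal(nrow(cohort), 0)
  expect_error(generate_cohort(p), "seed")
  expect_error(summarize_cohort(cohort), "empty")
})

test_that("invalid probabilities fail validation before any sampling", {
  expect_error(cohort_params(advanced_prob = 1.2), "advanced_prob")
  expect_error(cohort_params(retest_prob = -0.1), "retest_prob")
  vt <- default_variant_table()
  vt$freq <- vt$freq * 3
  expect_error(cohort_params(variant_table = vt), "sum to at most 1")
})

test_that("same parameters and seed give bitwise-identical cohorts", {
  p <- cohort_params(n = 300)
  c1 <- generate_cohort(p, seed = 77)
  c2 <- generate_cohort(p, seed = 77)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(c1, f1); write_cohort(c2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  c3 <- generate_cohort(p, seed = 78)
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(101)
  a <- runif(5)
  set.seed(101)
  invisible(generate_cohort(cohort_params(n = 50), seed = 1))
  expect_identical(runif(5), a)
})

test_that("the advanced-stage fraction converges to its parameter", {
  p <- cohort_params(n = 10000, advanced_prob = 0.781)
  cohort <- generate_cohort(p, seed = 4)
  se <- sqrt(0.781 * (1 - 0.781) / 10000)
  expect_lt(abs(mean(cohort$stage == "advanced") - 0.781), 3 * se)
})

test_that("therapy is only ever assigned to eligible advanced cases", {
  p <- cohort_params(n = 5000)
  cohort <- generate_cohort(p, seed = 5)
  treated <- !is.na(cohort$therapy_gene)
  expect_true(all(cohort$stage[treated] == "advanced"))
  reimb <- with(p$variant_table, gene[reimbursed])
  expect_true(all(cohort$therapy_gene[treated] %in% reimb))
  expect_true(all(cohort$gene[treated] == cohort$therapy_gene[treated]))
  # and every eligible advanced case is treated
  eligible <- cohort$stage == "advanced" & cohort$gene %in% reimb
  expect_identical(treated, eligible)
  # confirmed cases always used at least one orthogonal method
  expect_true(all(cohort$tat_days > 0))
})

test_that("generator parameters are recovered within 3 SE at n = 5000", {
  p <- cohort_params(n = 5000)
  n <- p$n
  pass <- 0L
  for (seed in 1:20) {
    cohort <- generate_cohort(p, seed = seed)
    s <- summarize_cohort(cohort)
    overall_tat_mean <- p$tat_base_mean +
      (1 - (1 - p$retest_prob) * (1 - p$orthogonal_prob)) *
        p$repeat_delay_mean
    tat_sd <- stats::sd(cohort$tat_days)
    ok <- abs(s$advanced_fraction - 0.781) <
            3 * sqrt(0.781 * 0.219 / n) &&
          abs(s$retest_rate - 0.038) < 3 * sqrt(0.038 * 0.962 / n) &&
          abs(s$orthogonal_rate - 0.10) < 3 * sqrt(0.10 * 0.90 / n) &&
          abs(s$tat_mean - overall_tat_mean) < 3 * tat_sd / sqrt(n)
    pass <- pass + ok
  }
  expect_gte(pass, 19L)
})

test_that("the routine-workflow TAT mean sits near 9.44 and the overall near 9.89", {
  cohort <- generate_cohort(cohort_params(n = 5000), seed = 6)
  incl <- summarize_cohort(cohort)
  excl <- summarize_cohort(cohort, exclude_repeats = TRUE)
  expect_equal(incl$tat_mean, 9.89, tolerance = 0.02)
  expect_equal(excl$tat_mean, 9.44, tolerance = 0.02)
  expect_lt(excl$tat_mean, incl$tat_mean)
})

test_that("cohort summaries match hand arithmetic on a built cohort", {
  cohort <- data.frame(
    case_id = paste0("c", 1:4), stage = c("advanced", "early",
                                          "advanced", "advanced"),
    gene = c("EGFR", "WT", "WT", "ALK"),
    escat_tier = c("I", NA, NA, "I"),
    retest = c(FALSE, FALSE, FALSE, TRUE),
    orth_ihc = FALSE, orth_pcr = FALSE,
    tat_days = c(8, 10, 12, 20),
    therapy_gene = c("EGFR", NA, NA, "ALK"), stringsAsFactors = FALSE)
  s_incl <- summarize_cohort(cohort)
  s_excl <- summarize_cohort(cohort, exclude_repeats = TRUE)
  expect_equal(s_incl$tat_mean, 12.5)
  expect_equal(s_excl$tat_mean, 10.0)
  expect_equal(s_incl$n_escat_i_ii, 2)
  expect_equal(s_incl$retest_rate, 0.25)
})

test_that("cohort CSV round-trips through write/read", {
  cohort <- generate_cohort(cohort_params(n = 40), seed = 9)
  f <- tempfile(fileext = ".csv")
  write_cohort(cohort, f)
  back <- read_cohort(f)
  expect_equal(back$gene, cohort$gene)
  expect_equal(back$tat_days, cohort$tat_days, tolerance = 1e-12)
  sidecar <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(sidecar$seed, 9)
  expect_equal(sidecar$params_hash, attr(cohort, "params_hash"))
})
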