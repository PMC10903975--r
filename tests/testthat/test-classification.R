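test_that("AVLT process-score formulas are applied verbatim", {
  df <- tibble::tibble(
    avlt_trial1 = 3, avlt_trial2 = 6, avlt_trial3 = 8, avlt_trial4 = 11,
    avlt_trial5 = 13, avlt_trial6 = 6,
    intrusions_t1 = 1, intrusions_t2 = 0, intrusions_t3 = 2,
    intrusions_t4 = 0, intrusions_t5 = 1, intrusions_t6 = 0
  )
  out <- compute_process_scores(df)
  expect_equal(out$learning_slope, 2.0)
  expect_equal(out$retroactive_interference, 6 / 13)
  expect_equal(out$total_intrusions, 4)

  # the published worked ratio: trial6 = 6, trial5 = 8
  out2 <- compute_process_scores(tibble::tibble(
    avlt_trial1 = 5, avlt_trial5 = 8, avlt_trial6 = 6))
  expect_equal(out2$retroactive_interference, 0.75)

  # trial 5 of zero leaves retroactive interference undefined, not zero
  out3 <- compute_process_scores(tibble::tibble(
    avlt_trial1 = 0, avlt_trial5 = 0, avlt_trial6 = 0))
  expect_true(is.na(out3$retroactive_interference))
})

test_that("norm fitting recovers a noiseless linear generating model exactly", {
  set.seed(1)
  n <- 60
  df <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:n), is_normative = TRUE,
    age = runif(n, 60, 85), education = runif(n, 10, 20),
    sex = rbinom(n, 1, 0.5)
  )
  df$score <- 30 - 0.1 * df$age + 0.2 * df$education + 1 * df$sex
  norms <- fit_norms(df, tests = "score")
  m <- tidy(norms)
  expect_equal(m$intercept, 30, tolerance = 1e-8)
  expect_equal(m$b_age, -0.1, tolerance = 1e-8)
  expect_equal(m$b_edu, 0.2, tolerance = 1e-8)
  expect_equal(m$b_sex, 1, tolerance = 1e-8)
  expect_lt(m$see, 1e-8)
})

test_that("a constant score column yields zero weights and the constant intercept", {
  df <- tibble::tibble(
    is_normative = TRUE, age = runif(20, 60, 85),
    education = runif(20, 12, 20), sex = rep(0:1, 10), score = 7
  )
  m <- tidy(fit_norms(df, tests = "score"))
  expect_equal(m$intercept, 7)
  expect_equal(c(m$b_age, m$b_edu, m$b_sex), c(0, 0, 0))
  expect_equal(m$see, 0)
})

test_that("degenerate designs and small samples are rejected with clear errors", {
  df <- tibble::tibble(is_normative = TRUE, age = rep(70, 20),
                       education = runif(20, 12, 20), sex = rep(0:1, 10),
                       score = rnorm(20))
  expect_error(fit_norms(df, tests = "score"), "age")
  expect_error(fit_norms(df[1:5, ], tests = "score"), "at least 10")
})

test_that("z-scores follow the (observed - predicted)/SEE formula with orientation", {
  m <- list(intercept = 25, b_age = 0, b_edu = 0, b_sex = 0, see = 2.5)
  expect_equal(compute_z(20, m, 70, 16, 1), -2)
  expect_equal(compute_z(25, m, 70, 16, 1), 0)
  # timed test: 60 s observed vs 30 s predicted at SEE 10 is 3 SD slower,
  # oriented to z = -3
  mt <- list(test = "tmt_a", intercept = 30, b_age = 0, b_edu = 0, b_sex = 0, see = 10)
  expect_equal(compute_z(60, mt, 70, 16, 1), -3)
  # missing covariate propagates to a missing z
  expect_true(is.na(compute_z(20, m, NA, 16, 1)))
})

test_that("orientation makes worse performance weakly decrease z on every test", {
  norms <- demo_norms()
  dict <- test_dictionary()
  for (i in seq_len(nrow(dict))) {
    m <- tidy(norms)[tidy(norms)$test == dict$test[i], ]
    z_good <- compute_z(if (dict$higher_better[i]) 100 else 1, m, 72, 16, 0.5)
    z_bad <- compute_z(if (dict$higher_better[i]) 1 else 100, m, 72, 16, 0.5)
    expect_lt(z_bad, z_good)
  }
})

test_that("actuarial decision rules fire as specified", {
  base <- tibble::tibble(
    participant_id = "p1", age = 72, education = 16, sex = 1,
    avlt_delayed = 8.4, avlt_recognition = 12.8, bnt = 28.4, aft = 22,
    tmt_a = 29, tmt_b = 67, learning_slope = 1.33,
    retroactive_interference = 0.8, total_intrusions = 2
  )
  norms <- demo_norms()
  impair <- function(df, cols) {
    dict <- test_dictionary()
    m <- tidy(norms)
    for (cl in cols) {
      hb <- dict$higher_better[dict$test == cl]
      mu <- m$intercept[m$test == cl]
      sdv <- m$see[m$test == cl]
      df[[cl]] <- if (hb) mu - 3 * sdv else mu + 3 * sdv
    }
    df
  }
  lab <- function(df) classify_participant(zscore_cohort(df, norms))$label

  # two impaired totals in the memory domain -> MCI
  expect_equal(lab(impair(base, c("avlt_delayed", "avlt_recognition"))), "MCI")
  # one impaired total in each of the three domains -> MCI
  expect_equal(lab(impair(base, c("avlt_delayed", "bnt", "tmt_a"))), "MCI")
  # two impaired process scores only -> Obj-SCD
  expect_equal(lab(impair(base, c("learning_slope", "retroactive_interference"))),
               "Obj-SCD")
  # impaired totals in two different domains -> Obj-SCD
  expect_equal(lab(impair(base, c("avlt_delayed", "bnt"))), "Obj-SCD")
  # one impaired total plus one impaired process score -> Obj-SCD
  expect_equal(lab(impair(base, c("bnt", "total_intrusions"))), "Obj-SCD")
  # no flags -> CN
  expect_equal(lab(base), "CN")
  # boundary: z exactly -1 is not impaired (strict inequality)
  m <- tidy(norms)
  b <- base
  b$avlt_delayed <- m$intercept[m$test == "avlt_delayed"] - m$see[m$test == "avlt_delayed"]
  b$bnt <- m$intercept[m$test == "bnt"] - m$see[m$test == "bnt"]
  expect_equal(lab(b), "CN")
})

test_that("amyloid stratification uses the strict 192 pg/mL cutoff", {
  expect_equal(amyloid_stratify(c(150, 192, 191.99, NA)),
               c("A+", "A-", "A+", "unknown"))
  expect_error(amyloid_stratify(-5), "negative")
})

test_that("cohort classification recovers planted labels and calibrated norms", {
  cohort <- generate_phenotypes(cohort_spec(seed = 31))
  cls <- classify_cohort(cohort$phenotypes)
  merged <- dplyr::left_join(cohort$truth,
                             cls$labels[, c("participant_id", "label")],
                             by = "participant_id")
  expect_gt(mean(merged$label == merged$true_label), 0.85)

  # robust normative subsample: oriented z approximately standard normal,
  # per-test impairment fraction near the Gaussian tail mass at -1
  norm_ids <- cohort$phenotypes$participant_id[cohort$phenotypes$is_normative]
  zn <- cls$zprofile[cls$zprofile$participant_id %in% norm_ids, ]
  stats <- dplyr::summarise(dplyr::group_by(zn, test),
                            m = mean(z), s = sd(z), frac = mean(impaired))
  expect_true(all(abs(stats$m) < 0.1))
  expect_true(all(abs(stats$s - 1) < 0.1))
  expect_true(all(abs(stats$frac - pnorm(-1)) < 0.05))
})

test_that("labels partition the cohort and reclassification is idempotent", {
  cohort <- generate_phenotypes(cohort_spec(n_per_group = c(12, 10, 14),
                                            n_normative = 60, seed = 8))
  cls <- classify_cohort(cohort$phenotypes)
  expect_true(all(cls$labels$label %in% c("CN", "Obj-SCD", "MCI", "unclassifiable")))
  expect_equal(nrow(cls$labels), nrow(cohort$phenotypes))
  # re-classifying the labelled table with the same norms reproduces labels
  cls2 <- classify_cohort(cls$labels, norms = cls$norms)
  expect_identical(cls2$labels$label, cls$labels$label)
})

test_that("an empty table classifies to an empty result", {
  cls <- classify_cohort(tibble::tibble(), norms = demo_norms())
  expect_equal(nrow(cls$labels), 0)
  expect_equal(sum(cls$counts$n), 0)
})

test_that("norms serialize to JSON and back without loss", {
  cohort <- generate_phenotypes(cohort_spec(n_per_group = c(5, 5, 5),
                                            n_normative = 40, seed = 4))
  norms <- fit_norms(cohort$phenotypes)
  path <- withr::local_tempfile(fileext = ".json")
  write_norms(norms, path)
  back <- read_norms(path)
  expect_equal(tidy(back), tidy(norms), tolerance = 1e-12)
})
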