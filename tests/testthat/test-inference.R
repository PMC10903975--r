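test_that("summary-statistic ANOVA equals full-data ANOVA exactly", {
  set.seed(4)
  g <- rep(c("a", "b", "c"), times = c(12, 9, 15))
  y <- rnorm(36, mean = rep(c(0, 0.5, 1), times = c(12, 9, 15)))
  s <- tibble::tibble(
    mean = tapply(y, g, mean), sd = tapply(y, g, sd),
    n = as.numeric(table(g))
  )
  ours <- anova_oneway_from_summary(s)
  full <- anova(aov(y ~ g))
  expect_equal(ours$statistic, full$`F value`[1], tolerance = 1e-10)
  expect_equal(ours$df1, full$Df[1])
  expect_equal(ours$df2, full$Df[2])
  expect_equal(ours$p.value, full$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("summary ANOVA degenerate and error cases behave", {
  expect_equal(anova_oneway_from_summary(means = c(5, 5, 5), sds = c(1, 2, 1),
                                         ns = c(10, 10, 10))$statistic, 0)
  expect_error(anova_oneway_from_summary(means = 5, sds = 1, ns = 10), "2 groups")
  expect_error(anova_oneway_from_summary(means = c(1, 1), sds = c(0, 0),
                                         ns = c(5, 5)), "undefined")
})

test_that("chi-square matches hand computation and is invariant to permutation", {
  tab <- rbind(c(24, 14, 27), c(18, 15, 28))
  res <- chi_square_independence(tab)
  # independent hand computation from marginals
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - e)^2 / e), tolerance = 1e-12)
  expect_equal(res$df, 2)
  # row/column permutation invariance
  perm <- chi_square_independence(tab[2:1, c(3, 1, 2)])
  expect_equal(perm$statistic, res$statistic, tolerance = 1e-12)
  # multiplying all counts scales the statistic linearly
  expect_equal(chi_square_independence(tab * 3)$statistic, 3 * res$statistic,
               tolerance = 1e-10)
  # proportional table has no association
  expect_equal(chi_square_independence(rbind(c(10, 10), c(20, 20)))$statistic, 0)
  expect_error(chi_square_independence(rbind(c(0, 0), c(2, 3))), "marginal")
  expect_error(chi_square_independence(rbind(c(1.5, 2), c(2, 3))), "integers")
})

test_that("partial correlation reduces to Pearson and matches the precision matrix", {
  set.seed(11)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  expect_equal(partial_correlation(x, y)$estimate, cor(x, y), tolerance = 1e-12)
  expect_equal(partial_correlation(x, x + 0, covariates = NULL)$estimate, 1)

  covs <- matrix(rnorm(40 * 4), 40, 4)
  res <- partial_correlation(x, y, covs)
  # inverse-correlation-matrix oracle
  r <- cor(cbind(x, y, covs))
  p <- solve(r)
  oracle <- -p[1, 2] / sqrt(p[1, 1] * p[2, 2])
  expect_equal(res$estimate, oracle, tolerance = 1e-10)
  expect_equal(res$df, 40 - 4 - 2)
  expect_error(partial_correlation(x, y, cbind(covs[, 1], covs[, 1])), "collinear")
})

test_that("post hoc LSD contrast is zero for identical groups and gated on the omnibus", {
  set.seed(21)
  v <- rnorm(30)
  design <- tibble::tibble(group = rep(c("CN", "Obj-SCD"), each = 15),
                           age = rnorm(30, 72, 5))
  res <- posthoc_lsd(rep(v[1:15], 2), design, c("Obj-SCD", "CN"),
                     covariates = character(0))
  expect_equal(res$estimate, 0, tolerance = 1e-10)
  expect_equal(res$statistic, 0, tolerance = 1e-10)

  # planted shift: contrast detected and omnibus gate open
  design3 <- tibble::tibble(group = rep(c("CN", "Obj-SCD", "MCI"), each = 20),
                            age = rnorm(60, 72, 5))
  val <- rnorm(60) + ifelse(design3$group == "Obj-SCD", 2, 0)
  r2 <- posthoc_lsd(val, design3, c("Obj-SCD", "CN"), covariates = "age")
  expect_true(r2$gated)
  expect_gt(r2$statistic, 2)
  expect_error(posthoc_lsd(val, design3, c("Obj-SCD", "XX")), "not present")
})

test_that("repeated-measures interaction equals the change-score ANCOVA", {
  set.seed(31)
  n <- 24
  d <- tibble::tibble(
    subject = rep(sprintf("s%02d", 1:n), each = 2),
    group = rep(rep(c("CN", "Obj-SCD"), each = n / 2), each = 2),
    time = rep(c("baseline", "month6"), n),
    age = rep(rnorm(n, 72, 5), each = 2)
  )
  subj_eff <- rep(rnorm(n), each = 2)
  d$value <- subj_eff + ifelse(d$time == "month6" & d$group == "Obj-SCD", -1, 0) +
    rnorm(2 * n, sd = 0.3)
  res <- rm_interaction(d, pair = c("CN", "Obj-SCD"), covariates = "age")

  # oracle: lm on change scores
  wide <- tidyr::pivot_wider(d, id_cols = c(subject, group, age),
                             names_from = time, values_from = value)
  wide$change <- wide$month6 - wide$baseline
  fit <- lm(change ~ age + group, data = wide)
  tval <- summary(fit)$coefficients["groupObj-SCD", "t value"]
  expect_equal(res$statistic, tval^2, tolerance = 1e-10)
  expect_lt(res$p.value, 0.01)
})

test_that("interaction test excludes incomplete subjects and needs both groups", {
  d <- tibble::tibble(
    subject = c("a", "a", "b", "c", "c"),
    group = c("CN", "CN", "CN", "Obj-SCD", "Obj-SCD"),
    time = c("t1", "t2", "t1", "t1", "t2"),
    value = c(1, 2, 3, 4, 5)
  )
  expect_warning(res <- rm_interaction(d, c("CN", "Obj-SCD")),
                 "missing a timepoint")
  expect_equal(res$n, 2)
  expect_error(rm_interaction(d, c("CN", "XX")), "not present")
})

test_that("a pure group shift without time effect gives a null interaction", {
  set.seed(41)
  rejections <- 0
  fstats <- numeric(200)
  for (r in 1:200) {
    n <- 20
    d <- tibble::tibble(
      subject = rep(sprintf("s%02d", 1:n), each = 2),
      group = rep(rep(c("CN", "MCI"), each = n / 2), each = 2)[1:(2 * n)],
      time = rep(c("t1", "t2"), n)
    )
    # group shifts level only; both groups change identically over time
    d$value <- rep(rnorm(n), each = 2) + ifelse(d$group == "MCI", 3, 0) +
      ifelse(d$time == "t2", -0.5, 0) + rnorm(2 * n, sd = 0.5)
    res <- rm_interaction(d, c("CN", "MCI"))
    fstats[r] <- res$statistic
    rejections <- rejections + (res$p.value < 0.05)
  }
  expect_lt(abs(mean(fstats) - 1), 0.35)   # F under H0 has mean ~ df2/(df2-2)
  expect_lt(rejections / 200, 0.12)
})

test_that("demographics table reproduces group summaries with ANOVA and chi-square", {
  phen <- generate_phenotypes(cohort_spec(n_per_group = c(20, 20, 20),
                                          n_normative = 0, seed = 6))$phenotypes
  tab <- demographics_table(phen, variables = c("age", "avlt_delayed"))
  expect_setequal(tab$variable, c("sex", "age", "avlt_delayed"))
  # oracle: aov on the raw data for age
  full <- anova(aov(age ~ group, data = phen))
  expect_equal(tab$statistic[tab$variable == "age"], full$`F value`[1],
               tolerance = 1e-10)
})
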