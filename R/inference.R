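#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the one-way ANOVA F statistic from per-group means, SDs and
#' sample sizes (no raw data required):
#' SS_between = sum n_i (m_i - m)^2 with m the weighted grand mean, and
#' SS_within = sum (n_i - 1) SD_i^2; F = MS_between / MS_within with
#' df = (k - 1, N - k). Applied to summaries computed from raw data this is
#' algebraically identical to the full-data one-way ANOVA.
#'
#' @param data Data frame with columns `mean`, `sd`, `n` (one row per
#'   group), or `NULL` when the vectors are given directly.
#' @param means,sds,ns Numeric vectors (alternative to `data`).
#' @return One-row tibble: `statistic`, `df1`, `df2`, `p.value`.
#' @export
#' @examples
#' anova_oneway_from_summary(
#'   tibble::tibble(mean = c(71.29, 71.97, 73.58),
#'                  sd = c(6.85, 6.47, 6.66), n = c(42, 29, 55)))
anova_oneway_from_summary <- function(data = NULL, means = NULL, sds = NULL, ns = NULL) {
  if (!is.null(data)) {
    means <- data$mean; sds <- data$sd; ns <- data$n
  }
  k <- length(means)
  if (k < 2) stopf("need at least 2 groups")
  if (length(sds) != k || length(ns) != k) stopf("means, sds, ns must have equal length")
  if (any(ns < 2)) stopf("each group needs n >= 2")
  if (any(sds < 0)) stopf("SDs must be nonnegative")
  n_total <- sum(ns)
  grand <- sum(ns * means) / n_total
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum((ns - 1) * sds^2)
  df1 <- k - 1
  df2 <- n_total - k
  if (ss_w == 0 && ss_b == 0) stopf("zero within- and between-group variance; F undefined")
  f <- (ss_b / df1) / (ss_w / df2)
  tibble::tibble(statistic = f, df1 = df1, df2 = df2,
                 p.value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Pearson chi-square test of independence
#'
#' Pearson X^2 on a contingency table of counts, expected values from the
#' row/column marginals, without continuity correction;
#' df = (r - 1)(c - 1).
#'
#' @param counts Matrix (or data frame) of nonnegative integer counts.
#' @return One-row tibble: `statistic`, `df`, `p.value`.
#' @export
#' @examples
#' chi_square_independence(rbind(c(24, 14, 27), c(18, 15, 28)))
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("counts must be nonnegative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stopf("contingency table has a zero marginal")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p.value = unname(ct$p.value))
}

# residualize a vector (or columns of a matrix) on covariates + intercept
residualize <- function(y, covariates = NULL) {
  x <- cbind(intercept = rep(1, NROW(y)),
             if (!is.null(covariates)) as.matrix(covariates))
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) stopf("collinear covariates in residualization")
  qr.resid(qrx, as.matrix(y))
}

#' Partial correlation
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on the covariates,
#' with t-based two-sided p using df = n - (number of covariates) - 2. With
#' no covariates this is the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data frame / matrix of covariates.
#' @return One-row tibble: `estimate` (r), `statistic` (t), `df`, `p.value`,
#'   `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  keep <- stats::complete.cases(x, y, if (!is.null(covariates)) as.data.frame(covariates))
  x <- x[keep]; y <- y[keep]
  ncov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (!is.null(covariates)) covariates <- as.matrix(covariates)[keep, , drop = FALSE]
  n <- length(x)
  if (n <= ncov + 2) stopf("need n > number of covariates + 2")
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  r <- as.numeric(stats::cor(rx, ry))
  df <- n - ncov - 2
  tstat <- r * sqrt(df / (1 - r^2))
  tibble::tibble(estimate = r, statistic = tstat, df = df,
                 p.value = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE), n = n)
}

# covariate-adjusted three-group linear model shared by the post hoc and
# omnibus ROI tests; `data` must carry `value`, `group`, and covariate columns
roi_model_frame <- function(values, design) {
  d <- tibble::as_tibble(design)
  if (!"group" %in% names(d)) stopf("`design` must contain a `group` column")
  d$value <- values
  d$group <- factor(d$group, levels = intersect(c("CN", "Obj-SCD", "MCI"), unique(d$group)))
  d
}

#' Post hoc pairwise contrast with Fisher's LSD
#'
#' Pairwise group contrast on ROI values from the covariate-adjusted
#' three-group linear model, using the pooled error term across all groups.
#' Fisher's least-significant-difference convention: the pairwise p is
#' unadjusted but only interpreted when the omnibus group test is
#' significant (`gated` reports the gated decision).
#'
#' @param values Per-subject ROI values.
#' @param design Data frame with `group` and covariate columns (e.g. `age`,
#'   `sex`, `education`, `mean_fd`).
#' @param pair Character vector of two group labels, e.g.
#'   `c("Obj-SCD", "CN")`; the estimate is `pair[1] - pair[2]`.
#' @param covariates Names of the covariate columns in `design` to adjust
#'   for; defaults to all columns except `group`.
#' @param alpha Test level for the omnibus gate (default 0.05).
#' @return One-row tibble: `contrast`, `estimate`, `statistic` (t), `df`,
#'   `p.value` (unadjusted), `omnibus_p`, `gated` (significant under LSD).
#' @export
posthoc_lsd <- function(values, design, pair, covariates = NULL, alpha = 0.05) {
  d <- roi_model_frame(values, design)
  covariates <- covariates %||% setdiff(names(design), "group")
  if (!all(pair %in% levels(d$group))) {
    stopf("pair (%s) not present in the design groups", paste(pair, collapse = ", "))
  }
  fml <- stats::reformulate(c("group", covariates), response = "value")
  fit <- stats::lm(fml, data = d)
  fit0 <- stats::lm(stats::reformulate(c(covariates, "1"), response = "value"), data = d)
  omni <- stats::anova(fit0, fit)
  omnibus_p <- omni$`Pr(>F)`[2]
  # contrast vector for pair[1] - pair[2] on the treatment-coded fit
  cf <- stats::coef(fit)
  cn <- names(cf)
  w <- setNames(numeric(length(cf)), cn)
  term_of <- function(g) if (g == levels(d$group)[1]) NULL else paste0("group", g)
  for (s in c(1, -1)) {
    g <- pair[if (s == 1) 1 else 2]
    tm <- term_of(g)
    if (!is.null(tm)) w[tm] <- w[tm] + s
  }
  est <- sum(w * cf)
  se <- sqrt(drop(t(w) %*% stats::vcov(fit) %*% w))
  tstat <- est / se
  df <- fit$df.residual
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  tibble::tibble(contrast = paste(pair, collapse = " - "), estimate = est,
                 statistic = tstat, df = df, p.value = p,
                 omnibus_p = omnibus_p, gated = omnibus_p < alpha & p < alpha)
}

#' Group-by-time interaction for two timepoints
#'
#' Tests whether two groups change differently between baseline and
#' follow-up. For a two-timepoint design the mixed-model group-by-time
#' interaction is algebraically an ANCOVA on within-subject change scores:
#' the function regresses (value at timepoint 2 minus value at timepoint 1)
#' on group (optionally plus between-subject covariates) and reports the
#' partial F for group with df (1, n - p). Subjects missing a timepoint are
#' excluded with a warning.
#'
#' @param data Long data frame with columns `subject`, `group`, `time`
#'   (two levels), `value`, and any covariate columns.
#' @param pair Two group labels to compare.
#' @param covariates Character vector of covariate column names to adjust
#'   for (default none, plain repeated-measures ANOVA; the covariate-adjusted
#'   variant is the repeated-measures ANCOVA).
#' @return One-row tibble: `statistic` (F), `df1`, `df2`, `p.value`, `n`.
#' @export
rm_interaction <- function(data, pair, covariates = character(0)) {
  d <- tibble::as_tibble(data)
  need <- c("subject", "group", "time", "value")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) stopf("missing columns: %s", paste(miss, collapse = ", "))
  d <- d[d$group %in% pair, ]
  if (length(unique(d$group)) != 2) stopf("pair (%s) not present in the data",
                                          paste(pair, collapse = ", "))
  tlev <- sort(unique(d$time))
  if (length(tlev) != 2) stopf("`time` must have exactly two levels")
  wide <- tidyr::pivot_wider(
    d, id_cols = dplyr::all_of(c("subject", "group", covariates)),
    names_from = "time", values_from = "value"
  )
  complete <- stats::complete.cases(wide[, as.character(tlev)])
  if (any(!complete)) {
    warnf("excluding %d subject(s) missing a timepoint", sum(!complete))
    wide <- wide[complete, ]
  }
  wide$change <- wide[[as.character(tlev[2])]] - wide[[as.character(tlev[1])]]
  wide$group <- factor(wide$group, levels = pair)
  fml1 <- stats::reformulate(c("group", covariates), response = "change")
  fml0 <- stats::reformulate(c(covariates, "1"), response = "change")
  fit1 <- stats::lm(fml1, data = wide)
  fit0 <- stats::lm(fml0, data = wide)
  a <- stats::anova(fit0, fit1)
  tibble::tibble(statistic = a$F[2], df1 = a$Df[2], df2 = fit1$df.residual,
                 p.value = a$`Pr(>F)`[2], n = nrow(wide))
}

#' Demographic comparison table for a labelled cohort
#'
#' Reproduces a characteristics table: one-way ANOVA across the three groups
#' for continuous variables and a chi-square test for sex, from a labelled
#' phenotype table.
#'
#' @param data Phenotype data frame with a `group` column.
#' @param variables Continuous columns to compare (default the demographic
#'   and neuropsychological measures present).
#' @return Tibble with per-variable group means/SDs and the F (or X^2)
#'   statistic and p value.
#' @export
demographics_table <- function(data, variables = NULL) {
  variables <- variables %||% intersect(
    c("age", "education", "mmse", "avlt_delayed", "avlt_recognition", "aft",
      "bnt", "tmt_a", "tmt_b", "learning_slope", "retroactive_interference",
      "total_intrusions", "csf_abeta42", "csf_ptau181", "csf_ttau", "plasma_nfl"),
    names(data)
  )
  rows <- purrr::map(variables, function(v) {
    s <- data %>%
      dplyr::filter(!is.na(.data[[v]])) %>%
      dplyr::group_by(.data$group) %>%
      dplyr::summarise(mean = mean(.data[[v]]), sd = sd(.data[[v]]),
                       n = dplyr::n(), .groups = "drop")
    a <- anova_oneway_from_summary(s)
    tibble::tibble(variable = v, test = "anova",
                   statistic = a$statistic, p.value = a$p.value)
  })
  out <- purrr::list_rbind(rows)
  if ("sex" %in% names(data)) {
    tab <- table(data$sex, data$group)
    cs <- chi_square_independence(as.matrix(tab))
    out <- dplyr::bind_rows(
      tibble::tibble(variable = "sex", test = "chi_square",
                     statistic = cs$statistic, p.value = cs$p.value),
      out
    )
  }
  out
}
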