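new_norm_models <- function(models, source = "fitted") {
  structure(list(models = models, source = source), class = "norm_models")
}

#' Fit regression-based norms on a robust normative sample
#'
#' For each neuropsychological test, regresses the observed score on age,
#' education and sex by ordinary least squares in the robust normative rows
#' of a phenotype table, storing the b-weights and the standard error of the
#' estimate (SEE, residual standard error with denominator n - 4). These
#' norms define the demographically adjusted z-scores used by the actuarial
#' classifier.
#'
#' @param data Phenotype data frame. Rows used for fitting are those with
#'   `is_normative == TRUE` when that column exists, otherwise all rows.
#' @param tests Character vector of score columns to fit norms for; defaults
#'   to the nine measures in [test_dictionary()].
#' @return A `norm_models` object; [tidy()] returns the per-test weight table
#'   (`test`, `intercept`, `b_age`, `b_edu`, `b_sex`, `see`, `n`).
#' @export
#' @examples
#' cohort <- generate_phenotypes(cohort_spec(seed = 1))
#' norms <- fit_norms(cohort$phenotypes)
#' tidy(norms)
fit_norms <- function(data, tests = test_dictionary()$test) {
  if ("is_normative" %in% names(data)) data <- data[data$is_normative %in% TRUE, ]
  if (nrow(data) < 10) stopf("need at least 10 normative rows, got %d", nrow(data))
  for (v in c("age", "education", "sex")) {
    if (!v %in% names(data)) stopf("missing covariate column `%s`", v)
    if (stats::var(data[[v]], na.rm = TRUE) == 0) {
      stopf("covariate `%s` is constant in the normative sample; design is rank-deficient", v)
    }
  }
  miss <- setdiff(tests, names(data))
  if (length(miss) > 0) stopf("missing test columns: %s", paste(miss, collapse = ", "))

  fit_one <- function(test) {
    d <- data[stats::complete.cases(data[, c(test, "age", "education", "sex")]), ]
    y <- d[[test]]
    if (stats::var(y) == 0) {
      # constant response: all weights zero, intercept at the constant
      return(tibble::tibble(test = test, intercept = y[1], b_age = 0, b_edu = 0,
                            b_sex = 0, see = 0, n = nrow(d)))
    }
    fit <- stats::lm(y ~ age + education + sex, data = d)
    cf <- stats::coef(fit)
    res <- stats::residuals(fit)
    see <- sqrt(sum(res^2) / (nrow(d) - 4))
    tibble::tibble(
      test = test,
      intercept = cf[["(Intercept)"]],
      b_age = cf[["age"]], b_edu = cf[["education"]], b_sex = cf[["sex"]],
      see = see, n = nrow(d)
    )
  }
  models <- purrr::list_rbind(purrr::map(tests, fit_one))
  new_norm_models(models, source = sprintf("robust normative sample (n = %d)", nrow(data)))
}

#' @export
print.norm_models <- function(x, ...) {
  cat("<norm_models> fitted on", x$source, "\n")
  print(x$models)
  invisible(x)
}

#' @export
tidy.norm_models <- function(x, ...) x$models

#' @export
glance.norm_models <- function(x, ...) {
  tibble::tibble(n_tests = nrow(x$models), source = x$source,
                 median_see = stats::median(x$models$see))
}

#' Serialize norms to JSON
#'
#' Stores the per-test regression weights and SEE as a JSON document so norms
#' fitted on one cohort can be reused on another.
#'
#' @param norms A `norm_models` object.
#' @param path JSON file path.
#' @return `write_norms()` returns `path` invisibly; `read_norms()` returns a
#'   `norm_models` object.
#' @export
write_norms <- function(norms, path) {
  jsonlite::write_json(
    list(source = norms$source, models = norms$models),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_norms
#' @export
read_norms <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_norm_models(tibble::as_tibble(obj$models), source = obj$source)
}

# residual tolerance under which a degenerate (SEE = 0) norm model maps an
# exactly-predicted score to z = 0 rather than 0/0
.zero_see_tol <- 1e-6

#' Demographically adjusted z-score for one test
#'
#' Computes z = (observed - predicted) / SEE against a fitted normative
#' regression, then applies the score orientation so that z < -1 uniformly
#' denotes impairment (timed/error measures are sign-flipped). With a
#' degenerate model (SEE = 0, e.g. norms fitted on noiseless data) the limit
#' convention is used: z = 0 for an exactly predicted score, signed infinity
#' otherwise.
#'
#' @param observed Observed score(s).
#' @param model One row of a norms table (list or one-row data frame with
#'   `intercept`, `b_age`, `b_edu`, `b_sex`, `see`).
#' @param age,education,sex Covariates (sex coded 0 = male, 1 = female).
#' @param higher_better Orientation of the raw score; defaults to the
#'   [test_dictionary()] entry when `model` carries a `test` name, else `TRUE`.
#' @return Oriented z-score(s); `NA` where a covariate or score is missing.
#' @export
#' @examples
#' m <- list(intercept = 25, b_age = 0, b_edu = 0, b_sex = 0, see = 2.5)
#' compute_z(20, m, age = 70, education = 16, sex = 1)  # -2
compute_z <- function(observed, model, age, education, sex, higher_better = NULL) {
  if (is.null(higher_better)) {
    higher_better <- TRUE
    if (!is.null(model$test)) {
      dict <- test_dictionary()
      hit <- match(model$test, dict$test)
      if (!is.na(hit)) higher_better <- dict$higher_better[hit]
    }
  }
  predicted <- model$intercept + model$b_age * age + model$b_edu * education +
    model$b_sex * sex
  resid <- observed - predicted
  if (model$see > .zero_see_tol) {
    z <- resid / model$see
  } else {
    z <- ifelse(abs(resid) < .zero_see_tol * pmax(1, abs(observed)),
                0, sign(resid) * Inf)
  }
  if (!higher_better) z <- -z
  z
}

#' Z-score a cohort against fitted norms
#'
#' Applies [compute_z()] to every test in the norms table for every row of a
#' phenotype table, returning a long tibble of oriented z-scores and
#' impairment flags (z < -1, strict).
#'
#' @param data Phenotype data frame with score and covariate columns.
#' @param norms A `norm_models` object.
#' @param z_cut Impairment threshold on the oriented z-score (default -1).
#' @return Tibble with columns `participant_id`, `test`, `kind`, `domain`,
#'   `observed`, `z`, `impaired`.
#' @export
zscore_cohort <- function(data, norms, z_cut = -1) {
  dict <- test_dictionary()
  models <- norms$models
  ids <- data$participant_id %||% sprintf("row%04d", seq_len(nrow(data)))
  out <- purrr::map(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    if (!m$test %in% names(data)) return(NULL)
    di <- match(m$test, dict$test)
    z <- compute_z(data[[m$test]], m, data$age, data$education, data$sex,
                   higher_better = if (is.na(di)) TRUE else dict$higher_better[di])
    tibble::tibble(
      participant_id = ids,
      test = m$test,
      kind = if (is.na(di)) NA_character_ else dict$kind[di],
      domain = if (is.na(di)) NA_character_ else dict$domain[di],
      observed = data[[m$test]],
      z = z,
      impaired = !is.na(z) & z < z_cut
    )
  })
  purrr::list_rbind(out)
}
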