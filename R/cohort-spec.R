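#' Neuropsychological test dictionary
#'
#' Reference table for the nine neuropsychological measures used by the
#' actuarial classifier (six total test scores spanning three cognitive
#' domains, plus three AVLT process scores), together with their score
#' orientation. `higher_better = FALSE` marks timed/error measures
#' (TMT-A, TMT-B, total intrusions) whose z-scores are sign-flipped so that
#' z < -1 uniformly denotes impairment.
#'
#' @return A tibble with columns `test`, `kind` ("total" or "process"),
#'   `domain` ("memory", "language", "attention_executive", or NA for
#'   process scores) and `higher_better`.
#' @export
#' @examples
#' test_dictionary()
test_dictionary <- function() {
  tibble::tribble(
    ~test,                       ~kind,     ~domain,                ~higher_better,
    "avlt_delayed",              "total",   "memory",               TRUE,
    "avlt_recognition",          "total",   "memory",               TRUE,
    "bnt",                       "total",   "language",             TRUE,
    "aft",                       "total",   "language",             TRUE,
    "tmt_a",                     "total",   "attention_executive",  FALSE,
    "tmt_b",                     "total",   "attention_executive",  FALSE,
    "learning_slope",            "process", NA,                     TRUE,
    "retroactive_interference",  "process", NA,                     TRUE,
    "total_intrusions",          "process", NA,                     FALSE
  )
}

# per-test, per-group score means/SDs for the two cohort presets, plus the
# linear covariate weights (age/education/sex) the generator adds on top of
# the group means; sex coded 0 = male, 1 = female
score_distribution_defaults <- function(preset = c("cross_sectional", "longitudinal")) {
  preset <- match.arg(preset)
  cs <- tibble::tribble(
    ~test,                      ~cn_mean, ~cn_sd, ~obj_mean, ~obj_sd, ~mci_mean, ~mci_sd,
    "mmse",                     28.74,    1.21,   28.59,     1.59,    27.85,     1.79,
    "avlt_delayed",             8.36,     2.79,   5.21,      3.08,    3.15,      3.34,
    "avlt_recognition",         12.76,    1.85,   11.79,     2.11,    8.36,      3.59,
    "aft",                      22.05,    4.03,   20.59,     4.08,    17.29,     4.45,
    "bnt",                      28.42,    1.44,   27.72,     1.81,    26.60,     3.66,
    "tmt_a",                    29.48,    7.71,   27.72,     1.81,    44.91,     17.26,
    "tmt_b",                    67.00,    17.75,  89.07,     40.75,   125.96,    68.46,
    "learning_slope",           1.33,     0.39,   0.91,      0.45,    0.74,      0.46,
    "retroactive_interference", 0.80,     0.17,   0.69,      0.27,    0.59,      0.24,
    "total_intrusions",         2.24,     2.38,   3.82,      2.90,    3.51,      3.49,
    "csf_abeta42",              195.84,   54.64,  170.81,    48.35,   182.35,    56.57,
    "csf_ptau181",              37.71,    21.99,  42.98,     18.05,   41.80,     26.97,
    "csf_ttau",                 77.37,    50.06,  86.88,     47.00,   81.16,     43.81,
    "plasma_nfl",               31.51,    12.91,  31.90,     9.69,    39.89,     16.46
  )
  lg <- tibble::tribble(
    ~test,                      ~cn_mean, ~cn_sd, ~obj_mean, ~obj_sd, ~mci_mean, ~mci_sd,
    "mmse",                     28.63,    1.22,   28.36,     1.73,    27.63,     1.79,
    "avlt_delayed",             8.40,     2.96,   5.09,      3.25,    3.00,      3.22,
    "avlt_recognition",         12.60,    1.98,   12.00,     2.14,    8.02,      3.47,
    "aft",                      22.83,    3.38,   20.73,     4.15,    17.00,     4.48,
    "bnt",                      28.60,    1.35,   27.55,     1.90,    26.60,     3.52,
    "tmt_a",                    30.00,    8.23,   31.00,     6.19,    45.52,     16.91,
    "tmt_b",                    66.77,    17.05,  91.86,     44.02,   127.81,    69.58,
    "learning_slope",           1.34,     0.40,   0.92,      0.45,    0.71,      0.43,
    "retroactive_interference", 0.79,     0.17,   0.68,      0.28,    0.56,      0.23,
    "total_intrusions",         2.03,     1.96,   4.05,      3.23,    3.69,      3.68,
    "csf_abeta42",              194.19,   55.36,  168.85,    46.57,   178.41,    53.73,
    "csf_ptau181",              38.89,    23.62,  45.02,     19.17,   42.14,     27.83,
    "csf_ttau",                 80.22,    56.75,  92.25,     51.00,   81.28,     46.09,
    "plasma_nfl",               31.07,    13.52,  31.44,     8.29,    40.11,     17.28
  )
  tab <- if (preset == "cross_sectional") cs else lg
  dplyr::left_join(tab, covariate_effect_defaults(), by = "test")
}

# modest, sign-plausible linear effects of age (years), education (years) and
# sex (0 = M, 1 = F) on each measure; biomarkers carry no covariate structure
covariate_effect_defaults <- function() {
  tibble::tribble(
    ~test,                      ~b_age,  ~b_edu, ~b_sex,
    "mmse",                     -0.03,   0.05,   0.20,
    "avlt_delayed",             -0.08,   0.12,   0.90,
    "avlt_recognition",         -0.04,   0.06,   0.50,
    "aft",                      -0.10,   0.20,  -0.30,
    "bnt",                      -0.03,   0.10,  -0.20,
    "tmt_a",                     0.25,  -0.30,  -1.00,
    "tmt_b",                     0.80,  -1.00,  -3.00,
    "learning_slope",           -0.008,  0.010,  0.050,
    "retroactive_interference", -0.002,  0.004,  0.010,
    "total_intrusions",          0.040, -0.050, -0.200,
    "csf_abeta42",               0,      0,      0,
    "csf_ptau181",               0,      0,      0,
    "csf_ttau",                  0,      0,      0,
    "plasma_nfl",                0,      0,      0
  )
}

# demographics per preset: age/education mean+SD per group, P(female), P(APOE4)
demographic_defaults <- function(preset = c("cross_sectional", "longitudinal")) {
  preset <- match.arg(preset)
  if (preset == "cross_sectional") {
    tibble::tibble(
      group     = c("CN", "Obj-SCD", "MCI"),
      age_mean  = c(71.29, 71.97, 73.58),
      age_sd    = c(6.85, 6.47, 6.66),
      edu_mean  = c(16.36, 16.59, 15.76),
      edu_sd    = c(2.56, 2.73, 2.49),
      p_female  = c(24 / 42, 14 / 29, 27 / 55),
      p_apoe4   = c(16 / 42, 13 / 28, 20 / 55)
    )
  } else {
    tibble::tibble(
      group     = c("CN", "Obj-SCD", "MCI"),
      age_mean  = c(70.55, 71.36, 73.59),
      age_sd    = c(7.51, 5.87, 6.91),
      edu_mean  = c(16.63, 16.59, 15.58),
      edu_sd    = c(2.16, 2.86, 2.47),
      p_female  = c(16 / 30, 10 / 22, 21 / 48),
      p_apoe4   = c(12 / 30, 10 / 22, 19 / 48)
    )
  }
}

#' Specify a synthetic cohort
#'
#' Builds the configuration object consumed by [generate_phenotypes()]. The
#' defaults reproduce the published study structure: a three-group
#' cross-sectional cohort of 42 cognitively normal (CN), 29 objectively-defined
#' subtle cognitive decline (Obj-SCD) and 55 mild cognitive impairment (MCI)
#' participants (30/22/48 under the longitudinal preset), per-test score
#' means/SDs matching the cohort characteristics tables, linear
#' age/education/sex effects on every neuropsychological measure, and a
#' separate robust normative sample of 239 CN-like participants used to fit
#' regression-based norms.
#'
#' Scores are generated as group mean + centred covariate effects + Gaussian
#' noise. `noise_scale` multiplies every score SD (0 yields a deterministic
#' cohort of covariate-adjusted group means). AVLT trial scores are generated
#' first and the process scores are derived from them, so derived scores are
#' exactly consistent with the emitted trials.
#'
#' @param n_per_group Named or positional integer vector of group sizes
#'   (CN, Obj-SCD, MCI).
#' @param preset `"cross_sectional"` (default) or `"longitudinal"`; selects the
#'   group sizes, demographics and score distributions of the corresponding
#'   cohort.
#' @param score_distributions Data frame of per-test, per-group means and SDs
#'   plus covariate weights; defaults to the preset's published values.
#' @param n_normative Size of the robust normative sample generated alongside
#'   the analysis cohort (default 239).
#' @param noise_scale Multiplier on all score SDs (default 1).
#' @param covariate_scale Multiplier on the age/education/sex weights
#'   (default 1; 0 removes covariate structure).
#' @param missing_rate Per-biomarker-column probability that a value is
#'   missing (default 0).
#' @param seed Integer RNG seed for [generate_phenotypes()].
#' @return An object of class `cohort_spec`.
#' @seealso [generate_phenotypes()], [phantom_spec()]
#' @export
#' @examples
#' spec <- cohort_spec(seed = 1)
#' spec$n_per_group
cohort_spec <- function(n_per_group = NULL,
                        preset = c("cross_sectional", "longitudinal"),
                        score_distributions = NULL,
                        n_normative = 239,
                        noise_scale = 1,
                        covariate_scale = 1,
                        missing_rate = 0,
                        seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(n_per_group)) {
    n_per_group <- if (preset == "cross_sectional") c(42L, 29L, 55L) else c(30L, 22L, 48L)
  }
  if (length(n_per_group) != 3) stopf("`n_per_group` must give counts for CN, Obj-SCD and MCI")
  n_per_group <- as.integer(n_per_group)
  names(n_per_group) <- c("CN", "Obj-SCD", "MCI")
  if (any(n_per_group < 2)) stopf("each group needs at least 2 participants")
  dist <- score_distributions %||% score_distribution_defaults(preset)
  sds <- unlist(dist[, c("cn_sd", "obj_sd", "mci_sd")])
  if (any(!is.finite(sds)) || any(sds <= 0)) stopf("all score SDs must be positive")
  if (noise_scale < 0) stopf("`noise_scale` must be >= 0")
  if (missing_rate < 0 || missing_rate > 1) stopf("`missing_rate` must be in [0, 1]")
  structure(
    list(
      n_per_group = n_per_group,
      preset = preset,
      score_distributions = dist,
      demographics = demographic_defaults(preset),
      n_normative = as.integer(n_normative),
      noise_scale = noise_scale,
      covariate_scale = covariate_scale,
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat("  preset:     ", x$preset, "\n")
  cat("  groups:     ", paste(names(x$n_per_group), x$n_per_group, sep = "=", collapse = ", "), "\n")
  cat("  normative:  ", x$n_normative, "\n")
  cat("  noise scale:", x$noise_scale, " covariate scale:", x$covariate_scale, "\n")
  cat("  seed:       ", x$seed, "\n")
  invisible(x)
}

# the generating normative model implied by a cohort spec: for every
# neuropsychological test, the true regression of score on age/education/sex
# in the CN (normative) population, with SEE equal to the CN noise SD.
# Covariate effects are centred at the CN demographic means in the
# generator, which fixes the true intercept.
true_norm_model <- function(spec) {
  d <- spec$score_distributions
  d <- d[d$test %in% test_dictionary()$test, ]
  cs <- spec$covariate_scale
  cn <- spec$demographics[spec$demographics$group == "CN", ]
  models <- tibble::tibble(
    test = d$test,
    intercept = d$cn_mean - cs * (cn$age_mean * d$b_age + cn$edu_mean * d$b_edu +
                                    cn$p_female * d$b_sex),
    b_age = cs * d$b_age,
    b_edu = cs * d$b_edu,
    b_sex = cs * d$b_sex,
    see = d$cn_sd * spec$noise_scale,
    n = Inf
  )
  new_norm_models(models, source = "generating model")
}
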