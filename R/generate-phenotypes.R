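#' Generate a synthetic phenotype table with ground truth
#'
#' Draws a three-group cohort (CN / Obj-SCD / MCI) plus a robust normative
#' sample from a [cohort_spec()]. Every neuropsychological score is generated
#' as group mean + centred linear age/education/sex effects + Gaussian noise
#' with the per-test SD of the spec. AVLT trial scores (trials 1-6, per-trial
#' intrusions, recognition hits/false positives) are generated first; the
#' process scores and the recognition total stored in the table are derived
#' from them, so recomputing them from the trials reproduces the stored
#' values exactly.
#'
#' The ground-truth cognitive label of each participant is obtained by
#' applying the actuarial decision rules to the participant's scores under
#' the *generating* normative model (true covariate weights; standard error
#' of the estimate equal to the generating noise SD). With default noise the
#' sampling group and the rule-based label coincide for most participants;
#' the rule-based label is the quantity a classifier can be asked to recover.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `scd_cohort` with elements
#'   \describe{
#'     \item{phenotypes}{tibble, one row per participant-visit (analysis and
#'       normative rows; `is_normative` flags the robust sample).}
#'     \item{truth}{tibble of ground-truth sampling group, rule-based label
#'       and per-test true z-scores.}
#'     \item{true_norms}{the generating normative model (a `norm_models`
#'       object).}
#'     \item{spec}{the input spec.}
#'   }
#' @export
#' @examples
#' cohort <- generate_phenotypes(cohort_spec(seed = 7))
#' dplyr::count(cohort$phenotypes, group, is_normative)
generate_phenotypes <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stopf("`spec` must be a cohort_spec")
  with_seed(child_seed(spec$seed, "phenotypes"), {
    groups <- rep(names(spec$n_per_group), times = spec$n_per_group)
    roles <- rep("analysis", length(groups))
    if (spec$n_normative > 0) {
      groups <- c(groups, rep("CN", spec$n_normative))
      roles <- c(roles, rep("normative", spec$n_normative))
    }
    n <- length(groups)
    demo <- spec$demographics
    gi <- match(groups, demo$group)

    age <- rnorm(n, demo$age_mean[gi], demo$age_sd[gi])
    education <- rnorm(n, demo$edu_mean[gi], demo$edu_sd[gi])
    sex <- rbinom(n, 1L, demo$p_female[gi])
    apoe4 <- rbinom(n, 1L, demo$p_apoe4[gi])

    dist <- spec$score_distributions
    cs <- spec$covariate_scale
    # covariate-adjusted per-participant mean for one named measure; effects
    # are centred at the group's own demographic means so the planted group
    # mean equals the configured value exactly
    mu_for <- function(test) {
      row <- dist[dist$test == test, ]
      gm <- c(row$cn_mean, row$obj_mean, row$mci_mean)[gi]
      gm + cs * (row$b_age * (age - demo$age_mean[gi]) +
                   row$b_edu * (education - demo$edu_mean[gi]) +
                   row$b_sex * (sex - demo$p_female[gi]))
    }
    sd_for <- function(test) {
      row <- dist[dist$test == test, ]
      c(row$cn_sd, row$obj_sd, row$mci_sd)[gi] * spec$noise_scale
    }
    draw <- function(test) mu_for(test) + rnorm(n, 0, sd_for(test))

    # AVLT learning curve: trial 5 is drawn directly, trial 1 follows from the
    # drawn learning slope, trial 6 from the drawn retroactive-interference
    # ratio; intermediate trials interpolate with small jitter
    avlt_trial5 <- c(12, 10, 7.5)[gi] + rnorm(n, 0, 2)
    slope <- draw("learning_slope")
    retro <- draw("retroactive_interference")
    avlt_trial1 <- avlt_trial5 - 5 * slope
    avlt_trial6 <- retro * avlt_trial5
    interp <- function(k) avlt_trial1 + (avlt_trial5 - avlt_trial1) * (k - 1) / 4 + rnorm(n, 0, 0.8)
    avlt_trial2 <- interp(2); avlt_trial3 <- interp(3); avlt_trial4 <- interp(4)

    # per-trial intrusions sum to a Gaussian total with the spec'd moments
    intr_mu <- mu_for("total_intrusions") / 6
    intr_sd <- sd_for("total_intrusions") / sqrt(6)
    intr <- matrix(rnorm(6 * n, rep(intr_mu, 6), rep(intr_sd, 6)), nrow = n)
    colnames(intr) <- paste0("intrusions_t", 1:6)

    recognition <- draw("avlt_recognition")
    avlt_fp <- abs(rnorm(n, 1, 1))
    avlt_hits <- recognition + avlt_fp

    phen <- tibble::tibble(
      participant_id = sprintf("S%04d", seq_len(n)),
      role = roles,
      is_normative = roles == "normative",
      group = groups,
      age = age,
      sex = sex,
      education = education,
      apoe4 = apoe4,
      avlt_trial1 = avlt_trial1, avlt_trial2 = avlt_trial2,
      avlt_trial3 = avlt_trial3, avlt_trial4 = avlt_trial4,
      avlt_trial5 = avlt_trial5, avlt_trial6 = avlt_trial6,
      avlt_hits = avlt_hits, avlt_fp = avlt_fp,
      avlt_delayed = draw("avlt_delayed"),
      mmse = draw("mmse"),
      bnt = draw("bnt"),
      aft = draw("aft"),
      tmt_a = draw("tmt_a"),
      tmt_b = draw("tmt_b"),
      csf_abeta42 = draw("csf_abeta42"),
      csf_ptau181 = draw("csf_ptau181"),
      csf_ttau = draw("csf_ttau"),
      plasma_nfl = draw("plasma_nfl")
    )
    phen <- dplyr::bind_cols(phen, tibble::as_tibble(intr))
    phen <- compute_process_scores(phen)
    phen$avlt_recognition <- phen$avlt_hits - phen$avlt_fp

    if (spec$missing_rate > 0) {
      for (col in c("csf_abeta42", "csf_ptau181", "csf_ttau", "plasma_nfl")) {
        phen[[col]][runif(n) < spec$missing_rate] <- NA_real_
      }
    }

    truth <- build_truth(phen, spec)
    structure(
      list(phenotypes = phen, truth = truth, true_norms = true_norm_model(spec), spec = spec),
      class = "scd_cohort"
    )
  })
}

# rule-based ground-truth labels under the generating normative model
build_truth <- function(phen, spec) {
  zp <- zscore_cohort(phen, true_norm_model(spec))
  lab <- classify_from_z(zp)
  truth <- dplyr::left_join(
    phen[, c("participant_id", "group", "is_normative")],
    lab[, c("participant_id", "label", "rule")],
    by = "participant_id"
  )
  names(truth)[names(truth) == "label"] <- "true_label"
  names(truth)[names(truth) == "rule"] <- "true_rule"
  truth
}

#' @export
print.scd_cohort <- function(x, ...) {
  cat("<scd_cohort> ", nrow(x$phenotypes), " participants (",
      sum(!x$phenotypes$is_normative), " analysis, ",
      sum(x$phenotypes$is_normative), " normative)\n", sep = "")
  print(dplyr::count(x$truth[!x$truth$is_normative, ], .data$group, .data$true_label))
  invisible(x)
}

#' Phenotype table data dictionary
#'
#' Column-by-column description of the phenotype TSV emitted by
#' [generate_phenotypes()] / [write_phenotypes()], including units and
#' codings (sex: 0 = male, 1 = female).
#'
#' @return A tibble with columns `column`, `description`, `units`.
#' @export
phenotype_dictionary <- function() {
  tibble::tribble(
    ~column,            ~description,                                          ~units,
    "participant_id",   "unique participant identifier",                       "",
    "role",             "analysis cohort row or robust normative row",         "",
    "is_normative",     "TRUE for robust normative sample members",            "",
    "group",            "sampling group: CN, Obj-SCD or MCI",                  "",
    "age",              "age at visit",                                        "years",
    "sex",              "0 = male, 1 = female",                                "",
    "education",        "completed education",                                 "years",
    "apoe4",            "APOE epsilon-4 carrier flag (0/1)",                   "",
    "avlt_trial1",      "AVLT list A trial 1 words recalled",                  "words",
    "avlt_trial5",      "AVLT list A trial 5 words recalled",                  "words",
    "avlt_trial6",      "AVLT list A trial 6 (post-interference) recall",      "words",
    "avlt_hits",        "AVLT recognition hits",                               "words",
    "avlt_fp",          "AVLT recognition false positives",                    "words",
    "avlt_recognition", "recognition discrimination (hits - false positives)", "words",
    "avlt_delayed",     "AVLT 30-minute delayed free recall",                  "words",
    "mmse",             "Mini-Mental State Examination total",                 "points",
    "bnt",              "30-item Boston Naming Test total correct",            "points",
    "aft",              "Animal Fluency total",                                "animals",
    "tmt_a",            "Trail Making Test part A completion time",            "seconds",
    "tmt_b",            "Trail Making Test part B completion time",            "seconds",
    "learning_slope",   "(trial5 - trial1) / 5",                               "words/trial",
    "retroactive_interference", "trial6 / trial5",                             "ratio",
    "total_intrusions", "extra-list intrusions summed over recall trials",     "count",
    "csf_abeta42",      "CSF amyloid-beta 42",                                 "pg/mL",
    "csf_ptau181",      "CSF phosphorylated tau (181)",                        "pg/mL",
    "csf_ttau",         "CSF total tau",                                       "pg/mL",
    "plasma_nfl",       "plasma neurofilament light chain",                    "pg/mL"
  )
}

#' Write / read a phenotype table as TSV
#'
#' Plain tab-separated serialization of a phenotype tibble (missing values as
#' `NA`), the cohort exchange format used by the pipeline stages.
#'
#' @param x A phenotype tibble.
#' @param path Output file path.
#' @return `write_phenotypes()` returns `path` invisibly; `read_phenotypes()`
#'   returns a tibble.
#' @export
write_phenotypes <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}
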