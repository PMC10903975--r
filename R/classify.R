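# actuarial decision rules applied to a long z-profile (one cohort);
# expects the output of zscore_cohort(); returns one row per participant
classify_from_z <- function(zprofile) {
  tot <- zprofile[zprofile$kind %in% "total", ]
  pro <- zprofile[zprofile$kind %in% "process", ]

  tot_sum <- tot %>%
    dplyr::group_by(.data$participant_id) %>%
    dplyr::summarise(
      n_tests_present = sum(!is.na(.data$z)),
      n_imp_tot = sum(.data$impaired),
      n_domains_hit = dplyr::n_distinct(.data$domain[.data$impaired]),
      any_domain_double = any(tapply(.data$impaired, .data$domain, sum) >= 2),
      all_domains_hit = dplyr::n_distinct(.data$domain[.data$impaired]) >= 3,
      .groups = "drop"
    )
  pro_sum <- pro %>%
    dplyr::group_by(.data$participant_id) %>%
    dplyr::summarise(n_imp_proc = sum(.data$impaired), .groups = "drop")

  out <- dplyr::left_join(tot_sum, pro_sum, by = "participant_id")
  out$n_imp_proc[is.na(out$n_imp_proc)] <- 0L
  out %>%
    dplyr::mutate(
      label = dplyr::case_when(
        n_tests_present == 0 ~ "unclassifiable",
        any_domain_double | all_domains_hit ~ "MCI",
        n_domains_hit >= 2 ~ "Obj-SCD",
        n_imp_proc >= 2 ~ "Obj-SCD",
        n_imp_tot >= 1 & n_imp_proc >= 1 ~ "Obj-SCD",
        TRUE ~ "CN"
      ),
      rule = dplyr::case_when(
        label == "unclassifiable" ~ "no scorable totals",
        any_domain_double ~ "MCI: >=2 impaired totals in one domain",
        all_domains_hit ~ "MCI: >=1 impaired total in all three domains",
        label == "Obj-SCD" & n_domains_hit >= 2 ~ "Obj-SCD: impaired totals in two domains",
        label == "Obj-SCD" & n_imp_proc >= 2 ~ "Obj-SCD: >=2 impaired process scores",
        label == "Obj-SCD" ~ "Obj-SCD: 1 impaired total + 1 impaired process",
        TRUE ~ "CN: no qualifying impairment pattern"
      )
    ) %>%
    dplyr::select("participant_id", "label", "rule", "n_imp_tot", "n_imp_proc",
                  "n_domains_hit")
}

#' Classify one participant from a z-profile
#'
#' Applies the actuarial criteria to a single participant's oriented
#' z-scores. MCI is evaluated first: (i) two impaired total scores within one
#' cognitive domain, or (ii) at least one impaired total in each of the three
#' domains. Remaining participants are Obj-SCD if (i) impaired totals in two
#' different domains, (ii) at least two impaired AVLT process scores, or
#' (iii) one impaired total and one impaired process score; otherwise CN.
#' Impairment is z < -1 (strict). Missing tests count as not impaired; a
#' participant with no scorable total is `"unclassifiable"`.
#'
#' @param zprofile Tibble as returned by [zscore_cohort()] restricted to (or
#'   containing) one participant: columns `test`, `kind`, `domain`, `z`,
#'   `impaired`.
#' @return One-row tibble with `label` and the `rule` that fired.
#' @export
#' @examples
#' zp <- zscore_cohort(
#'   tibble::tibble(participant_id = "p1", age = 72, education = 16, sex = 1,
#'                  avlt_delayed = 2, avlt_recognition = 6, bnt = 28, aft = 22,
#'                  tmt_a = 30, tmt_b = 70, learning_slope = 1.3,
#'                  retroactive_interference = 0.8, total_intrusions = 2),
#'   demo_norms())
#' classify_participant(zp)
classify_participant <- function(zprofile) {
  if (!"participant_id" %in% names(zprofile)) zprofile$participant_id <- "participant"
  res <- classify_from_z(zprofile)
  if (nrow(res) != 1) stopf("`zprofile` must describe exactly one participant")
  res
}

#' Classify a cohort with actuarial criteria
#'
#' End-to-end actuarial classification of a phenotype table: derives AVLT
#' process scores where absent, fits (or reuses) regression-based norms on
#' the robust normative rows, z-scores every measure, applies the MCI /
#' Obj-SCD / CN decision rules, and stratifies amyloid status from CSF
#' A\eqn{\beta}42.
#'
#' @param data Phenotype data frame (one row per participant).
#' @param norms Optional `norm_models`; fitted on the `is_normative` rows of
#'   `data` when omitted.
#' @param z_cut Impairment threshold (default -1).
#' @param abeta_cutoff CSF A\eqn{\beta}42 positivity cutoff in pg/mL
#'   (default 192).
#' @return A list of class `scd_classification`: `labels` (input table plus
#'   `label`, `rule`, `amyloid`), `zprofile` (long z table), `norms`, and
#'   `counts` (label tally). [tidy()] returns the labelled table, [glance()]
#'   the counts.
#' @export
#' @examples
#' cohort <- generate_phenotypes(cohort_spec(seed = 2))
#' cls <- classify_cohort(cohort$phenotypes)
#' glance(cls)
classify_cohort <- function(data, norms = NULL, z_cut = -1, abeta_cutoff = 192) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) {
    return(structure(list(
      labels = dplyr::mutate(data, label = character(0), rule = character(0),
                             amyloid = character(0)),
      zprofile = tibble::tibble(), norms = norms,
      counts = tibble::tibble(label = character(0), n = integer(0))
    ), class = "scd_classification"))
  }
  if (!"participant_id" %in% names(data)) {
    data$participant_id <- sprintf("row%04d", seq_len(nrow(data)))
  }
  if (!"learning_slope" %in% names(data) && "avlt_trial1" %in% names(data)) {
    data <- compute_process_scores(data)
  }
  # drop classifier output columns from a previously labelled table so
  # re-classification is idempotent
  data <- data[, setdiff(names(data), c("label", "rule", "amyloid", "n_imp_tot",
                                        "n_imp_proc", "n_domains_hit"))]
  if (is.null(norms)) norms <- fit_norms(data)
  zp <- zscore_cohort(data, norms, z_cut = z_cut)
  lab <- classify_from_z(zp)
  labels <- dplyr::left_join(data, lab, by = "participant_id")
  labels$amyloid <- if ("csf_abeta42" %in% names(labels)) {
    amyloid_stratify(labels$csf_abeta42, cutoff = abeta_cutoff)
  } else {
    "unknown"
  }
  counts <- dplyr::count(labels, .data$label)
  structure(list(labels = labels, zprofile = zp, norms = norms, counts = counts),
            class = "scd_classification")
}

#' @export
print.scd_classification <- function(x, ...) {
  cat("<scd_classification> ", nrow(x$labels), " participants\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @export
tidy.scd_classification <- function(x, ...) x$labels

#' @export
glance.scd_classification <- function(x, ...) {
  tidyr::pivot_wider(x$counts, names_from = "label", values_from = "n",
                     values_fill = 0L)
}

#' Illustrative norms for examples
#'
#' A small fixed `norm_models` table (flat demographics, SEE equal to typical
#' control-group score SDs) used in documentation examples.
#' @return A `norm_models` object.
#' @export
demo_norms <- function() {
  d <- score_distribution_defaults("cross_sectional")
  d <- d[d$test %in% test_dictionary()$test, ]
  new_norm_models(
    tibble::tibble(test = d$test, intercept = d$cn_mean, b_age = 0, b_edu = 0,
                   b_sex = 0, see = d$cn_sd, n = NA_integer_),
    source = "illustrative fixed norms"
  )
}
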