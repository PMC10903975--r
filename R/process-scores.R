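#' Derive AVLT process scores
#'
#' Computes the three Rey Auditory Verbal Learning Test process scores used by
#' the Obj-SCD criteria from the per-trial records:
#' \describe{
#'   \item{learning_slope}{(Trial 5 - Trial 1) / 5}
#'   \item{retroactive_interference}{Trial 6 / Trial 5, undefined (NA) when
#'     Trial 5 is 0}
#'   \item{total_intrusions}{sum of extra-list intrusion errors across all
#'     recall trials}
#' }
#'
#' @param data A data frame with columns `avlt_trial1`, `avlt_trial5`,
#'   `avlt_trial6` and (optionally) `intrusions_t1` ... `intrusions_t6`.
#' @return `data` with columns `learning_slope`, `retroactive_interference`
#'   and (when intrusion columns are present) `total_intrusions` added or
#'   replaced.
#' @export
#' @examples
#' df <- tibble::tibble(avlt_trial1 = 3, avlt_trial5 = 13, avlt_trial6 = 9)
#' compute_process_scores(df)$learning_slope  # 2
compute_process_scores <- function(data) {
  need <- c("avlt_trial1", "avlt_trial5", "avlt_trial6")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) stopf("missing AVLT trial columns: %s", paste(miss, collapse = ", "))
  data$learning_slope <- (data$avlt_trial5 - data$avlt_trial1) / 5
  data$retroactive_interference <- ifelse(
    !is.na(data$avlt_trial5) & data$avlt_trial5 == 0,
    NA_real_,
    data$avlt_trial6 / data$avlt_trial5
  )
  intr_cols <- grep("^intrusions_t[0-9]+$", names(data), value = TRUE)
  if (length(intr_cols) > 0) {
    data$total_intrusions <- rowSums(as.data.frame(data[, intr_cols]))
  }
  data
}

#' Stratify amyloid status from CSF A\eqn{\beta}42
#'
#' Applies the established CSF amyloid-beta-42 positivity cutoff: values below
#' 192 pg/mL (equivalently ng/L) are classified abnormal (`"A+"`), values at
#' or above the cutoff normal (`"A-"`), and missing values `"unknown"`.
#'
#' @param csf_abeta42 Numeric vector of CSF A\eqn{\beta}42 concentrations in
#'   pg/mL; `NA` allowed.
#' @param cutoff Positivity cutoff (default 192).
#' @return Character vector in `{"A+", "A-", "unknown"}`.
#' @export
#' @examples
#' amyloid_stratify(c(150, 192, NA))
amyloid_stratify <- function(csf_abeta42, cutoff = 192) {
  if (any(csf_abeta42 < 0, na.rm = TRUE)) stopf("negative CSF concentration")
  dplyr::case_when(
    is.na(csf_abeta42) ~ "unknown",
    csf_abeta42 < cutoff ~ "A+",
    TRUE ~ "A-"
  )
}
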