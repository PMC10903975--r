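#' Plot an axial slice of a centrality map
#'
#' @param object A `centrality_map`.
#' @param slice Axial (z) slice index; defaults to the mask's busiest slice.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.centrality_map <- function(object, slice = NULL, ...) {
  slice <- slice %||% which.max(apply(object$mask, 3, sum))
  df <- tidy(object) %>% dplyr::filter(.data$z == slice)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste0(object$metric, " map (z = ", slice, ")"),
                  fill = object$metric) +
    ggplot2::theme_minimal()
}

#' Plot suprathreshold clusters over the mask
#'
#' @param object A `cluster_result`.
#' @param slice Axial slice; defaults to the slice containing the largest
#'   cluster's peak.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cluster_result <- function(object, slice = NULL, ...) {
  if (is.null(slice)) {
    slice <- if (nrow(object$clusters) > 0) object$clusters$peak_z[1] else
      which.max(apply(object$mask, 3, sum))
  }
  co <- which(object$mask, arr.ind = TRUE)
  df <- tibble::tibble(x = co[, 1], y = co[, 2], z = co[, 3],
                       cluster = object$labels[object$mask]) %>%
    dplyr::filter(.data$z == slice) %>%
    dplyr::mutate(cluster = ifelse(.data$cluster == 0, NA, .data$cluster))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = factor(.data$cluster))) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("Suprathreshold clusters (z = ", slice, ")"),
                  fill = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot per-group ROI means across timepoints
#'
#' Spaghetti/summary plot of ROI centrality values by group and timepoint,
#' the longitudinal change-pattern display.
#'
#' @param data Long tibble with `group`, `time`, `value` (and optionally
#'   `subject`).
#' @return A ggplot object.
#' @export
plot_roi_trajectories <- function(data) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$time, y = .data$value,
                                          colour = .data$group,
                                          group = .data$group))
  if ("subject" %in% names(data)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data$subject),
                                alpha = 0.25, linewidth = 0.3)
  }
  p +
    ggplot2::stat_summary(fun = mean, geom = "line", linewidth = 1.2) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 2.5) +
    ggplot2::labs(x = NULL, y = "ROI mean (standardized)") +
    ggplot2::theme_minimal()
}

#' Plot the z-score profile of a classified cohort
#'
#' Heat-style summary of oriented z-scores per test and participant, split
#' by assigned label; impaired cells (z < -1) are those below the dashed
#' reference in the accompanying distribution.
#'
#' @param object An `scd_classification`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.scd_classification <- function(object, ...) {
  zp <- object$zprofile %>%
    dplyr::left_join(object$labels[, c("participant_id", "label")],
                     by = "participant_id")
  ggplot2::ggplot(zp, ggplot2::aes(x = .data$test, y = .data$z,
                                   colour = .data$label)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = -1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "oriented z (impaired < -1)", x = NULL) +
    ggplot2::theme_minimal()
}
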