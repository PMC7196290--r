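#' Per-cell EMT score bars
#'
#' One bar per cell, height = M-score, colored by the E/M/hybrid label, with
#' the hybrid band shaded. The mirror-image E-score is 100 minus the bar.
#'
#' @param scores Output of [classify_emt()].
#' @param hybrid_band Band to shade; should match the classification call.
#' @return A ggplot object.
#' @export
plot_emt_scores <- function(scores, hybrid_band = c(40, 60)) {
  assert_cols(scores, c("cell_id", "m_score", "label"), "EMT score tibble")
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = stats::reorder(.data$cell_id, .data$m_score),
                               y = .data$m_score, fill = .data$label)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = hybrid_band[1], ymax = hybrid_band[2],
                      alpha = 0.12) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "M-score (%)", fill = "EMT label") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' CTC count trajectories per patient
#'
#' @param counts Tibble `patient_id`, `day`, `raw_count`, `volume_mL` (an
#'   `arm` column, if present, colors the lines).
#' @return A ggplot object of per-7.5 mL counts over time.
#' @export
plot_ctc_trajectories <- function(counts) {
  assert_cols(counts, c("patient_id", "day", "raw_count", "volume_mL"),
              "CTC count tibble")
  counts <- counts %>%
    mutate(count_75 = normalize_count(.data$raw_count, .data$volume_mL))
  aes <- if ("arm" %in% names(counts)) {
    ggplot2::aes(x = .data$day, y = .data$count_75,
                 group = .data$patient_id, color = .data$arm)
  } else {
    ggplot2::aes(x = .data$day, y = .data$count_75, group = .data$patient_id)
  }
  ggplot2::ggplot(counts, aes) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Days from baseline", y = "CTCs / 7.5 mL") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ctc_km <- function(object, ...) {
  steps <- tidy(object)
  steps <- bind_rows(
    tibble(time = 0, surv = 1, conf_low = 1, conf_high = 1),
    steps %>% select("time", "surv", "conf_low", "conf_high")
  )
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf_low), linetype = 2,
                       na.rm = TRUE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf_high), linetype = 2,
                       na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ctc_cutoff_search <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$cutoff, y = .data$p_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$best_cutoff, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Baseline count cutoff (CTCs / 7.5 mL)",
                  y = "Log-rank p (exploratory)") +
    ggplot2::theme_minimal()
}

#' t-SNE embedding scatter
#'
#' @param embedding Output of [tsne_embed()].
#' @param groups Optional tibble `cell_id`, `group` to color points.
#' @return A ggplot object (first two embedding dimensions).
#' @export
plot_embedding <- function(embedding, groups = NULL) {
  assert_cols(embedding, c("cell_id", "tsne1", "tsne2"), "embedding tibble")
  if (!is.null(groups)) {
    embedding <- left_join(embedding, groups, by = "cell_id")
    p <- ggplot2::ggplot(embedding,
                         ggplot2::aes(x = .data$tsne1, y = .data$tsne2,
                                      color = .data$group))
  } else {
    p <- ggplot2::ggplot(embedding,
                         ggplot2::aes(x = .data$tsne1, y = .data$tsne2))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
    ggplot2::theme_minimal()
}
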