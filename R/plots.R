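# ggplot2 views of the main result types. Kept deliberately close to the
# figures practitioners draw for this kind of study: fixation trajectories,
# real-vs-synthetic embeddings, ROC curves, comparison forests.

#' Plot fixation trajectories of one or more phases
#'
#' Scanpath view: fixation centroids (point area ~ duration) connected in
#' temporal order, one facet per phase. MNL phases typically show wide
#' scattered scanning, non-MNL phases concentrated fixations.
#'
#' @param events a [detect_events()] tibble.
#' @param annotations phase annotations; used to facet and label phases.
#' @param phases optional vector of `phase_id`s to show.
#' @return A ggplot object.
#' @export
plot_fixation_trajectory <- function(events, annotations, phases = NULL) {
  fix <- events[events$kind == "fixation", ]
  df <- mutate(fix, phase = assign_events_to_phase(fix, annotations))
  df <- filter(df, !is.na(.data$phase))
  df$phase_id <- annotations$phase_id[df$phase]
  df$label <- annotations$label[df$phase]
  if (!is.null(phases)) df <- filter(df, .data$phase_id %in% phases)
  ggplot2::ggplot(df, ggplot2::aes(.data$centroid_x, .data$centroid_y)) +
    ggplot2::geom_path(colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(size = .data$duration_ms, colour = .data$label),
                        alpha = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~ phase_id) +
    ggplot2::labs(x = "x (px)", y = "y (px)", size = "duration (ms)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mnl_comparison <- function(object, alpha = 0.05, ...) {
  df <- mutate(as_tibble(unclass(object)),
               significant = .data$p_value < alpha,
               measure = factor(.data$measure, levels = rev(.data$measure)))
  long <- tidyr::pivot_longer(
    df, c("mean_mnl", "mean_non"),
    names_to = "group", values_to = "mean"
  )
  long$se <- ifelse(long$group == "mean_mnl", long$se_mnl, long$se_non)
  long$group <- ifelse(long$group == "mean_mnl", "MNL", "non-MNL")
  ggplot2::ggplot(long, ggplot2::aes(.data$mean, .data$measure, colour = .data$group)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$mean - 2 * .data$se, xmax = .data$mean + 2 * .data$se),
      position = ggplot2::position_dodge(width = 0.5), fatten = 1.5
    ) +
    ggplot2::labs(x = "group mean (+/- 2 SE)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.overlap_report <- function(object, ...) {
  ggplot2::ggplot(object$embedding,
                  ggplot2::aes(.data$dim1, .data$dim2, colour = .data$set)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::labs(
      title = sprintf("real vs synthetic embedding (separability %.2f)",
                      object$separability),
      x = "t-SNE 1", y = "t-SNE 2", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.classification_metrics <- function(object, ...) {
  if (is.null(object$roc)) {
    stop_contract("no ROC points attached to these metrics")
  }
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey70") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                  title = sprintf("ROC (accuracy %.1f%%)", object$accuracy)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mnl_dcgan <- function(object, ...) {
  long <- tidyr::pivot_longer(object$losses, c("d_loss", "g_loss"),
                              names_to = "network", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$loss, colour = .data$network)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mnl_lstm <- function(object, ...) {
  ggplot2::ggplot(object$losses, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss") +
    ggplot2::theme_minimal()
}

#' @export
tidy.mnl_lstm <- function(x, ...) x$losses

#' @export
glance.mnl_lstm <- function(x, ...) {
  tibble(
    units = x$cfg$units, epochs = x$cfg$epochs,
    n_features = length(x$feature_names),
    final_loss = tail(x$losses$loss, 1)
  )
}
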