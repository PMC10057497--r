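#' Plot an SPM t trajectory
#'
#' t trajectory with the symmetric critical threshold pair and shaded
#' suprathreshold clusters.
#'
#' @param object a `swing_spm`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot swing_spm
#' @export
autoplot.swing_spm <- function(object, ...) {
  td <- tidy(object)
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$node, y = .data$t)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$threshold,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "normalized node", y = "SPM{t}",
                  title = sprintf("Two-sample SPM{t} (|t*| = %.2f, alpha = %g)",
                                  object$threshold, object$alpha)) +
    ggplot2::theme_minimal()
  if (nrow(object$clusters) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$clusters,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red",
      inherit.aes = FALSE)
  }
  p
}

#' Plot mean CRP curves by sex
#'
#' Group-mean pelvis-thorax CRP over the normalized stroke, one line per
#' sex, with the alignment node (maximal pelvis rotation) marked.
#'
#' @param results a `swing_analysis` bundle.
#' @return a ggplot.
#' @export
plot_crp_means <- function(results) {
  stopifnot(inherits(results, "swing_analysis"))
  node_cols <- grep("^node_", names(results$mean_crp), value = TRUE)
  long <- results$mean_crp %>%
    tidyr::pivot_longer(all_of(node_cols), names_to = "node",
                        values_to = "crp_deg") %>%
    mutate(node = as.integer(sub("node_", "", .data$node))) %>%
    group_by(.data$sex, .data$node) %>%
    summarise(crp_deg = mean(.data$crp_deg), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$node, y = .data$crp_deg,
                                     linetype = .data$sex)) +
    ggplot2::geom_vline(xintercept = results$spm$metadata$align_node,
                        linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "normalized node", y = "CRP (deg)",
                  title = "Mean pelvis-thorax continuous relative phase",
                  linetype = "sex") +
    ggplot2::theme_minimal()
}

#' Plot one trial's kinematics
#'
#' Pelvis and thorax angles with the detected events overlaid — the
#' quickest sanity check of event detection on a new data set.
#'
#' @param angles output of [segment_angles()].
#' @param events a `swing_events`.
#' @return a ggplot.
#' @export
plot_trial_angles <- function(angles, events) {
  long <- angles %>%
    tidyr::pivot_longer(c("pelvis_deg", "thorax_deg"),
                        names_to = "segment", values_to = "angle_deg") %>%
    mutate(segment = sub("_deg", "", .data$segment))
  ev <- tibble(event = c("start", "top", "impact"),
               time = angles$time[c(events$start_frame, events$top_frame,
                                    events$impact_frame)])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$angle_deg,
                                     colour = .data$segment)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = ev, ggplot2::aes(xintercept = .data$time),
                        linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "rotation (deg)", colour = NULL) +
    ggplot2::theme_minimal()
}
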