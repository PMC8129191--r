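#' Plot epoched band power
#'
#' Across-trial mean z-power with a ±1 standard-error ribbon per class,
#' faceted by contact.
#'
#' @param object a `seeg_epochs`.
#' @param contacts optional subset of contact ids to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.seeg_epochs <- function(object, contacts = NULL, ...) {
  kept <- object$contacts[!object$contacts$excluded, ]
  idx <- seq_len(nrow(kept))
  if (!is.null(contacts)) idx <- match(contacts, kept$contact_id)
  t_ms <- (seq_len(dim(object$z_power)[3]) - 0.5) / object$fs * 1000
  rows <- list()
  for (j in idx) {
    for (cl in unique(object$labels)) {
      tr <- object$z_power[object$labels == cl, j, , drop = FALSE]
      m <- apply(tr, 3, mean)
      se <- apply(tr, 3, stats::sd) / sqrt(dim(tr)[1])
      rows[[length(rows) + 1]] <- tibble::tibble(
        contact_id = kept$contact_id[j], class_label = cl,
        time_ms = t_ms, mean_z = m, se_z = se)
    }
  }
  df <- dplyr::bind_rows(rows)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$mean_z,
                                   colour = .data$class_label,
                                   fill = .data$class_label)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_z - .data$se_z,
                                      ymax = .data$mean_z + .data$se_z),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~contact_id) +
    ggplot2::labs(x = "time after onset (ms)", y = "z-scored band power",
                  colour = "class", fill = "class")
}

#' Plot a decoding result against its permutation null
#'
#' Histogram of the permuted accuracies with the observed accuracy and the
#' 95th-percentile significance threshold marked.
#'
#' @param object a `seeg_decoding` with significance computed.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.seeg_decoding <- function(object, ...) {
  if (is.null(object$perm_accuracies))
    stop("run accuracy_significance() first")
  df <- tibble::tibble(accuracy = object$perm_accuracies)
  ggplot2::ggplot(df, ggplot2::aes(.data$accuracy)) +
    ggplot2::geom_histogram(binwidth = 2, fill = "grey70",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$significance_threshold,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$accuracy, colour = "red") +
    ggplot2::labs(x = "accuracy (%)", y = "permutations",
                  title = sprintf("observed %.1f%%, threshold %.1f%%, p = %.3g",
                                  object$accuracy,
                                  object$significance_threshold,
                                  object$permutation_p))
}

#' Plot a feature generation-time distribution
#'
#' @param object a `seeg_feature_density`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.seeg_feature_density <- function(object, ...) {
  df <- tibble::tibble(time_ms = object$grid_ms, density = object$density)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$mode_ms, linetype = "dashed") +
    ggplot2::labs(x = "feature generation time (ms)", y = "density")
}

#' Plot one-vs-rest ROC curves of a three-class report
#'
#' @param object a `seeg_multiclass`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.seeg_multiclass <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr,
                                           colour = .data$class)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate")
}
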