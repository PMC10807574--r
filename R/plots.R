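# ggplot2 displays for the main result types.

#' Plot Kaplan-Meier curves
#'
#' @param object a `reosig_km` from [km_curve()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.reosig_km <- function(object, ...) {
  # prepend the (0, 1) anchor per group so steps start at full survival
  anchors <- dplyr::distinct(object$curves, .data$group)
  anchors$time <- 0; anchors$surv <- 1
  d <- dplyr::bind_rows(
    anchors[, c("group", "time", "surv")],
    object$curves[, c("group", "time", "surv")]
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$surv,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time", y = "Survival probability", colour = "Group") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.na(object$p_value)) {
    p <- p + ggplot2::labs(
      subtitle = sprintf("log-rank p = %.3g", object$p_value)
    )
  }
  p
}

#' Plot the forward-search acceptance path of a signature
#'
#' Training C-index against the number of accepted gene pairs; the curve is
#' strictly increasing by construction of the search.
#'
#' @param object a `reosig_signature`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.reosig_signature <- function(object, ...) {
  ggplot2::ggplot(object$path, ggplot2::aes(.data$step, .data$c_index)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Accepted gene pairs", y = "Training C-index") +
    ggplot2::theme_minimal()
}

#' Plot enrichment-score distributions by subtype
#'
#' @param object a `reosig_subtypes` from [median_split()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.reosig_subtypes <- function(object, ...) {
  thresholds <- attr(object, "thresholds")
  ggplot2::ggplot(object, ggplot2::aes(.data$score, fill = .data$subtype)) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.6) +
    ggplot2::geom_vline(data = thresholds,
                        ggplot2::aes(xintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$cohort), scales = "free") +
    ggplot2::labs(x = "Enrichment score", y = "Samples", fill = "Subtype") +
    ggplot2::theme_minimal()
}
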