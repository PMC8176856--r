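#' Scatter plot of PET volumes against the reference volumes
#'
#' @param results long-form output of [sweep_delineations()].
#' @param ground_truth data.frame with case_id, ct_reference_volume_ml.
#' @param method,level the family and grid level to plot.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_agreement <- function(results, ground_truth, method, level) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  sub <- results[results$method == method & results$level == level, ]
  if (!nrow(sub)) stop("no results for that method/level", call. = FALSE)
  ref <- stats::setNames(ground_truth$ct_reference_volume_ml,
                         ground_truth$case_id)
  df <- data.frame(reference_ml = unname(ref[sub$case_id]),
                   pet_ml = sub$volume_ml)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference_ml, y = .data$pet_ml)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Reference volume (ml)", y = "PET volume (ml)",
                  title = sprintf("%s @ %g", method, level))
}

#' Bland-Altman plot for one method level
#'
#' Mean difference (red) and limits of agreement at +/- 1.96 SD (green),
#' axes in ml.
#'
#' @inheritParams plot_agreement
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_bland_altman <- function(results, ground_truth, method, level) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  sub <- results[results$method == method & results$level == level, ]
  if (!nrow(sub)) stop("no results for that method/level", call. = FALSE)
  ref <- stats::setNames(ground_truth$ct_reference_volume_ml,
                         ground_truth$case_id)
  a <- sub$volume_ml
  b <- unname(ref[sub$case_id])
  ba <- bland_altman(a, b)
  df <- data.frame(mean_ml = (a + b) / 2, diff_ml = a - b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_ml, y = .data$diff_ml)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "red") +
    ggplot2::geom_hline(yintercept = ba$loa, colour = "darkgreen",
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of PET and reference (ml)",
                  y = "PET - reference (ml)",
                  title = sprintf("Bland-Altman: %s @ %g", method, level))
}
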