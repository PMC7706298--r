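#' Plot per-band repeatability across the spectrum
#'
#' @param estimates Tibble from [estimate_band_repeatability()].
#' @param threshold Cutoff drawn as a dashed line (default 0.3).
#' @return A ggplot.
#' @export
plot_band_repeatability <- function(estimates, threshold = 0.3) {
  d <- estimates |> mutate(wavelength = as.numeric(.data$band))
  ggplot2::ggplot(d, ggplot2::aes(.data$wavelength, .data$H2)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "wavelength (nm)", y = expression(H^2),
                  title = "Waveband repeatability") +
    ggplot2::theme_minimal()
}

#' Plot normalised feature importance
#'
#' @param importance Tibble from [feature_importance()].
#' @param top_n Show the most important features only (default 20).
#' @return A ggplot.
#' @export
plot_feature_importance <- function(importance, top_n = 20) {
  d <- importance |> slice_head(n = top_n)
  ggplot2::ggplot(d, ggplot2::aes(.data$importance,
                                  stats::reorder(.data$feature,
                                                 .data$importance))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean importance (% of total)", y = NULL,
                  title = "Random-forest feature importance") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.cohort_result <- function(object, ...) {
  d <- object$summary |>
    mutate(method = paste("Method", .data$method))
  ggplot2::ggplot(d, ggplot2::aes(.data$cohort, .data$mean_rho,
                                  fill = .data$scenario)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_rho - .data$sd_rho,
                   ymax = .data$mean_rho + .data$sd_rho),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "predictor cohort",
                  y = "mean Spearman rank correlation",
                  title = "Rank-prediction accuracy by cohort") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.ga_result <- function(object, ...) {
  d <- object$log |>
    tidyr::pivot_longer(c("best", "mean"), names_to = "statistic",
                        values_to = "fitness")
  ggplot2::ggplot(d, ggplot2::aes(.data$generation, .data$fitness,
                                  colour = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "fitness (rank correlation)",
                  title = "Genetic-algorithm search trace") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.size_study <- function(object, ...) {
  d <- object$summary |>
    select("fraction", "scenario", "model", rho = "rho_mean",
           SPE = "SPE_mean", BAC = "BAC_mean", FS = "FS_mean") |>
    tidyr::pivot_longer(c("rho", "SPE", "BAC", "FS"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$fraction, .data$value,
                                  colour = .data$model,
                                  linetype = .data$scenario)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "training fraction", y = NULL,
                  title = "Prediction and selection metrics vs training size") +
    ggplot2::theme_minimal()
}
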