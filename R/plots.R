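#' Plot an EFR amplitude spectrum
#'
#' Marks the modulation-frequency bin and shades the flanking noise-floor
#' region.
#'
#' @param object an [efr_spectrum()] tibble.
#' @param xlim frequency range to display (defaults to the anchor +/- 40
#'   bins).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.efr_spectrum <- function(object, xlim = NULL, ...) {
  anchor <- attr(object, "anchor_hz")
  df <- attr(object, "bin_width_hz")
  xlim <- xlim %||% (anchor + c(-40, 40) * df)
  ggplot2::ggplot(object, ggplot2::aes(.data$freq, .data$amplitude)) +
    ggplot2::annotate(
      "rect",
      xmin = anchor - 6.5 * df, xmax = anchor + 6.5 * df,
      ymin = 0, ymax = Inf, alpha = 0.08
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = anchor, linetype = 2, colour = "red3") +
    ggplot2::coord_cartesian(xlim = xlim) +
    ggplot2::labs(
      x = "Frequency (Hz)", y = "Amplitude (\u00b5V)",
      title = sprintf("EFR spectrum (bin width %.2f Hz)", df)
    ) +
    ggplot2::theme_minimal()
}

#' Plot group-mean pupillary responses by SNR
#'
#' @param pupil_means tibble `group`, `snr`, `window`, `t_rel_s`, `value`
#'   (e.g. `run$pupil_means`).
#' @return A ggplot object.
#' @export
plot_pupil_response <- function(pupil_means) {
  ggplot2::ggplot(
    pupil_means,
    ggplot2::aes(.data$t_rel_s, .data$value,
      colour = factor(.data$snr), linetype = .data$group
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~window, scales = "free_x") +
    ggplot2::labs(
      x = "Time in window (s)", y = "Pupil size (% change from baseline)",
      colour = "SNR (dB)", linetype = "Group"
    ) +
    ggplot2::theme_minimal()
}

#' Lollipop plot of elastic-net coefficients
#'
#' @param object an `"elnet_fit"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.elnet_fit <- function(object, ...) {
  d <- tidy(object) %>%
    filter(.data$term != "(Intercept)") %>%
    arrange(.data$estimate) %>%
    mutate(term = factor(.data$term, levels = .data$term))
  ggplot2::ggplot(d, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = 0, xend = .data$estimate, yend = .data$term),
      colour = "grey60"
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = expression(beta), y = NULL,
      title = sprintf(
        "Elastic net (alpha = %.1f, lambda = %.3g)",
        object$alpha, object$lambda
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot fitted growth curves over observed cell means
#'
#' Shows the observed group x SNR mean time courses with the fixed-effect
#' fitted second-order polynomial overlaid.
#'
#' @param object a [fit_gca()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gca_fit <- function(object, ...) {
  d <- object$data
  obs <- d %>%
    group_by(.data$group_f, .data$snr_f, .data$t_rel_s, .data$ot1, .data$ot2) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  beta <- if (object$random_effects) {
    lme4::fixef(object$model)
  } else {
    coef(object$model)
  }
  tt <- delete.response(terms(lme4::nobars(stats::formula(object$model))))
  obs$fitted <- as.numeric(model.matrix(tt, obs) %*% beta)
  ggplot2::ggplot(obs, ggplot2::aes(.data$t_rel_s, .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red3") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$group_f),
      cols = ggplot2::vars(.data$snr_f)
    ) +
    ggplot2::labs(
      x = "Time in window (s)",
      y = "Pupil size (% change from baseline)",
      title = paste("Growth-curve fit,", object$window, "window")
    ) +
    ggplot2::theme_minimal()
}

#' EFR amplitudes by AM rate and group
#'
#' @param efr tibble with `am_rate_hz`, `amplitude`, `group`.
#' @return A ggplot object.
#' @export
plot_efr_amplitudes <- function(efr) {
  ggplot2::ggplot(
    efr,
    ggplot2::aes(factor(.data$am_rate_hz), .data$amplitude,
      fill = .data$group
    )
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(
      x = "AM rate (Hz)", y = "EFR amplitude (\u00b5V)", fill = "Group"
    ) +
    ggplot2::theme_minimal()
}
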