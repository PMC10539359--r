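#' Plot a repeat-aggregated time series as mean with SEM ribbon
#'
#' @param object A `fab_timeseries_stat` from [aggregate_repeats()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fab_timeseries_stat
#' @export
autoplot.fab_timeseries_stat <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ns, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)",
                  y = object$metric[1],
                  subtitle = paste0("mean ± SEM over ",
                                    object$n_repeats[1], " repeats")) +
    ggplot2::theme_minimal()
}

#' Plot a calculated SAXS profile on a log intensity scale
#'
#' @param object A `fab_saxs_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fab_saxs_profile
#' @export
autoplot.fab_saxs_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "I(q) (a.u.)") +
    ggplot2::theme_minimal()
}

#' Chi-square versus radius of gyration landscape
#'
#' Scatter of per-frame goodness of fit against the frame's Rg, coloured by
#' repeat, with the `top_n` best fits highlighted.
#'
#' @param fits Fit table from [fit_trajectory()].
#' @param top_n Number of best-fit frames to highlight (default 10).
#' @return A ggplot.
#' @export
plot_chi_square_rg <- function(fits, top_n = 10) {
  ok <- dplyr::filter(fits, !.data$failed)
  best <- dplyr::slice(dplyr::arrange(ok, .data$chi_square), seq_len(min(top_n, nrow(ok))))
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$rg / 10, y = .data$chi_square,
                                   colour = .data$repeat_id)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_point(data = best, shape = 8, size = 2.5, colour = "black") +
    ggplot2::labs(x = "Rg (nm)", y = expression(chi^2), colour = "repeat") +
    ggplot2::theme_minimal()
}

#' Per-residue RMSF profile plot
#'
#' @param rmsf Output of [rmsf_windowed()] (rows from several domains may be
#'   bound together).
#' @return A ggplot faceted by domain.
#' @export
plot_rmsf <- function(rmsf) {
  ggplot2::ggplot(rmsf, ggplot2::aes(x = .data$residue_number, y = .data$rmsf)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~domain, scales = "free_x") +
    ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}
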