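#' Plot methods for socnet results
#'
#' `autoplot()` methods give the standard diagnostic figures: the avalanche
#' size CCDF on log-log axes (optionally with a truncated power-law fit
#' overlay), the mean-synaptic-strength trajectory against `W_c`, and the
#' susceptibility profile of a critical-point scan.
#'
#' @param object A socnet result object.
#' @param fit Optional `tpl_fit` overlay for the CCDF plot.
#' @param w_c Optional critical-value reference line for trace plots.
#' @param ... Unused.
#' @return A ggplot object.
#' @name socnet-plots
NULL

#' @rdname socnet-plots
#' @export
autoplot.soc_avalanches <- function(object, fit = NULL, ...) {
  emp <- attr(empirical_ccdf(object$size), "table")
  p <- ggplot2::ggplot(emp, ggplot2::aes(x = .data$s, y = .data$ccdf)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "avalanche size s", y = "P(S ≥ s)")
  if (!is.null(fit)) {
    xs <- sort(unique(round(exp(seq(log(min(emp$s)), log(max(emp$s)),
                                    length.out = 200)))))
    over <- tibble(s = xs, ccdf = fit$ccdf(xs))
    p <- p + ggplot2::geom_line(data = over, colour = "red")
  }
  p
}

#' @rdname socnet-plots
#' @export
autoplot.soc_trace <- function(object, w_c = NULL, ...) {
  p <- ggplot2::ggplot(object$trace,
                       ggplot2::aes(x = .data$t, y = .data$mean_w)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t (steps)", y = "mean synaptic strength W[t]")
  if (!is.null(w_c)) {
    p <- p + ggplot2::geom_hline(yintercept = w_c, linetype = "dashed",
                                 colour = "red")
  }
  p
}

#' @rdname socnet-plots
#' @export
autoplot.soc_wc <- function(object, ...) {
  ggplot2::ggplot(object$scan, ggplot2::aes(x = .data$w, y = .data$chi)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$w_c, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "synaptic strength W", y = "susceptibility χ_s")
}

#' Phase-diagram tile plot of a sweep result
#'
#' @param sweep A [run_phase_sweep()] result.
#' @param fill One of `"regime"`, `"me"`, `"mae"`.
#' @return A ggplot object: tau x u tiles, facetted by network kind.
#' @export
plot_phase_diagram <- function(sweep, fill = c("regime", "me", "mae")) {
  fill <- match.arg(fill)
  ggplot2::ggplot(sweep, ggplot2::aes(x = factor(.data$tau),
                                      y = factor(.data$u),
                                      fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~kind) +
    ggplot2::labs(x = "τ (steps)", y = "u")
}

#' ISI distribution plot
#'
#' @param rates A [rate_profile()] result.
#' @return A ggplot object: ISI CCDF on log-log axes.
#' @export
plot_isi <- function(rates) {
  stopifnot(inherits(rates, "soc_rates"))
  emp <- attr(empirical_ccdf(rates$isi), "table")
  ggplot2::ggplot(emp, ggplot2::aes(x = .data$s, y = .data$ccdf)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "inter-spike interval (steps)", y = "P(ISI ≥ x)")
}
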