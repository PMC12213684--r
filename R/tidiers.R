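#' Tidiers for socnet result objects
#'
#' Broom-style `tidy()` and `glance()` methods: `tidy()` returns the
#' component-level table of a result (fit parameters, scan profile, regime
#' evidence), `glance()` a one-row summary.
#'
#' @param x A fitted/estimated socnet object.
#' @param ... Unused.
#' @return A tibble.
#' @name socnet-tidiers
NULL

#' @rdname socnet-tidiers
#' @export
tidy.tpl_fit <- function(x, ...) {
  tibble(term = c("alpha", "lambda"), estimate = c(x$alpha, x$lambda))
}

#' @rdname socnet-tidiers
#' @export
glance.tpl_fit <- function(x, ...) {
  tibble(alpha = x$alpha, lambda = x$lambda, s_min = x$s_min,
         logLik = x$loglik, nobs = x$n)
}

#' @rdname socnet-tidiers
#' @export
tidy.soc_wc <- function(x, ...) x$scan

#' @rdname socnet-tidiers
#' @export
glance.soc_wc <- function(x, ...) {
  tibble(w_c = x$w_c, chi_max = max(x$scan$chi),
         n_grid = nrow(x$scan), steps_per_w = x$steps_per_w,
         kind = x$kind, n = x$n)
}

#' @rdname socnet-tidiers
#' @export
tidy.soc_regime <- function(x, ...) {
  ev <- x$evidence
  tibble(quantity = names(ev),
         value = vapply(ev, function(v) format(v), character(1)))
}

#' @rdname socnet-tidiers
#' @export
glance.soc_regime <- function(x, ...) {
  ev <- x$evidence
  tibble(label = x$label,
         n_raw = ev$n_raw,
         max_size = ev$max_size %||% NA_real_,
         ccdf_at_tail = ev$ccdf_at_tail %||% NA_real_,
         max_deviation_ratio = ev$max_deviation_ratio %||% NA_real_,
         alpha = ev$alpha %||% NA_real_,
         lambda = ev$lambda %||% NA_real_)
}

#' @rdname socnet-tidiers
#' @export
glance.soc_scaling <- function(x, ...) {
  tibble(alpha = x$alpha, beta = x$beta,
         gamma_fit = x$gamma_fit, gamma_pred = x$gamma_pred)
}

#' @rdname socnet-tidiers
#' @export
tidy.soc_scaling <- function(x, ...) x$curve

`%||%` <- function(a, b) if (is.null(a)) b else a
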