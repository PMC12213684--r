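#' Network-mean synaptic strength with the in-degree exclusion rule
#'
#' Mean of the synaptic strengths over all edges whose presynaptic (source)
#' neuron has in-degree at least 2.  A synapse depresses only when its source
#' neuron fires; a source with in-degree 0 or 1 fires (essentially) only
#' spontaneously, so its outgoing strengths grow by `1/tau` almost unchecked
#' and would dominate the network mean.  Those edges are excluded.
#'
#' @param net A `soc_network`.
#' @param weights Optional per-edge strengths aligned with `net$edges`
#'   (defaults to the network's own weights, e.g. after assigning
#'   `run_simulation()$w_final`).
#' @return The mean strength over qualifying edges.
#' @export
network_mean_weight <- function(net, weights = NULL) {
  stopifnot(inherits(net, "soc_network"))
  w <- if (is.null(weights)) net$edges$weight else weights
  if (length(w) != nrow(net$edges)) {
    abort("`weights` must align with the edge list.",
          class = "socnet_spec_error")
  }
  qual <- net$in_degree[net$edges$source] >= 2
  if (!any(qual)) {
    abort("no edge has a source with in-degree >= 2.",
          class = "socnet_metric_error")
  }
  mean(w[qual])
}

#' Deviation of the mean synaptic strength from the critical value
#'
#' Windowed mean signed error (ME) and mean absolute error (MAE) of the
#' network-mean strength series against the critical value:
#' `ME  = sum(W[t] - W_c) / (t_b - t_a + 1)` and
#' `MAE = sum(|W[t] - W_c|) / (t_b - t_a + 1)` over `t in [t_a, t_b]`.
#' A positive ME means the network hovers above its critical strength.  The
#' reference window is `t_a = 1e4` to `t_b = 1e5`; shorter runs use a window
#' scaled with the run (see [run_single_characterization()]).
#'
#' @param x A `soc_trace` (its `mean_w` series is used) or a numeric series
#'   indexed from t = 1.
#' @param w_c Critical strength reference.
#' @param t_a,t_b Window bounds in steps, `t_a < t_b`, both covered by the
#'   series.
#' @return A one-row tibble: `me`, `mae`, `t_a`, `t_b`, `w_c`.
#' @examples
#' deviation_report(rep(1.8, 100), w_c = 1.7, t_a = 1, t_b = 100)$me # 0.1
#' @export
deviation_report <- function(x, w_c, t_a = 1e4, t_b = 1e5) {
  series <- if (inherits(x, "soc_trace")) x$trace$mean_w else as.numeric(x)
  if (t_a >= t_b) abort("need `t_a` < `t_b`.", class = "socnet_spec_error")
  if (t_a < 1 || t_b > length(series)) {
    abort("window [t_a, t_b] must lie within the series.",
          class = "socnet_spec_error")
  }
  w <- series[t_a:t_b]
  tibble(me = mean(w - w_c), mae = mean(abs(w - w_c)),
         t_a = t_a, t_b = t_b, w_c = w_c)
}

#' Per-neuron firing rates and inter-spike intervals
#'
#' Computes each neuron's mean firing rate (spikes per step over the window)
#' and the pooled inter-spike intervals (successive spike-time differences
#' per neuron; neurons with fewer than two spikes in the window contribute no
#' ISI).
#'
#' @param trace A `soc_trace` recorded with `record_raster = TRUE`.
#' @param net The `soc_network` the trace was run on (for in-degrees);
#'   optional.
#' @param window Integer window `c(t_a, t_b)`; defaults to the full run.
#' @return A `soc_rates` object: `$rates` tibble (`neuron`, `in_degree`,
#'   `rate`) over all neurons, and `$isi`, an integer vector of pooled
#'   intervals.
#' @export
rate_profile <- function(trace, net = NULL, window = NULL) {
  stopifnot(inherits(trace, "soc_trace"))
  if (is.null(trace$raster)) {
    abort("trace has no raster; rerun with `record_raster = TRUE`.",
          class = "socnet_spec_error")
  }
  if (is.null(window)) window <- c(1L, trace$t_max)
  if (window[1] < 1 || window[2] > trace$t_max || window[1] >= window[2]) {
    abort("invalid `window`.", class = "socnet_spec_error")
  }
  len <- window[2] - window[1] + 1
  ras <- dplyr::filter(trace$raster,
                       .data$t >= window[1], .data$t <= window[2])
  counts <- tabulate(ras$neuron, nbins = trace$n)
  in_deg <- if (is.null(net)) rep(NA_integer_, trace$n) else net$in_degree
  rates <- tibble(neuron = seq_len(trace$n), in_degree = in_deg,
                  rate = counts / len)
  isi <- ras |>
    dplyr::arrange(.data$neuron, .data$t) |>
    dplyr::group_by(.data$neuron) |>
    dplyr::reframe(isi = diff(.data$t)) |>
    dplyr::pull(.data$isi)
  structure(list(rates = rates, isi = as.integer(isi),
                 window = window), class = "soc_rates")
}

#' @export
print.soc_rates <- function(x, ...) {
  cat(sprintf("<soc_rates> %d neurons, window [%d, %d], %d ISIs, mean rate %.3g\n",
              nrow(x$rates), x$window[1], x$window[2], length(x$isi),
              mean(x$rates$rate)))
  invisible(x)
}

#' In-degree versus firing-rate regression by avalanche class
#'
#' Ordinary least-squares fit of per-neuron firing rate on in-degree within
#' each partition (e.g. spikes occurring during Dragon-king events versus
#' during power-law-abiding avalanches).  A positive slope in the Dragon-king
#' partition but not the power-law partition is the hub-driving signature of
#' scale-free networks.
#'
#' @param df A data frame with columns `partition`, `in_degree`, `rate` (one
#'   row per neuron per partition), e.g. from [hub_activity_analysis()].
#' @return A tibble with one row per partition: `partition`, `slope`,
#'   `intercept`, `n`.  Partitions with fewer than two distinct in-degree
#'   values are omitted with a warning.
#' @export
degree_rate_regression <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("partition", "in_degree", "rate") %in% names(df)))
  parts <- split(as_tibble(df), df$partition)
  rows <- purrr::map(names(parts), function(nm) {
    d <- parts[[nm]]
    if (length(unique(d$in_degree)) < 2) {
      warn(sprintf("partition '%s' has < 2 distinct in-degrees; omitted.", nm))
      return(NULL)
    }
    fit <- lm(rate ~ in_degree, data = d)
    tibble(partition = nm, slope = unname(coef(fit)[2]),
           intercept = unname(coef(fit)[1]), n = nrow(d))
  })
  dplyr::bind_rows(rows)
}

#' Per-class firing rates during Dragon-king versus power-law avalanches
#'
#' Labels each avalanche of a run as a Dragon-king event or a
#' power-law-abiding avalanche and computes per-neuron firing rates within
#' each class of periods.  The catalog is classified with
#' [classify_regime()]; when the regime is `dragon_king`, the Dragon-king
#' events are the avalanches whose size reaches the tail region where the
#' empirical CCDF exceeds the fitted truncated power law by more than
#' `dk_factor` (the same locus the classifier tests); all other avalanches
#' are power-law events.  A neuron's rate within a class is its spike count
#' during that class's avalanche periods divided by the total number of steps
#' those periods cover.
#'
#' @param trace A `soc_trace` with a raster (`record_raster = TRUE`, probe
#'   `"all"`).
#' @param net The `soc_network` simulated.
#' @param dk_factor Tail-excess threshold, as in [classify_regime()].
#' @return A list with `$rates` (tibble `partition`, `neuron`, `in_degree`,
#'   `rate` suitable for [degree_rate_regression()]), `$regime` (the
#'   `soc_regime`), and `$avalanches` (the labelled catalog).
#' @export
hub_activity_analysis <- function(trace, net, dk_factor = 1.1) {
  stopifnot(inherits(trace, "soc_trace"), inherits(net, "soc_network"))
  if (is.null(trace$raster)) {
    abort("trace has no raster; rerun with `record_raster = TRUE`.",
          class = "socnet_spec_error")
  }
  av <- extract_avalanches(trace)
  regime <- classify_regime(av, dk_factor = dk_factor)
  av <- dplyr::mutate(av, partition = "power_law")
  if (regime$label == "dragon_king" && !is.null(regime$fit)) {
    s_used <- av$size[-(1:5)]
    emp <- empirical_ccdf(s_used)
    floor_ev <- max(10, ceiling(length(s_used) / 1000))
    tail_s <- sort(unique(s_used[s_used >= 100]))
    tail_s <- tail_s[emp(tail_s) >= floor_ev / length(s_used)]
    ratios <- emp(tail_s) / pmax(regime$fit$ccdf(tail_s),
                                 .Machine$double.xmin)
    exceeds <- tail_s[ratios > dk_factor]
    if (length(exceeds) > 0) {
      s_dk <- min(exceeds)
      av$partition[av$size >= s_dk] <- "dragon_king"
    }
  } else {
    warn(sprintf("regime is '%s'; all avalanches labelled power_law.",
                 regime$label))
  }

  # map each raster spike to the avalanche period covering it
  rates <- purrr::map(c("dragon_king", "power_law"), function(lbl) {
    sel <- av[av$partition == lbl, , drop = FALSE]
    if (nrow(sel) == 0) return(NULL)
    steps <- unlist(purrr::map2(sel$start_t, sel$duration,
                                function(a, d) seq.int(a, a + d - 1L)))
    total <- length(steps)
    ras <- trace$raster[trace$raster$t %in% steps, , drop = FALSE]
    counts <- tabulate(ras$neuron, nbins = trace$n)
    tibble(partition = lbl, neuron = seq_len(trace$n),
           in_degree = net$in_degree, rate = counts / total)
  })
  list(rates = dplyr::bind_rows(rates), regime = regime, avalanches = av)
}
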