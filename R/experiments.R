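#' Default deviation window for a run of a given length
#'
#' The reference analysis averages deviations from `t = 1e4` to `t = 1e5` on
#' runs of `1e5` steps, i.e. from a tenth of the run to its end; shorter runs
#' use the same proportions.
#'
#' @param t_max Run length in steps.
#' @return `c(t_a, t_b)`.
#' @export
default_window <- function(t_max) {
  c(max(1L, as.integer(floor(t_max / 10))), as.integer(t_max))
}

#' Deterministic seed derivation for sweep cells
#'
#' Hashes a master seed together with any cell key (kind, tau, u, replicate,
#' ...) into a positive 31-bit integer seed, so every sweep cell gets an
#' independent, reproducible RNG stream and sweeps can be resumed.
#'
#' @param master Master integer seed.
#' @param ... Cell key components (coerced to character).
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483563
  as.integer(h + 1)
}

#' Single-run characterization of one network topology
#'
#' Builds a network, estimates (or reuses) its critical strength `W_c`, runs
#' the plastic simulation from `w_init` (default `W_c`), and assembles the
#' standard single-run outputs: avalanche catalog, truncated power-law fit
#' (when the catalog supports one), regime label, deviation report, and the
#' mean-strength trajectory.
#'
#' @param kind Network kind, as in [build_network()].
#' @param tau,u Plasticity parameters (reference values 500 and 0.1).
#' @param n,avg_degree Network size and mean total degree.
#' @param t_max Steps; must cover the deviation window.
#' @param w_c Known critical strength; if `NULL` it is estimated with
#'   `scan_args`.
#' @param w_init Initial strength; defaults to `w_c`.
#' @param window Deviation window `c(t_a, t_b)`; defaults to
#'   [default_window()] of `t_max`.
#' @param lif [lif_params()].
#' @param dk_factor Dragon-king tail threshold.
#' @param scan_args List of overrides for [estimate_critical_point()] (e.g.
#'   `w_step`, `steps_per_w`).
#' @param record_raster Keep the spike raster.
#' @param seed Master seed for build + scan + run.
#' @return A `soc_characterization` list: `net`, `w_c`, `trace`,
#'   `avalanches`, `fit` (or `NULL`), `regime`, `deviation`.
#' @export
run_single_characterization <- function(kind, tau = 500, u = 0.1,
                                        n = 2000, avg_degree = 8,
                                        t_max = 5e4, w_c = NULL,
                                        w_init = NULL, window = NULL,
                                        lif = lif_params(), dk_factor = 1.1,
                                        scan_args = list(),
                                        record_raster = FALSE, seed = 1) {
  if (is.null(window)) window <- default_window(t_max)
  if (t_max < window[2]) {
    abort("`t_max` must cover the deviation window.",
          class = "socnet_spec_error")
  }
  net <- build_network(kind, n = n, avg_degree = avg_degree,
                       seed = derive_seed(seed, kind, "net"))
  if (is.null(w_c)) {
    w_c <- do.call(estimate_critical_point, c(
      list(net = net, lif = lif, seed = derive_seed(seed, kind, "scan")),
      scan_args))$w_c
  }
  if (is.null(w_init)) w_init <- w_c
  trace <- run_simulation(net, lif = lif,
                          plast = plasticity_params(tau = tau, u = u),
                          t_max = t_max, w_init = w_init,
                          record_raster = record_raster,
                          seed = derive_seed(seed, kind, "run"))
  av <- extract_avalanches(trace)
  regime <- classify_regime(av, dk_factor = dk_factor)
  fit <- regime$fit
  dev <- deviation_report(trace, w_c = w_c, t_a = window[1], t_b = window[2])
  structure(list(kind = kind, net = net, w_c = w_c, trace = trace,
                 avalanches = av, fit = fit, regime = regime,
                 deviation = dev, tau = tau, u = u, seed = seed),
            class = "soc_characterization")
}

#' @export
print.soc_characterization <- function(x, ...) {
  cat(sprintf(
    "<soc_characterization> %s (n=%d) tau=%g u=%g: %s; W_c=%.3g ME=%.4g MAE=%.4g\n",
    x$kind, x$net$n, x$tau, x$u, x$regime$label, x$w_c,
    x$deviation$me, x$deviation$mae))
  invisible(x)
}

#' Repeated-run distribution of the mean-strength deviation
#'
#' Runs the same (kind, tau, u) configuration `n_runs` times with distinct
#' derived seeds and reports the per-run ME/MAE, for box-plot style
#' comparisons of topologies.
#'
#' @inheritParams run_single_characterization
#' @param n_runs Number of replicate runs.
#' @return A tibble with one row per run: `kind`, `tau`, `u`, `run`, `seed`,
#'   `me`, `mae`, `regime`, `n_avalanches`.
#' @export
run_me_replicates <- function(kind, tau = 200, u = 0.5, n_runs = 100,
                              n = 2000, avg_degree = 8, t_max = 5e4,
                              w_c = NULL, window = NULL, lif = lif_params(),
                              scan_args = list(), seed = 1) {
  if (is.null(window)) window <- default_window(t_max)
  if (is.null(w_c)) {
    net0 <- build_network(kind, n = n, avg_degree = avg_degree,
                          seed = derive_seed(seed, kind, "net"))
    w_c <- do.call(estimate_critical_point, c(
      list(net = net0, lif = lif, seed = derive_seed(seed, kind, "scan")),
      scan_args))$w_c
  }
  purrr::map_dfr(seq_len(n_runs), function(r) {
    sr <- derive_seed(seed, kind, tau, u, r)
    net <- build_network(kind, n = n, avg_degree = avg_degree,
                         seed = derive_seed(sr, "net"))
    tr <- run_simulation(net, lif = lif,
                         plast = plasticity_params(tau = tau, u = u),
                         t_max = t_max, w_init = w_c,
                         seed = derive_seed(sr, "run"))
    av <- extract_avalanches(tr)
    dev <- deviation_report(tr, w_c = w_c, t_a = window[1], t_b = window[2])
    tibble(kind = kind, tau = tau, u = u, run = r, seed = sr,
           me = dev$me, mae = dev$mae,
           regime = classify_regime(av)$label, n_avalanches = nrow(av))
  })
}

#' Phase-diagram sweep over plasticity timescales
#'
#' For every (kind, tau, u, replicate) cell: build the network, simulate with
#' plasticity from `W_c`, classify the avalanche catalog, and compute the
#' ME/MAE deviation indices.  The reference sweep covers `tau` in 100..1000
#' and `u` in 0.1..0.9.  `W_c` is estimated once per kind (it depends on size
#' and topology) unless supplied; per-cell seeds are derived
#' deterministically from the master seed so the sweep is reproducible
#' bit-for-bit and resumable (`done` rows are skipped).  A failing cell is
#' recorded with an `error` message rather than aborting the sweep.
#'
#' @param kinds Character vector of network kinds.
#' @param tau_grid,u_grid Plasticity grids.
#' @param replicates Replicate runs per cell.
#' @param n,avg_degree,t_max,lif,window,dk_factor,scan_args As in
#'   [run_single_characterization()].
#' @param w_c Named numeric vector of critical strengths per kind, or `NULL`
#'   to estimate them.
#' @param done Optional previous sweep tibble; matching (kind, tau, u,
#'   replicate) rows are carried over instead of recomputed.
#' @param seed Master seed.
#' @return A tibble with one row per cell x replicate: `kind`, `tau`, `u`,
#'   `replicate`, `seed`, `regime`, `me`, `mae`, `alpha`, `n_avalanches`,
#'   `w_c_used`, `error`.
#' @export
run_phase_sweep <- function(kinds, tau_grid, u_grid, replicates = 1,
                            n = 2000, avg_degree = 8, t_max = 5e4,
                            w_c = NULL, window = NULL, lif = lif_params(),
                            dk_factor = 1.1, scan_args = list(),
                            done = NULL, seed = 1) {
  if (any(tau_grid <= 0)) abort("`tau_grid` must be positive.",
                                class = "socnet_spec_error")
  if (any(u_grid <= 0 | u_grid >= 1)) abort("`u_grid` must lie in (0, 1).",
                                            class = "socnet_spec_error")
  if (is.null(window)) window <- default_window(t_max)
  if (t_max < window[2]) abort("`t_max` must cover the deviation window.",
                               class = "socnet_spec_error")

  wc_tab <- w_c
  if (is.null(wc_tab)) {
    wc_tab <- vapply(kinds, function(k) {
      net0 <- build_network(k, n = n, avg_degree = avg_degree,
                            seed = derive_seed(seed, k, "net"))
      do.call(estimate_critical_point, c(
        list(net = net0, lif = lif, seed = derive_seed(seed, k, "scan")),
        scan_args))$w_c
    }, numeric(1))
  }
  if (!all(kinds %in% names(wc_tab))) {
    abort("`w_c` must name every kind in `kinds`.",
          class = "socnet_spec_error")
  }

  grid <- tidyr::expand_grid(kind = kinds, tau = tau_grid, u = u_grid,
                             replicate = seq_len(replicates))
  purrr::pmap_dfr(grid, function(kind, tau, u, replicate) {
    if (!is.null(done)) {
      hit <- dplyr::filter(done, .data$kind == !!kind, .data$tau == !!tau,
                           .data$u == !!u, .data$replicate == !!replicate)
      if (nrow(hit) == 1) return(hit)
    }
    sr <- derive_seed(seed, kind, tau, u, replicate)
    wc_k <- unname(wc_tab[[kind]])
    res <- tryCatch({
      net <- build_network(kind, n = n, avg_degree = avg_degree,
                           seed = derive_seed(sr, "net"))
      tr <- run_simulation(net, lif = lif,
                           plast = plasticity_params(tau = tau, u = u),
                           t_max = t_max, w_init = wc_k,
                           seed = derive_seed(sr, "run"))
      av <- extract_avalanches(tr)
      reg <- classify_regime(av, dk_factor = dk_factor)
      dev <- deviation_report(tr, w_c = wc_k,
                              t_a = window[1], t_b = window[2])
      tibble(kind = kind, tau = tau, u = u, replicate = replicate,
             seed = sr, regime = reg$label, me = dev$me, mae = dev$mae,
             alpha = if (is.null(reg$fit)) NA_real_ else reg$fit$alpha,
             n_avalanches = nrow(av), w_c_used = wc_k,
             error = NA_character_)
    }, error = function(e) {
      tibble(kind = kind, tau = tau, u = u, replicate = replicate,
             seed = sr, regime = NA_character_, me = NA_real_,
             mae = NA_real_, alpha = NA_real_, n_avalanches = NA_integer_,
             w_c_used = wc_k, error = conditionMessage(e))
    })
    res
  })
}
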