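#' Extract neuronal avalanches from a spike-count series
#'
#' An avalanche is a maximal contiguous run of strictly positive per-step
#' spike counts: it starts when the count first becomes non-zero and ends when
#' the count returns to zero.  Its size is the total spike count over the run
#' and its duration is the run length in steps.  A run still open at the end
#' of the series has no observed endpoint and is discarded.
#'
#' @param x A `soc_trace` (its `probe_spikes` column is used) or a nonnegative
#'   integer vector of per-step spike counts.
#' @return A `soc_avalanches` tibble with columns `start_t`, `size`,
#'   `duration`, and attributes `n_steps` and `total_spikes` (spikes in the
#'   whole series, including any discarded open run).
#' @examples
#' extract_avalanches(c(0, 2, 3, 0, 1, 0)) # sizes 5 and 1
#' @export
extract_avalanches <- function(x) {
  counts <- if (inherits(x, "soc_trace")) x$trace$probe_spikes else x
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("spike counts must be nonnegative integers.",
          class = "socnet_spec_error")
  }
  counts <- as.integer(counts)
  nt <- length(counts)
  out <- tibble(start_t = integer(), size = integer(), duration = integer())
  if (nt > 0) {
    pos <- counts > 0L
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    active <- which(r$values)
    # discard a run truncated by the end of the series
    if (length(active) > 0 && ends[active[length(active)]] == nt) {
      active <- active[-length(active)]
    }
    if (length(active) > 0) {
      cs <- c(0L, cumsum(counts))
      out <- tibble(
        start_t = starts[active],
        size = cs[ends[active] + 1L] - cs[starts[active]],
        duration = r$lengths[active]
      )
    }
  }
  structure(out, class = c("soc_avalanches", class(out)),
            n_steps = nt, total_spikes = sum(counts))
}

#' Avalanche-size susceptibility
#'
#' The susceptibility `chi_s = <s^2> - <s>^2`, i.e. the population variance of
#' the avalanche-size catalog.  It peaks at the critical synaptic strength,
#' which is how [estimate_critical_point()] locates `W_c`.
#'
#' @param sizes A `soc_avalanches` tibble or a numeric vector of sizes with at
#'   least two entries.
#' @return The value of `chi_s` (>= 0).
#' @examples
#' susceptibility(c(1, 3)) # 1
#' @export
susceptibility <- function(sizes) {
  s <- if (inherits(sizes, "soc_avalanches")) sizes$size else sizes
  if (length(s) < 2) {
    abort("susceptibility needs at least 2 avalanche sizes.",
          class = "socnet_spec_error")
  }
  mean(s^2) - mean(s)^2
}

#' Estimate the critical synaptic strength by susceptibility scan
#'
#' Runs fixed-strength simulations (plasticity off, all edges at the same `W`)
#' over a grid of strengths, extracts the avalanche catalog at each grid
#' point, and computes the susceptibility `chi_s`.  The critical strength
#' `W_c` is the grid value maximising `chi_s`; ties break towards the smallest
#' `W`.  Grid points producing fewer than two avalanches contribute
#' `chi_s = 0`.
#'
#' The reference scan is `W` from 0 to 4 in steps of 0.01 with long runs per
#' point; coarser grids and shorter runs give a stable peak location at much
#' lower cost and are the practical default for moderate `n`.
#'
#' @param net A `soc_network`.
#' @param lif [lif_params()].
#' @param w_min,w_max,w_step Scan grid (inclusive endpoints).
#' @param steps_per_w Simulation steps per grid point.
#' @param probe Probe set forwarded to [run_simulation()].
#' @param seed Optional seed covering the whole scan.
#' @return A `soc_wc` object: `$scan` tibble (`w`, `chi`, `n_avalanches`),
#'   `$w_c`, plus the grid settings.
#' @examples
#' \donttest{
#' net <- build_network("random", 500, 8, seed = 1)
#' wc <- estimate_critical_point(net, w_step = 0.25, steps_per_w = 2000,
#'                               seed = 1)
#' wc$w_c
#' }
#' @export
estimate_critical_point <- function(net, lif = lif_params(),
                                    w_min = 0, w_max = 4, w_step = 0.01,
                                    steps_per_w = 1e5, probe = "all",
                                    seed = NULL) {
  stopifnot(inherits(net, "soc_network"))
  grid <- seq(w_min, w_max, by = w_step)
  scan_one <- function(w) {
    if (w <= 0) w <- 1e-12  # W = 0: fully decoupled neurons
    tr <- run_simulation(net, lif = lif,
                         plast = plasticity_params(enabled = FALSE),
                         t_max = steps_per_w, w_init = w, probe = probe)
    av <- extract_avalanches(tr)
    chi <- if (nrow(av) < 2) 0 else susceptibility(av)
    c(chi = chi, n_avalanches = nrow(av))
  }
  run_all <- function() vapply(grid, scan_one, c(chi = 0, n_avalanches = 0))
  res <- if (is.null(seed)) run_all() else withr::with_seed(seed, run_all())

  scan <- tibble(w = grid, chi = res["chi", ],
                 n_avalanches = as.integer(res["n_avalanches", ]))
  structure(
    list(scan = scan, w_c = grid[which.max(scan$chi)],
         w_min = w_min, w_max = w_max, w_step = w_step,
         steps_per_w = steps_per_w, n = net$n, kind = net$kind, seed = seed),
    class = "soc_wc"
  )
}

#' @export
print.soc_wc <- function(x, ...) {
  cat(sprintf("<soc_wc> kind=%s n=%d grid [%g, %g] step %g -> W_c = %g\n",
              x$kind, x$n, x$w_min, x$w_max, x$w_step, x$w_c))
  invisible(x)
}

#' Write an avalanche catalog to CSV
#'
#' @param av A `soc_avalanches` tibble.
#' @param path Output path (`start_t, size, duration`).
#' @return `path`, invisibly.
#' @export
write_avalanches <- function(av, path) {
  stopifnot(inherits(av, "soc_avalanches"))
  utils::write.csv(as.data.frame(av), path, row.names = FALSE)
  invisible(path)
}

#' Read a one-column (or catalog) CSV of avalanche sizes
#'
#' Accepts either the catalog format written by [write_avalanches()] or a
#' one-column CSV of sizes, for standalone regime classification of external
#' catalogs.
#'
#' @param path CSV path.
#' @return Integer vector of avalanche sizes, in file order.
#' @export
read_sizes <- function(path) {
  df <- utils::read.csv(path)
  col <- if ("size" %in% names(df)) df$size else df[[1]]
  as.integer(col)
}
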