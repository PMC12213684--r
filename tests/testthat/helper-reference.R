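# Pure-R reference implementation of the LIF + plasticity dynamics, written
# directly from the update equations with no shared code with the package's
# compiled core.  It consumes one uniform draw per neuron per step in neuron
# order, exactly like the core, so under the same seed the two must agree
# bitwise on the spike raster and the recorded series.
reference_simulation <- function(net, lif, plast, t_max, w_init,
                                 record_raster = TRUE) {
  n <- net$n
  src <- net$edges$source
  tgt <- net$edges$target
  k <- net$in_degree
  w <- rep(w_init, nrow(net$edges))
  v <- rep(0, n)
  qual <- k[src] >= 2
  probe_counts <- integer(t_max)
  mean_w <- rep(NA_real_, t_max)
  raster <- list()
  for (t in seq_len(t_max)) {
    p <- ifelse(v - lif$theta > 0,
                lif$gamma * (v - lif$theta) / (1 + lif$gamma * (v - lif$theta)),
                lif$p_spont)
    x <- as.integer(runif(n) < p)
    probe_counts[t] <- sum(x)
    if (record_raster && any(x == 1)) {
      raster[[length(raster) + 1]] <- cbind(t, which(x == 1))
    }
    v_new <- ifelse(x == 1, 0, lif$mu * v + lif$i_ext)
    inputs <- rep(0, n)
    firing_edges <- x[src] == 1
    if (any(firing_edges)) {
      contrib <- tapply(w[firing_edges], tgt[firing_edges], sum)
      idx <- as.integer(names(contrib))
      inputs[idx] <- as.numeric(contrib) / k[idx]
    }
    v_new <- v_new + ifelse(x == 1, 0, inputs)
    if (plast$enabled) {
      w <- w + 1 / plast$tau - plast$u * w * x[src]
    }
    if (any(qual)) mean_w[t] <- mean(w[qual])
    v <- v_new
  }
  ras <- if (length(raster)) {
    m <- do.call(rbind, raster)
    tibble::tibble(t = m[, 1], neuron = m[, 2])
  } else {
    tibble::tibble(t = integer(), neuron = integer())
  }
  list(probe_counts = probe_counts, mean_w = mean_w, raster = ras,
       w_final = w, v_final = v)
}

# Critical Galton-Watson (branching-process) avalanche generator:
# unit-mean Poisson offspring, size = total progeny, duration = generations.
galton_watson_avalanches <- function(n, seed, size_cap = 1e5) {
  withr::with_seed(seed, {
    sizes <- integer(n)
    durs <- integer(n)
    for (i in seq_len(n)) {
      gen <- 1L
      s <- 1L
      d <- 1L
      while (gen > 0 && s < size_cap) {
        gen <- sum(stats::rpois(gen, 1))
        if (gen > 0) {
          s <- s + gen
          d <- d + 1L
        }
      }
      sizes[i] <- s
      durs[i] <- d
    }
    tibble::tibble(start_t = seq_len(n), size = sizes, duration = durs)
  })
}

# Brute-force mean local clustering by exhaustive triangle counting over the
# undirected skeleton (independent of igraph).
brute_force_clustering <- function(net) {
  n <- net$n
  adj <- matrix(FALSE, n, n)
  for (e in seq_len(nrow(net$edges))) {
    i <- net$edges$source[e]
    j <- net$edges$target[e]
    adj[i, j] <- TRUE
    adj[j, i] <- TRUE
  }
  local <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ])
    d <- length(nb)
    if (d < 2) return(0)
    links <- 0L
    for (a in seq_along(nb)) {
      for (b in seq_len(a - 1L)) {
        if (adj[nb[a], nb[b]]) links <- links + 1L
      }
    }
    2 * links / (d * (d - 1))
  }, numeric(1))
  mean(local)
}

make_tiny_net <- function(edges_df, n) {
  structure(
    list(kind = "manual", n = n,
         avg_degree = NA_integer_,
         edges = tibble::tibble(source = edges_df$source,
                                target = edges_df$target,
                                weight = if ("weight" %in% names(edges_df))
                                  edges_df$weight else 1),
         in_degree = tabulate(edges_df$target, nbins = n),
         params = list(), seed = NULL),
    class = "soc_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
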