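#' Build a directed network for avalanche simulations
#'
#' Constructs one of five directed topologies with a matched node count and a
#' matched edge budget of `n * avg_degree / 2` directed edges: a regular ring
#' lattice, a Watts-Strogatz small-world network, a Barabasi-Albert scale-free
#' network, a stochastic-block modular network, or an Erdos-Renyi random
#' network.  An undirected skeleton is generated first and every skeleton edge
#' is then assigned one direction uniformly at random, which excludes
#' reciprocal (bidirectional) pairs by construction so that cascades cannot
#' echo through immediate feedback loops.
#'
#' `avg_degree` is the mean *total* degree (in + out), so a network with
#' `n = 100` and `avg_degree = 8` has exactly 400 directed edges.  The
#' Barabasi-Albert and stochastic-block skeletons do not land on the budget
#' exactly; they are trimmed or augmented with uniformly random edges so that
#' all five kinds are structurally comparable at identical size.
#'
#' @param kind One of `"regular"`, `"small_world"`, `"scale_free"`,
#'   `"modular"`, `"random"`.
#' @param n Number of neurons (nodes), at least 2.
#' @param avg_degree Mean total degree; must be even, at least 2, and less
#'   than `n`.  Default 8.
#' @param p_rewire Watts-Strogatz rewiring probability (small-world only),
#'   in \[0, 1\].
#' @param blocks Number of modules for the modular network (at least 2).
#' @param within_frac Expected fraction of modular edges placed within blocks.
#' @param seed Optional integer seed; two builds with the same seed are
#'   identical.
#'
#' @return A `soc_network` object: a list with `n`, `kind`, `avg_degree`,
#'   `edges` (a tibble with `source`, `target`, `weight` columns, node ids
#'   1-based), `in_degree` (integer vector of length `n`), and the build
#'   parameters.
#'
#' @examples
#' net <- build_network("random", n = 100, avg_degree = 8, seed = 1)
#' nrow(net$edges) # 400
#' @export
build_network <- function(kind = c("regular", "small_world", "scale_free",
                                   "modular", "random"),
                          n, avg_degree = 8, p_rewire = 0.1, blocks = 10,
                          within_frac = 0.9, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    abort("`n` must be a single integer >= 2.", class = "socnet_spec_error")
  }
  n <- as.integer(n)
  if (!is.numeric(avg_degree) || length(avg_degree) != 1L ||
      avg_degree < 2 || avg_degree %% 2 != 0) {
    abort("`avg_degree` must be an even integer >= 2.",
          class = "socnet_spec_error")
  }
  if (avg_degree >= n) {
    abort("`avg_degree` must be smaller than `n`.",
          class = "socnet_spec_error")
  }
  if (kind == "small_world" && (p_rewire < 0 || p_rewire > 1)) {
    abort("`p_rewire` must lie in [0, 1].", class = "socnet_spec_error")
  }
  if (kind == "modular" && (blocks < 2 || blocks != round(blocks))) {
    abort("`blocks` must be an integer >= 2.", class = "socnet_spec_error")
  }
  if (kind %in% c("regular", "small_world") && avg_degree / 2 > (n - 1) / 2) {
    abort("ring lattice needs `avg_degree/2` neighbours per side; reduce `avg_degree`.",
          class = "socnet_spec_error")
  }

  m_target <- as.integer(n * avg_degree / 2)
  builder <- function() {
    g <- switch(kind,
      regular     = igraph::sample_smallworld(1, n, avg_degree / 2, 0),
      small_world = igraph::sample_smallworld(1, n, avg_degree / 2, p_rewire),
      random      = igraph::sample_gnm(n, m_target),
      scale_free  = igraph::sample_pa(n, m = avg_degree / 2, directed = FALSE),
      modular     = sbm_skeleton(n, m_target, blocks, within_frac)
    )
    g <- match_edge_budget(g, m_target)
    el <- igraph::as_edgelist(g, names = FALSE)
    flip <- runif(nrow(el)) < 0.5
    src <- ifelse(flip, el[, 2L], el[, 1L])
    tgt <- ifelse(flip, el[, 1L], el[, 2L])
    list(src = as.integer(src), tgt = as.integer(tgt))
  }
  el <- if (is.null(seed)) builder() else withr::with_seed(seed, builder())

  structure(
    list(
      kind = kind, n = n, avg_degree = as.integer(avg_degree),
      edges = tibble(source = el$src, target = el$tgt, weight = 1),
      in_degree = tabulate(el$tgt, nbins = n),
      params = list(p_rewire = if (kind == "small_world") p_rewire else NULL,
                    blocks = if (kind == "modular") as.integer(blocks) else NULL,
                    within_frac = if (kind == "modular") within_frac else NULL),
      seed = seed
    ),
    class = "soc_network"
  )
}

# Stochastic-block skeleton: `blocks` near-equal blocks, connection
# probabilities chosen so that ~within_frac of the m_target edges fall within
# blocks; the exact budget is enforced afterwards by match_edge_budget().
sbm_skeleton <- function(n, m_target, blocks, within_frac) {
  sizes <- rep(n %/% blocks, blocks)
  rem <- n %% blocks
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  pairs_within <- sum(sizes * (sizes - 1) / 2)
  pairs_between <- n * (n - 1) / 2 - pairs_within
  p_in <- min(1, within_frac * m_target / pairs_within)
  p_out <- min(1, (1 - within_frac) * m_target / pairs_between)
  pm <- matrix(p_out, blocks, blocks)
  diag(pm) <- p_in
  igraph::sample_sbm(n, pref.matrix = pm, block.sizes = sizes)
}

# Trim or augment an undirected simple graph to exactly m_target edges.
match_edge_budget <- function(g, m_target, max_tries = 100000L) {
  g <- igraph::simplify(g)
  m <- igraph::ecount(g)
  if (m > m_target) {
    drop <- sample.int(m, m - m_target)
    g <- igraph::delete_edges(g, drop)
  } else if (m < m_target) {
    n <- igraph::vcount(g)
    need <- m_target - m
    tries <- 0L
    while (need > 0L) {
      tries <- tries + 1L
      if (tries > max_tries) {
        abort("could not place extra edges without duplicates.",
              class = "socnet_build_error")
      }
      v <- sample.int(n, 2L)
      if (!igraph::are_adjacent(g, v[1L], v[2L])) {
        g <- igraph::add_edges(g, v)
        need <- need - 1L
      }
    }
  }
  g
}

#' @export
print.soc_network <- function(x, ...) {
  cat(sprintf("<soc_network> kind=%s n=%d directed edges=%d avg total degree=%.2f\n",
              x$kind, x$n, nrow(x$edges), 2 * nrow(x$edges) / x$n))
  invisible(x)
}

#' Mean local clustering coefficient of the undirected skeleton
#'
#' Edge directions are ignored: the directed edge list is folded back to its
#' undirected skeleton and the average local (Watts-Strogatz) clustering
#' coefficient is returned, with isolated and degree-1 nodes contributing 0.
#' For a ring lattice with total degree k this equals the closed form
#' 3(k - 2) / (4(k - 1)).
#'
#' @param net A `soc_network`.
#' @return A single value in \[0, 1\].
#' @examples
#' clustering_coefficient(build_network("regular", 100, 8, seed = 1))
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "soc_network"))
  if (net$n < 3) abort("clustering needs at least 3 nodes.",
                       class = "socnet_spec_error")
  g <- igraph::graph_from_edgelist(
    cbind(net$edges$source, net$edges$target), directed = FALSE)
  if (igraph::vcount(g) < net$n) {
    g <- igraph::add_vertices(g, net$n - igraph::vcount(g))
  }
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Count reciprocal (bidirectional) edge pairs
#'
#' Returns the number of ordered pairs (j, i) in the edge list whose reverse
#' (i, j) is also present.  Generated networks always score 0.
#'
#' @param net A `soc_network`.
#' @return Number of reciprocal pairs (each bidirectional pair counts once).
#' @export
reciprocal_pair_count <- function(net) {
  stopifnot(inherits(net, "soc_network"))
  key <- paste(net$edges$source, net$edges$target)
  rev <- paste(net$edges$target, net$edges$source)
  sum(rev %in% key) / 2
}

#' Write / read a directed edge list as TSV
#'
#' Plain `source<TAB>target<TAB>weight` with 0-based node ids and a single
#' header comment line `# N=<n> kind=<kind> seed=<seed>`.
#'
#' @param net A `soc_network`.
#' @param path File path.
#' @return `write_edgelist()` returns `path` invisibly; `read_edgelist()`
#'   returns a `soc_network`.
#' @export
write_edgelist <- function(net, path) {
  stopifnot(inherits(net, "soc_network"))
  header <- sprintf("# N=%d kind=%s seed=%s", net$n, net$kind,
                    if (is.null(net$seed)) "NA" else net$seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(
    data.frame(source = net$edges$source - 1L,
               target = net$edges$target - 1L,
               weight = net$edges$weight),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  header <- readLines(path, n = 1L)
  fields <- regmatches(header, gregexpr("[A-Za-z]+=[^ ]+", header))[[1]]
  kv <- strsplit(fields, "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  df <- utils::read.table(path, sep = "\t", skip = 1L,
                          col.names = c("source", "target", "weight"))
  n <- as.integer(meta[["N"]])
  tgt <- df$target + 1L
  structure(
    list(kind = meta[["kind"]], n = n, avg_degree = NA_integer_,
         edges = tibble(source = df$source + 1L, target = tgt,
                        weight = df$weight),
         in_degree = tabulate(tgt, nbins = n),
         params = list(),
         seed = suppressWarnings(as.integer(meta[["seed"]]))),
    class = "soc_network")
}
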