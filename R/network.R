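#' Build an intra-population small-world network
#'
#' Watts-Strogatz construction: a ring lattice in which every node connects
#' to its `mean_degree/2` nearest neighbours on each side is rewired with
#' probability `rewiring_p` per edge. The undirected skeleton is duplicated
#' into two directed edges, so every chemical synapse is directed and the
#' average out-degree equals `mean_degree`. Each directed edge carries an
#' independent intra-population conduction delay drawn from Gamma(shape = 1,
#' scale = 1) ms, and a synapse class determined by the presynaptic cell
#' type.
#'
#' @param N neuron count
#' @param mean_degree target average number of connections per neuron (even)
#' @param rewiring_p Watts-Strogatz rewiring probability in `[0, 1]`
#' @param frac_exc fraction of excitatory neurons in `(0, 1)`
#' @param seed integer seed; construction is a pure function of
#'   (arguments, seed)
#' @return a `network_spec` list: `N`, `exc_mask` (logical), `edges`
#'   (data.frame with `pre`, `post`, `delay`, `class`), `mean_degree`,
#'   `rewiring_p`
#' @export
build_small_world <- function(N, mean_degree, rewiring_p, frac_exc = 0.8,
                              seed = 1) {
  if (!(N > mean_degree && mean_degree >= 2)) {
    stop("build_small_world: need N > mean_degree >= 2")
  }
  if (mean_degree %% 2 != 0) {
    stop("build_small_world: mean_degree must be even (ring lattice)")
  }
  set.seed(seed)
  g <- igraph::sample_smallworld(dim = 1, size = N, nei = mean_degree / 2,
                                 p = rewiring_p, loops = FALSE,
                                 multiple = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  exc_mask <- assign_cell_types(N, frac_exc, seed = seed + 1L)
  # undirected skeleton -> two directed edges per pair
  pre <- c(el[, 1], el[, 2])
  post <- c(el[, 2], el[, 1])
  delays <- sample_intra_delays(length(pre), seed = seed + 2L)
  edges <- data.frame(
    pre = as.integer(pre), post = as.integer(post), delay = delays,
    class = ifelse(exc_mask[pre], "ampa", "gaba"),
    stringsAsFactors = FALSE
  )
  structure(list(N = as.integer(N), exc_mask = exc_mask, edges = edges,
                 mean_degree = mean_degree, rewiring_p = rewiring_p,
                 seed = as.integer(seed)),
            class = "network_spec")
}

#' Assign excitatory/inhibitory cell types
#'
#' Exactly `round(N * frac_exc)` neurons are labelled excitatory, at
#' positions drawn uniformly; deterministic under `seed`.
#'
#' @param N neuron count
#' @param frac_exc excitatory fraction, strictly inside (0, 1): an
#'   all-excitatory network cannot generate the inhibition-paced gamma
#'   rhythm
#' @param seed integer seed
#' @return logical vector, `TRUE` for excitatory
#' @export
assign_cell_types <- function(N, frac_exc, seed = 1) {
  if (!(frac_exc > 0 && frac_exc < 1)) {
    stop("assign_cell_types: frac_exc must lie strictly in (0, 1)")
  }
  n_exc <- round(N * frac_exc)
  set.seed(seed)
  mask <- rep(FALSE, N)
  mask[sample.int(N, n_exc)] <- TRUE
  mask
}

#' Sample intra-population conduction delays
#'
#' I.i.d. Gamma(shape = 1, scale = 1) draws in milliseconds, i.e.
#' Exponential(1): mean 1 ms, coefficient of variation 1, strictly positive.
#'
#' @param n_edges number of delays
#' @param seed integer seed
#' @return positive numeric vector of delays (ms)
#' @export
sample_intra_delays <- function(n_edges, seed = 1) {
  stopifnot(n_edges >= 1)
  set.seed(seed)
  d <- stats::rgamma(n_edges, shape = 1, scale = 1)
  # guard against numerically zero draws (delay must be positive)
  pmax(d, 1e-6)
}

#' Inter-population coupling specification
#'
#' @param frac_source_exc fraction of each population's excitatory neurons
#'   that send long-range projections, in (0, 1]
#' @param frac_target fraction of the other population that can receive
#'   them, in (0, 1]
#' @param tau_inter mean inter-areal conduction delay tau (ms), `>= 0`
#' @param delay_mode `"gamma"` (delays ~ Gamma(shape = tau, scale = 1), so
#'   mean tau and CV 1/sqrt(tau)) or `"constant"` (all delays exactly tau)
#' @param unidirectional if `TRUE` only population 1 projects onto
#'   population 2
#' @param degree_per_source long-range out-degree of each projecting neuron
#'   (targets drawn uniformly from the allowed fraction); default 10, an
#'   order of magnitude below the intra-population degree at reference scale
#' @return a `coupling_spec` list
#' @export
coupling_spec <- function(frac_source_exc = 0.9, frac_target = 0.25,
                          tau_inter = 0, delay_mode = c("gamma", "constant"),
                          unidirectional = FALSE, degree_per_source = 10) {
  delay_mode <- match.arg(delay_mode)
  if (!(frac_source_exc > 0 && frac_source_exc <= 1) ||
      !(frac_target > 0 && frac_target <= 1)) {
    stop("coupling_spec: fractions must lie in (0, 1]")
  }
  if (tau_inter < 0) stop("coupling_spec: tau_inter must be >= 0")
  structure(list(frac_source_exc = frac_source_exc,
                 frac_target = frac_target, tau_inter = tau_inter,
                 delay_mode = delay_mode, unidirectional = unidirectional,
                 degree_per_source = degree_per_source),
            class = "coupling_spec")
}

#' Sample inter-areal delays
#'
#' Gamma-distributed with scale 1 ms and shape `tau`, so the mean equals
#' `tau` and the coefficient of variation `1/sqrt(tau)` shrinks as the mean
#' delay grows. `delay_mode = "constant"` returns all delays equal to `tau`.
#' `tau = 0` returns zero delays (with a notice in gamma mode, where the
#' distribution degenerates).
#'
#' @param n number of delays
#' @param tau mean delay (ms)
#' @param delay_mode `"gamma"` or `"constant"`
#' @param seed integer seed
#' @return numeric vector of delays (ms)
#' @export
sample_inter_delays <- function(n, tau, delay_mode = "gamma", seed = 1) {
  stopifnot(n >= 0, tau >= 0)
  if (n == 0) return(numeric(0))
  if (tau == 0) {
    if (delay_mode == "gamma") {
      message("tau = 0 with gamma delays: falling back to zero delays")
    }
    return(rep(0, n))
  }
  if (delay_mode == "constant") return(rep(tau, n))
  set.seed(seed)
  pmax(stats::rgamma(n, shape = tau, scale = 1), 1e-6)
}

#' Build the inter-population projection set
#'
#' Long-range projections are exclusively excitatory: source neurons are
#' drawn from each population's excitatory cells (`frac_source_exc` of
#' them), targets uniformly from the allowed fraction of the other
#' population. In the unidirectional control only population 1 projects.
#' Neuron indices in the returned edge list are global: population 1 holds
#' `1..spec_A$N`, population 2 holds `spec_A$N + (1..spec_B$N)`.
#'
#' @param spec_A,spec_B [build_small_world()] results for the two populations
#' @param c a [coupling_spec()]
#' @param seed integer seed
#' @return data.frame with `pre`, `post`, `delay`, `class` (all `"ampa"`)
#' @export
build_inter_coupling <- function(spec_A, spec_B, c, seed = 1) {
  stopifnot(inherits(c, "coupling_spec"))
  one_direction <- function(src_spec, dst_spec, src_offset, dst_offset,
                            sd) {
    set.seed(sd)
    exc <- which(src_spec$exc_mask)
    n_src <- max(1L, round(length(exc) * c$frac_source_exc))
    sources <- sort(sample(exc, n_src))
    n_tgt_pool <- max(1L, round(dst_spec$N * c$frac_target))
    target_pool <- sort(sample.int(dst_spec$N, n_tgt_pool))
    k <- c$degree_per_source
    if (k == 0) {
      return(data.frame(pre = integer(0), post = integer(0)))
    }
    pre <- rep(sources, each = k)
    post <- as.vector(vapply(
      seq_along(sources),
      function(i) sample(target_pool, k, replace = n_tgt_pool < k),
      integer(k)
    ))
    data.frame(pre = pre + src_offset, post = post + dst_offset,
               stringsAsFactors = FALSE)
  }
  edges <- one_direction(spec_A, spec_B, 0L, spec_A$N, seed)
  if (!c$unidirectional) {
    edges <- rbind(edges,
                   one_direction(spec_B, spec_A, spec_A$N, 0L, seed + 1L))
  }
  edges$delay <- sample_inter_delays(nrow(edges), c$tau_inter,
                                     c$delay_mode, seed = seed + 2L)
  edges$class <- rep("ampa", nrow(edges))
  edges
}

#' Clustering coefficient of a network spec
#'
#' Global transitivity of the undirected skeleton; for a ring lattice of
#' even degree k this equals `3(k-2) / (4(k-1))`.
#'
#' @param spec a `network_spec`
#' @return clustering coefficient in `[0, 1]`
#' @export
clustering_coefficient <- function(spec) {
  und <- unique(t(apply(cbind(spec$edges$pre, spec$edges$post), 1, sort)))
  g <- igraph::graph_from_edgelist(und, directed = FALSE)
  igraph::transitivity(g, type = "global")
}

#' Export a network spec as an edge-list CSV
#'
#' @param spec a `network_spec` or inter-coupling edge data.frame
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_edges_csv <- function(spec, path) {
  edges <- if (inherits(spec, "network_spec")) spec$edges else spec
  utils::write.csv(edges, path, row.names = FALSE)
  invisible(path)
}
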