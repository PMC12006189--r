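# Small-worldness (Humphries-Gurney sigma) and the threshold search that
# binarizes the fused connectivity matrix.

# cache of random-reference (C_rand, L_rand) keyed by node/edge count and
# seed, so the 41-point threshold search does not resample references for
# every segment that lands on the same graph density
.sw_cache <- new.env(parent = emptyenv())

graph_from_adjacency <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

# mean local clustering coefficient; nodes with degree < 2 count as 0
mean_clustering <- function(g) {
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

# characteristic path length over connected pairs of the largest component
char_path_length <- function(g) {
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  if (igraph::vcount(sub) < 2L) return(0)
  igraph::mean_distance(sub)
}

random_reference_stats <- function(n_nodes, n_edges, n_random, seed) {
  key <- paste(n_nodes, n_edges, n_random, seed, sep = ":")
  hit <- .sw_cache[[key]]
  if (!is.null(hit)) return(hit)
  C <- L <- numeric(n_random)
  for (r in seq_len(n_random)) {
    g <- with_seed(derive_seed(seed, n_nodes, n_edges, r),
                   igraph::sample_gnm(n_nodes, n_edges))
    C[r] <- mean_clustering(g)
    L[r] <- char_path_length(g)
  }
  out <- list(C_rand = mean(C), L_rand = mean(L))
  .sw_cache[[key]] <- out
  out
}

#' Small-worldness of a binary graph
#'
#' Humphries-Gurney sigma: `(C / C_rand) / (L / L_rand)`, where C is the
#' mean local clustering coefficient (nodes of degree < 2 contribute 0),
#' L the characteristic path length over connected pairs of the largest
#' component, and the reference values are means over `n_random`
#' density-matched uniform random graphs (same node and edge count,
#' seeded). Values above 1 indicate lattice-like clustering combined with
#' random-like short paths.
#'
#' @param adj Symmetric binary adjacency matrix with zero diagonal and at
#'   least one edge.
#' @param n_random Number of random reference graphs (default 20).
#' @param seed Integer seed for the reference ensemble.
#' @return Scalar sigma; `+Inf` (with a warning) when the random reference
#'   has zero clustering while the graph does not.
#' @export
small_worldness <- function(adj, n_random = 20, seed = 1L) {
  adj <- as.matrix(adj)
  if (any(adj != t(adj))) stop("adjacency must be symmetric")
  if (any(!adj %in% c(0, 1))) stop("adjacency must be binary")
  n_edges <- sum(adj[upper.tri(adj)])
  if (n_edges == 0L) stop("small-worldness undefined for an edgeless graph")
  g <- graph_from_adjacency(adj)
  C <- mean_clustering(g)
  L <- char_path_length(g)
  ref <- random_reference_stats(nrow(adj), n_edges, n_random, seed)
  if (ref$C_rand == 0) {
    if (C == 0) return(NaN)
    warning("random reference has zero clustering; sigma reported as +Inf")
    return(Inf)
  }
  if (L == 0 || ref$L_rand == 0) return(NaN)
  (C / ref$C_rand) / (L / ref$L_rand)
}

#' Small-worldness-maximizing binarization threshold
#'
#' Evaluates the small-worldness of the binarized graph at each threshold
#' on the grid 0.30 to 0.70 in steps of 0.01 and picks the maximizer, with
#' ties broken toward the smallest threshold. Edgeless binarizations score
#' `-Inf`; if every grid point is degenerate the search falls back to 0.5
#' with a warning.
#'
#' @param pcoh A [connectivity_matrix()] of kind "PCOH".
#' @param grid Threshold grid (default `seq(0.30, 0.70, by = 0.01)`).
#' @param n_random,seed Passed to [small_worldness()].
#' @return List with `grid`, `sigmas`, `chosen` and `sigma_at_threshold`.
#' @export
select_threshold <- function(pcoh, grid = seq(0.30, 0.70, by = 0.01),
                             n_random = 20, seed = 1L) {
  stopifnot(inherits(pcoh, "connectivity_matrix"))
  if (pcoh$kind != "PCOH") stop("select_threshold expects a PCOH matrix")
  sigmas <- vapply(grid, function(th) {
    adj <- binarize(pcoh, th)$adjacency
    if (sum(adj) == 0) return(-Inf)
    s <- small_worldness(adj, n_random = n_random, seed = seed)
    if (is.nan(s)) -Inf else s
  }, numeric(1))
  if (all(!is.finite(sigmas) & sigmas < 0)) {
    warning("all thresholds give degenerate graphs; falling back to 0.5")
    return(list(grid = grid, sigmas = sigmas, chosen = 0.5,
                sigma_at_threshold = NA_real_))
  }
  best <- which.max(sigmas)
  list(grid = grid, sigmas = sigmas, chosen = grid[best],
       sigma_at_threshold = sigmas[best])
}

#' Binarize at the small-worldness-maximizing threshold
#'
#' @param pcoh A [connectivity_matrix()] of kind "PCOH".
#' @param ... Passed to [select_threshold()].
#' @return List with `adjacency`, `threshold_used`, `sigma_at_threshold`.
#' @export
binarize_smallworld <- function(pcoh, ...) {
  sel <- select_threshold(pcoh, ...)
  out <- binarize(pcoh, sel$chosen)
  out$sigma_at_threshold <- sel$sigma_at_threshold
  out
}
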