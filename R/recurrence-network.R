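#' Recurrence matrix as a graph adjacency
#'
#' Reinterprets a recurrence matrix as the adjacency matrix of an
#' unweighted, undirected recurrence network: each embedded point becomes a
#' node and each recurrence (i, j) an edge. The diagonal and, by default,
#' the Theiler band of the source matrix are zeroed so that trivially
#' time-adjacent recurrences do not become edges.
#'
#' @param R a `neurodyn_rp` from [recurrence_matrix()] or a binary symmetric
#'   matrix.
#' @param zero_theiler drop edges inside the Theiler band (default `TRUE`;
#'   only relevant for `neurodyn_rp` input, which carries its window).
#' @return object of class `neurodyn_rn`: list with `adjacency` (binary,
#'   zero diagonal), `graph` (igraph object), `epsilon`.
#' @export
rn_adjacency <- function(R, zero_theiler = TRUE) {
  eps <- NA_real_
  theiler <- 0L
  if (inherits(R, "neurodyn_rp")) {
    eps <- R$epsilon
    if (zero_theiler) theiler <- R$theiler
    R <- R$matrix
  }
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  A <- (R != 0) * 1L
  np <- nrow(A)
  for (k in 0:min(theiler, np - 1L)) {
    idx <- seq_len(np - k)
    A[cbind(idx, idx + k)] <- 0L
    A[cbind(idx + k, idx)] <- 0L
  }
  diag(A) <- 0L
  A <- (A | t(A)) * 1L   # enforce symmetry defensively
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
  structure(list(adjacency = A, graph = g, epsilon = eps),
            class = "neurodyn_rn")
}

#' Recurrence-network measures
#'
#' Global network measures of the epsilon-recurrence network: edge density,
#' global clustering coefficient (transitivity), mean local clustering
#' coefficient, average shortest path length, global efficiency (mean
#' inverse shortest-path distance over distinct node pairs) and mean
#' betweenness centrality. On a disconnected graph the average path length
#' is computed on the largest connected component and the result carries
#' `flags = "disconnected"`; efficiency handles unreachable pairs naturally
#' (their inverse distance is 0).
#'
#' @param G a `neurodyn_rn` from [rn_adjacency()] (or adjacency matrix).
#' @param betweenness_max exact betweenness is computed on a uniform node
#'   subsample of this size (with the seed below) when the graph is larger;
#'   default 2000, i.e. exact for test-scale graphs.
#' @param seed seed for the betweenness subsample (default 1).
#' @return named numeric vector: `density`, `transitivity`,
#'   `local_clustering`, `avg_path_length`, `efficiency`, `betweenness`,
#'   with attribute `flags`.
#' @export
rn_measures <- function(G, betweenness_max = 2000L, seed = 1L) {
  if (!inherits(G, "neurodyn_rn")) G <- rn_adjacency(G)
  g <- G$graph
  n <- igraph::vcount(g)
  if (n < 3L) stop("need at least 3 nodes")
  flags <- character(0)
  dens <- igraph::edge_density(g)
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) { trans <- 0; flags <- c(flags, "transitivity") }
  locc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  comps <- igraph::components(g)
  if (comps$no > 1L) flags <- c(flags, "disconnected")
  biggest <- which.max(comps$csize)
  sub <- igraph::induced_subgraph(g, which(comps$membership == biggest))
  apl <- if (igraph::vcount(sub) > 1L)
    igraph::mean_distance(sub, directed = FALSE) else { flags <- c(flags, "avg_path_length"); 0 }
  D <- igraph::distances(g)
  inv <- 1 / D[upper.tri(D)]
  inv[!is.finite(inv)] <- 0
  eff <- mean(inv)
  btw <- if (n > betweenness_max) {
    keep <- with_seed(seed, sort(sample.int(n, betweenness_max)))
    gs <- igraph::induced_subgraph(g, keep)
    mean(igraph::betweenness(gs, directed = FALSE))
  } else {
    mean(igraph::betweenness(g, directed = FALSE))
  }
  structure(c(density = dens, transitivity = trans,
              local_clustering = mean(locc), avg_path_length = apl,
              efficiency = eff, betweenness = btw),
            flags = flags)
}
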