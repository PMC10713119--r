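#' Build the radius-thresholded neighbor graph
#'
#' Samples become nodes; an undirected edge joins samples i and j exactly
#' when their original dissimilarity is strictly below the neighborhood
#' radius. Edge weights are the original dissimilarities, so only pairwise
#' values the radius declares trustworthy enter the graph. Duplicate samples
#' (dissimilarity exactly 0 between distinct samples) are connected by a
#' zero-weight edge so they remain mutually at distance zero. The result may
#' be disconnected; see [connect_graph()].
#'
#' @param D distance matrix (or `dist`).
#' @param radius positive neighborhood radius in the units of `D`.
#' @return an object of class `neighbor_graph`: a list with the underlying
#'   `igraph` graph (`graph`, edge attributes `weight` and `borrowed`), the
#'   `radius`, sample `labels`, and `n_mst_edges` (0 until connectivity
#'   repair).
#' @seealso [connect_graph()], [geodesic_distances()]
#' @export
build_neighbor_graph <- function(D, radius) {
  D <- as_distance_matrix(D)
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stop("radius must be a single positive number")
  n <- nrow(D)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- rownames(D)
  sel <- upper.tri(D) & D < radius
  idx <- which(sel, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    g <- igraph::add_edges(g, as.vector(t(idx)),
                           weight = D[idx], borrowed = FALSE)
  }
  structure(list(graph = g, radius = radius, labels = rownames(D), n = n,
                 n_mst_edges = 0L),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  ne <- igraph::ecount(x$graph)
  cat(sprintf(
    "neighbor graph: %d samples, %d edges (%d borrowed from MST), radius %g\n",
    x$n, ne, x$n_mst_edges, x$radius))
  invisible(x)
}

# MST of the complete graph weighted by the original distances; edges built
# in lexicographic (i, j) order so ties break reproducibly.
complete_mst <- function(D) {
  n <- nrow(D)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  gc <- igraph::make_empty_graph(n, directed = FALSE)
  gc <- igraph::add_edges(gc, as.vector(t(idx)), weight = D[idx])
  mt <- igraph::mst(gc, weights = igraph::E(gc)$weight)
  list(edges = igraph::as_edgelist(mt, names = FALSE),
       weights = igraph::E(mt)$weight)
}

#' Repair connectivity by borrowing minimum-spanning-tree edges
#'
#' If the neighbor graph is disconnected (sparse sampling along the
#' gradient, or a small radius), a minimum spanning tree over the complete
#' graph of original distances is computed, and exactly those MST edges
#' whose endpoints lie in different connected components are added until the
#' graph is connected. Borrowed edges are flagged so diagnostics can count
#' how many pairwise values above the radius had to be trusted anyway.
#'
#' @param ng a `neighbor_graph` built from `D` with [build_neighbor_graph()].
#' @param D the same distance matrix the graph was built from.
#' @param mst optional precomputed result of the internal complete-graph MST
#'   (used by [select_radius()] to avoid recomputing it for every radius).
#' @return a connected `neighbor_graph`; `n_mst_edges` records how many
#'   edges were borrowed (number of components minus one).
#' @export
connect_graph <- function(ng, D, mst = NULL) {
  stopifnot(inherits(ng, "neighbor_graph"))
  comp <- igraph::components(ng$graph)
  if (comp$no == 1L) return(ng)
  D <- as_distance_matrix(D)
  if (!identical(rownames(D), ng$labels))
    stop("distance matrix labels do not match the graph")
  if (is.null(mst)) mst <- complete_mst(D)
  membership <- comp$membership
  g <- ng$graph
  added <- 0L
  for (k in seq_len(nrow(mst$edges))) {
    a <- mst$edges[k, 1]; b <- mst$edges[k, 2]
    if (membership[a] != membership[b]) {
      g <- igraph::add_edges(g, c(a, b),
                             weight = mst$weights[k], borrowed = TRUE)
      membership[membership == membership[b]] <- membership[a]
      added <- added + 1L
    }
  }
  ng$graph <- g
  ng$n_mst_edges <- added
  stopifnot(igraph::is_connected(g))
  ng
}

#' Average node degree of the neighbor graph
#'
#' Counts only radius-thresholded edges, not borrowed MST edges: the degree
#' filter exists to detect graphs too sparse to trust, and MST edges are
#' present at every radius by construction.
#'
#' @param ng a `neighbor_graph`.
#' @return mean number of neighbors per node, `2 * n_edges / n`.
#' @export
average_degree <- function(ng) {
  stopifnot(inherits(ng, "neighbor_graph"))
  ne <- igraph::ecount(ng$graph)
  if (ne == 0) return(0)
  borrowed <- igraph::E(ng$graph)$borrowed
  2 * sum(!borrowed) / ng$n
}

#' All-pairs geodesic distances on the neighbor graph
#'
#' The adjusted pairwise value between two samples is the total weight of
#' the shortest path between their nodes (Dijkstra from every source; all
#' weights are nonnegative). The output is a path-length metric: symmetric,
#' zero diagonal, and satisfying the triangle inequality. Where a direct
#' edge exists the geodesic can only be shorter or equal; for semimetric
#' inputs such as Bray-Curtis some direct values may genuinely shrink.
#'
#' @param ng a connected `neighbor_graph` (run [connect_graph()] first).
#' @return a distance matrix of geodesic lengths.
#' @export
geodesic_distances <- function(ng) {
  stopifnot(inherits(ng, "neighbor_graph"))
  if (!igraph::is_connected(ng$graph))
    stop("neighbor graph is disconnected; run connect_graph() first")
  dm <- igraph::distances(ng$graph, weights = igraph::E(ng$graph)$weight,
                          algorithm = "dijkstra")
  dimnames(dm) <- list(ng$labels, ng$labels)
  dm <- (dm + t(dm)) / 2
  diag(dm) <- 0
  stopifnot(all(is.finite(dm)), all(dm >= 0))
  dm
}

#' Local manifold adjustment at a fixed neighborhood radius
#'
#' The core transform: threshold the matrix into a neighbor graph, repair
#' connectivity with MST edges, and recompute all pairwise values as graph
#' geodesics. For a metric input and a radius above the largest distance
#' this is the identity; as the radius shrinks, distant samples must be
#' reached through chains of neighbors and their adjusted distances grow,
#' restoring the dynamic range a saturated measure has lost.
#'
#' @inheritParams build_neighbor_graph
#' @return the adjusted distance matrix.
#' @examples
#' D <- as_distance_matrix(as.matrix(dist(cbind(1:6))))
#' lmdist_fixed_radius(D, radius = 1.5)  # chain graph: identity here
#' @export
lmdist_fixed_radius <- function(D, radius) {
  D <- as_distance_matrix(D)
  ng <- build_neighbor_graph(D, radius)
  ng <- connect_graph(ng, D)
  geodesic_distances(ng)
}
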