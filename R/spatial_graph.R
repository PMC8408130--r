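#' Build a spatial patch network from coordinates
#'
#' Patches are connected when the Euclidean distance between their
#' coordinates is strictly below `radius`. The graph Laplacian is
#' degree matrix minus adjacency, so every row sums to zero.
#'
#' @param coords N x 2 matrix of patch coordinates in the unit square.
#' @param radius connection threshold (> 0).
#' @return An object of class `spatial_network`: list with `N`, `coords`,
#'   `radius`, `adjacency` (N x N logical, symmetric, diagonal-free) and
#'   `laplacian` (N x N numeric).
#' @seealso [rgg_network()] for connected random geometric graphs.
#' @export
spatial_network <- function(coords, radius) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, nrow(coords) >= 2, radius > 0)
  N <- nrow(coords)
  dmat <- as.matrix(dist(coords))
  adjacency <- dmat < radius
  diag(adjacency) <- FALSE
  laplacian <- diag(rowSums(adjacency)) - adjacency * 1
  structure(list(N = N, coords = coords, radius = radius,
                 adjacency = adjacency, laplacian = laplacian),
            class = "spatial_network")
}

#' Generate a connected random geometric graph of habitat patches
#'
#' Patch coordinates are drawn uniformly in the two-dimensional unit
#' square; patches closer than `radius` are connected. Draws that are not
#' a single connected component are discarded and redrawn. Defaults
#' (N = 10, radius = 0.32) are the study conditions used throughout the
#' package.
#'
#' @param N number of patches (>= 2).
#' @param radius connection threshold.
#' @param max_attempts rejection-sampling budget before the (N, radius)
#'   combination is declared infeasible.
#' @return A connected `spatial_network`.
#' @examples
#' set.seed(1)
#' net <- rgg_network()
#' rowSums(net$laplacian) # all zero
#' @export
rgg_network <- function(N = 10, radius = 0.32, max_attempts = 10000) {
  stopifnot(N >= 2, radius > 0, max_attempts >= 1)
  for (attempt in seq_len(max_attempts)) {
    net <- spatial_network(cbind(runif(N), runif(N)), radius)
    if (is_connected(net)) return(net)
  }
  stop("no connected random geometric graph in ", max_attempts,
       " attempts; (N = ", N, ", radius = ", radius, ") appears infeasible",
       call. = FALSE)
}

#' Is a spatial network a single connected component?
#'
#' @param net a `spatial_network`.
#' @return logical.
#' @export
is_connected <- function(net) {
  stopifnot(inherits(net, "spatial_network"))
  graph_connected(net$adjacency)
}

#' Eigenvalues of the patch-network Laplacian
#'
#' Returns the Laplacian spectrum sorted in increasing order,
#' \eqn{\mu_0 \le \ldots \le \mu_{N-1}}. The smallest eigenvalue is always
#' 0 (uniform eigenvector); the graph is connected iff the second-smallest
#' eigenvalue is positive. These eigenvalues govern the decomposition of
#' the metacommunity spectrum when all patches are identical.
#'
#' @param net a `spatial_network`.
#' @return numeric vector of N eigenvalues, ascending.
#' @export
laplacian_spectrum <- function(net) {
  stopifnot(inherits(net, "spatial_network"))
  sort(eigen(net$laplacian, symmetric = TRUE, only.values = TRUE)$values)
}

#' @export
print.spatial_network <- function(x, ...) {
  cat("spatial patch network (random geometric graph)\n")
  cat("  patches:  ", x$N, "\n")
  cat("  radius:   ", x$radius, "\n")
  cat("  links:    ", sum(x$adjacency) / 2, "\n")
  cat("  connected:", is_connected(x), "\n")
  invisible(x)
}

#' Write / read a spatial network as GraphML
#'
#' Coordinates are stored as vertex attributes `x` and `y`; the connection
#' radius as graph attribute `radius`.
#'
#' @param net a `spatial_network`.
#' @param path file path.
#' @return `write_spatial_network()` returns `path` invisibly;
#'   `read_spatial_network()` returns a `spatial_network`.
#' @export
write_spatial_network <- function(net, path) {
  stopifnot(inherits(net, "spatial_network"))
  g <- igraph::graph_from_adjacency_matrix(net$adjacency * 1,
                                           mode = "undirected")
  igraph::V(g)$x <- net$coords[, 1]
  igraph::V(g)$y <- net$coords[, 2]
  g <- igraph::set_graph_attr(g, "radius", net$radius)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_spatial_network
#' @export
read_spatial_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  coords <- cbind(igraph::V(g)$x, igraph::V(g)$y)
  spatial_network(coords, igraph::graph_attr(g, "radius"))
}

#' Export the Laplacian matrix as CSV
#'
#' @param net a `spatial_network`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_laplacian_csv <- function(net, path) {
  stopifnot(inherits(net, "spatial_network"))
  write.csv(net$laplacian, path, row.names = FALSE)
  invisible(path)
}
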