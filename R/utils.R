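#' @keywords internal
"_PACKAGE"

# Union-find with path halving; used for spanning-tree validation and Kruskal.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# Validate an edge list as a spanning tree over n nodes: exactly n-1 edges,
# no cycle (union-find), hence connected.
is_spanning_tree <- function(edges, n_nodes) {
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2)
  edges <- as.matrix(edges)
  if (nrow(edges) != n_nodes - 1L) return(FALSE)
  if (any(!is.finite(edges)) || any(edges < 1) || any(edges > n_nodes)) return(FALSE)
  if (any(edges[, 1] == edges[, 2])) return(FALSE)
  parent <- uf_new(n_nodes)
  for (k in seq_len(nrow(edges))) {
    a <- uf_find(parent, edges[k, 1])
    b <- uf_find(parent, edges[k, 2])
    if (a == b) return(FALSE)
    parent[a] <- b
  }
  TRUE
}

#' Random spanning tree over n nodes
#'
#' Draws a uniform labelled tree via a random Pruefer sequence.
#'
#' @param n_nodes number of nodes (>= 2)
#' @param seed integer seed
#' @return two-column integer matrix of edges (n_nodes - 1 rows)
#' @export
random_spanning_tree <- function(n_nodes, seed = NULL) {
  stopifnot(n_nodes >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (n_nodes == 2) return(matrix(c(1L, 2L), ncol = 2))
  pruefer <- sample.int(n_nodes, n_nodes - 2L, replace = TRUE)
  degree <- rep(1L, n_nodes)
  for (p in pruefer) degree[p] <- degree[p] + 1L
  edges <- matrix(0L, nrow = n_nodes - 1L, ncol = 2L)
  for (i in seq_along(pruefer)) {
    leaf <- which(degree == 1L)[1]
    edges[i, ] <- c(leaf, pruefer[i])
    degree[leaf] <- degree[leaf] - 1L
    degree[pruefer[i]] <- degree[pruefer[i]] - 1L
  }
  edges[n_nodes - 1L, ] <- which(degree == 1L)
  edges
}

# Deterministic per-subject seed derived from a master seed; a small
# multiplicative hash keeps values below 2^31 and distinct across subjects.
derive_seed <- function(master_seed, index) {
  x <- (as.numeric(master_seed) %% 2147483647) + 0
  x <- (x * 48271 + as.numeric(index) * 16807 + 12345) %% 2147483647
  as.integer(x)
}

# Linear-interpolation quantiles (type 7); the outlier rule and the IQR
# motion metric both depend on this convention.
quantile_li <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

stop_invalid <- function(...) stop(..., call. = FALSE)
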