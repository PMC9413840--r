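# Functional connectivity matrices, the maximum-weight spanning tree
# backbone (Kruskal + union-find), and global/nodal MST metrics.

#' Pearson connectivity matrix
#'
#' Pairwise Pearson correlation over the retained ROIs of a time-series
#' object. Excluded ROIs (named set or preset) are removed before
#' correlation, so edge counts and normalisations downstream refer to the
#' retained node set only.
#'
#' @param roi_ts a \code{\link{roi_timeseries}}
#' @param exclude character vector of ROI labels to drop, or a preset name
#'   (\code{"occipital8"}, \code{"occipital16"})
#' @return list of class \code{connectivity_matrix}: \code{weights}
#'   (symmetric, unit diagonal), \code{roi_labels}, \code{n_nodes}
#' @export
connectivity_matrix <- function(roi_ts, exclude = character(0)) {
  if (length(exclude) == 1 && exclude %in% c("occipital8", "occipital16"))
    exclude <- roi_exclusion_preset(exclude, length(roi_ts$roi_labels))
  keep <- !(roi_ts$roi_labels %in% exclude)
  vals <- roi_ts$values[keep, , drop = FALSE]
  if (ncol(vals) < 3) stop_invalid("need at least 3 retained volumes")
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0))
    stop_invalid("zero-variance ROI: ",
                 paste(roi_ts$roi_labels[keep][sds == 0], collapse = ", "))
  W <- stats::cor(t(vals))
  W <- (W + t(W)) / 2
  diag(W) <- 1
  structure(list(weights = W, roi_labels = roi_ts$roi_labels[keep],
                 n_nodes = sum(keep)),
            class = "connectivity_matrix")
}

#' Maximum-weight spanning tree of a connectivity matrix
#'
#' Negative correlations are set to 0, then Kruskal's algorithm is run
#' over the remaining positive edges in order of descending weight with
#' union-find cycle rejection, yielding the spanning tree of maximum
#' total weight — the strongest-connection backbone of the network. Ties
#' are broken deterministically by (smaller first node index, then second
#' index). If the positive-weight subgraph does not connect all nodes an
#' error is raised (zero-weight edges are never silently used).
#'
#' @param W a \code{connectivity_matrix}, or a plain symmetric weight
#'   matrix
#' @return list of class \code{spanning_tree}: \code{edges} (data frame
#'   \code{node_a}, \code{node_b}, \code{weight} — the original matrix
#'   weights), \code{n_nodes}, \code{roi_labels}, \code{adjacency}
#'   (unweighted logical matrix)
#' @export
build_mst <- function(W) {
  labels <- NULL
  if (inherits(W, "connectivity_matrix")) {
    labels <- W$roi_labels
    W <- W$weights
  }
  W <- as.matrix(W)
  n <- nrow(W)
  if (is.null(labels)) labels <- rownames(W)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  Wpos <- W
  Wpos[Wpos < 0] <- 0
  iu <- which(upper.tri(Wpos), arr.ind = TRUE)
  w <- Wpos[iu]
  keep <- w > 0
  iu <- iu[keep, , drop = FALSE]
  w <- w[keep]
  ord <- order(-w, iu[, 1], iu[, 2])
  parent <- uf_new(n)
  ea <- integer(n - 1); eb <- integer(n - 1); ew <- numeric(n - 1)
  n_edges <- 0L
  for (k in ord) {
    a <- uf_find(parent, iu[k, 1])
    b <- uf_find(parent, iu[k, 2])
    if (a != b) {
      parent[a] <- b
      n_edges <- n_edges + 1L
      ea[n_edges] <- iu[k, 1]; eb[n_edges] <- iu[k, 2]
      ew[n_edges] <- W[iu[k, 1], iu[k, 2]]
      if (n_edges == n - 1L) break
    }
  }
  if (n_edges < n - 1L) {
    roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
    stop_invalid("positive-weight subgraph is disconnected: ",
                 length(unique(roots)), " components")
  }
  adj <- matrix(FALSE, n, n)
  adj[cbind(ea, eb)] <- TRUE
  adj[cbind(eb, ea)] <- TRUE
  structure(list(edges = data.frame(node_a = ea, node_b = eb, weight = ew),
                 n_nodes = n, roi_labels = labels, adjacency = adj),
            class = "spanning_tree")
}

# Adjacency list of a spanning_tree.
tree_adjlist <- function(tree) {
  adj <- vector("list", tree$n_nodes)
  for (k in seq_len(nrow(tree$edges))) {
    a <- tree$edges$node_a[k]; b <- tree$edges$node_b[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# BFS distances (edge counts) from one source over an adjacency list.
bfs_dist <- function(adj, source, n) {
  dist <- rep(NA_integer_, n)
  dist[source] <- 0L
  queue <- source
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (is.na(dist[w])) {
      dist[w] <- dist[v] + 1L
      queue <- c(queue, w)
    }
  }
  dist
}

#' Nodal MST metrics: degree and betweenness centrality
#'
#' Degree is the adjacency row sum. Betweenness centrality of node v is
#' the fraction of unordered node pairs whose unique tree path passes
#' through v as an interior node, normalised by (N-1)(N-2)/2 so the
#' centre of a star scores 1 and every leaf scores 0. In a tree the raw
#' count is computed from the component sizes s_1..s_k of the forest left
#' by removing v: sum over pairs s_i s_j = ((sum s)^2 - sum s^2)/2.
#'
#' @param tree a \code{spanning_tree}
#' @return data frame: \code{node}, \code{roi}, \code{degree}, \code{bc}
#' @export
nodal_metrics <- function(tree) {
  n <- tree$n_nodes
  adj <- tree_adjlist(tree)
  degree <- lengths(adj)
  # iterative post-order subtree sizes rooted at 1
  parent <- integer(n); order <- integer(n)
  visited <- rep(FALSE, n); queue <- 1L; visited[1L] <- TRUE; pos <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; pos <- pos + 1L; order[pos] <- v
    for (w in adj[[v]]) if (!visited[w]) {
      visited[w] <- TRUE; parent[w] <- v; queue <- c(queue, w)
    }
  }
  size <- rep(1L, n)
  for (v in rev(order[-1])) size[parent[v]] <- size[parent[v]] + size[v]
  bc_raw <- numeric(n)
  for (v in seq_len(n)) {
    comp <- vapply(adj[[v]], function(w) {
      if (parent[w] == v) size[w] else n - size[v]
    }, numeric(1))
    bc_raw[v] <- (sum(comp)^2 - sum(comp^2)) / 2
  }
  denom <- (n - 1) * (n - 2) / 2
  data.frame(node = seq_len(n), roi = tree$roi_labels,
             degree = as.integer(degree),
             bc = if (denom > 0) bc_raw / denom else 0)
}

#' Global MST metrics
#'
#' Average connectivity strength (mean original weight of tree edges,
#' unnormalised), maximum betweenness centrality, leaf fraction, and
#' size-normalised diameter and average eccentricity. Leaf fraction
#' divides the number of degree-1 nodes by N-1 (a star maps to 1);
#' diameter and eccentricity divide edge counts by N-1 (a path's diameter
#' maps to 1), so every normalised metric lies in (0, 1].
#'
#' @param tree a \code{spanning_tree}
#' @return list of class \code{global_metrics}: \code{avg_strength},
#'   \code{max_bc}, \code{leaf_fraction}, \code{diameter_norm},
#'   \code{avg_eccentricity_norm}
#' @export
global_metrics <- function(tree) {
  n <- tree$n_nodes
  adj <- tree_adjlist(tree)
  nm <- nodal_metrics(tree)
  ecc <- vapply(seq_len(n),
                function(v) max(bfs_dist(adj, v, n)), integer(1))
  structure(list(
    avg_strength = mean(tree$edges$weight),
    max_bc = max(nm$bc),
    leaf_fraction = sum(nm$degree == 1L) / (n - 1),
    diameter_norm = max(ecc) / (n - 1),
    avg_eccentricity_norm = mean(ecc) / (n - 1)
  ), class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, ...) {
  cat("MST global metrics\n")
  cat(sprintf("  avg_strength          %.4f\n", x$avg_strength))
  cat(sprintf("  max_bc                %.4f\n", x$max_bc))
  cat(sprintf("  leaf_fraction         %.4f\n", x$leaf_fraction))
  cat(sprintf("  diameter_norm         %.4f\n", x$diameter_norm))
  cat(sprintf("  avg_eccentricity_norm %.4f\n", x$avg_eccentricity_norm))
  invisible(x)
}
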