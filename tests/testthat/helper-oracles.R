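# Independent oracle implementations used to cross-check the package.
# These deliberately take different computational routes from R/.

# --- FD oracle: explicit 4x4 transforms with analytic rigid inverse ---
# (the package route uses solve(); this one composes the inverse by hand)
fd_oracle <- function(params, head_radius = 80) {
  rotmat <- function(rx, ry, rz) {
    Rx <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx)))
    Ry <- rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry)))
    Rz <- rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
    Rz %*% Ry %*% Rx
  }
  make_T <- function(p) {
    T <- diag(4)
    T[1:3, 1:3] <- rotmat(p[4], p[5], p[6])
    T[1:3, 4] <- p[1:3]
    T
  }
  inv_rigid <- function(T) {
    Ti <- diag(4)
    R <- T[1:3, 1:3]
    Ti[1:3, 1:3] <- t(R)
    Ti[1:3, 4] <- -t(R) %*% T[1:3, 4]
    Ti
  }
  n <- nrow(params)
  fd <- numeric(n)
  for (t in 2:n) {
    M <- make_T(params[t, ]) %*% inv_rigid(make_T(params[t - 1, ])) - diag(4)
    A <- M[1:3, 1:3]
    b <- M[1:3, 4]
    fd[t] <- sqrt(head_radius^2 / 5 * sum(diag(t(A) %*% A)) + sum(b^2))
  }
  fd
}

# --- spanning-tree enumeration via Pruefer sequences ---
pruefer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (p in seq) degree[p] <- degree[p] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (i in seq_along(seq)) {
    leaf <- which(degree == 1L)[1]
    edges[i, ] <- c(leaf, seq[i])
    degree[leaf] <- degree[leaf] - 1L
    degree[seq[i]] <- degree[seq[i]] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  edges
}

all_labelled_trees <- function(n) {
  if (n == 2) return(list(matrix(c(1L, 2L), 1, 2)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  lapply(seq_len(nrow(seqs)), function(i) pruefer_decode(seqs[i, ], n))
}

# Maximum spanning-tree weight by exhaustive enumeration.
max_tree_weight_exhaustive <- function(W) {
  n <- nrow(W)
  best <- -Inf
  for (tree in all_labelled_trees(n)) {
    w <- sum(W[tree])
    if (w > best) best <- w
  }
  best
}

# --- betweenness oracle: enumerate the unique path of every pair ---
bc_path_enumeration <- function(edges, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  path_between <- function(s, t) {
    prev <- rep(NA_integer_, n)
    prev[s] <- s
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v == t) break
      for (w in adj[[v]]) if (is.na(prev[w])) {
        prev[w] <- v
        queue <- c(queue, w)
      }
    }
    path <- t
    while (path[1] != s) path <- c(prev[path[1]], path)
    path
  }
  counts <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    p <- path_between(s, t)
    interior <- setdiff(p, c(s, t))
    counts[interior] <- counts[interior] + 1
  }
  denom <- (n - 1) * (n - 2) / 2
  if (denom > 0) counts / denom else counts
}

# --- helpers to compare edge sets ---
edge_set <- function(edges) {
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  sort(paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2])))
}

# A spanning_tree object from a raw edge matrix (unit weights).
tree_from_edges <- function(edges, n) {
  adj <- matrix(FALSE, n, n)
  adj[edges] <- TRUE
  adj[edges[, 2:1, drop = FALSE]] <- TRUE
  structure(list(edges = data.frame(node_a = edges[, 1],
                                    node_b = edges[, 2], weight = 1),
                 n_nodes = n, roi_labels = as.character(seq_len(n)),
                 adjacency = adj),
            class = "spanning_tree")
}

# Direct DFT amplitude-spectrum oracle for ALFF.
alff_dft_oracle <- function(y, tr, band) {
  T_n <- length(y)
  freqs <- (seq_len(T_n) - 1) / (T_n * tr)
  k <- which(freqs >= band[1] & freqs <= band[2] &
               seq_len(T_n) >= 2 & seq_len(T_n) <= floor(T_n / 2 + 1))
  amps <- vapply(k, function(j) {
    f <- freqs[j]
    re <- sum(y * cos(-2 * pi * f * tr * (seq_len(T_n) - 1)))
    im <- sum(y * sin(-2 * pi * f * tr * (seq_len(T_n) - 1)))
    2 / T_n * sqrt(re^2 + im^2)
  }, numeric(1))
  mean(amps)
}
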