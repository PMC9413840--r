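# Cluster-based nonparametric permutation test on 3D maps
# (cluster-mass statistic, FWE correction by the max-cluster null).

# Label connected components of a logical 3D array under 26-connectivity.
label_clusters_26 <- function(mask3d) {
  dims <- dim(mask3d)
  labels <- array(0L, dims)
  idx <- which(mask3d, arr.ind = TRUE)
  if (!nrow(idx)) return(labels)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  current <- 0L
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    if (labels[v[1], v[2], v[3]] != 0L) next
    current <- current + 1L
    queue <- matrix(v, ncol = 3)
    labels[v[1], v[2], v[3]] <- current
    while (nrow(queue)) {
      p <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      nb <- sweep(offsets, 2, p, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      inmask <- mask3d[nb] & labels[nb] == 0L
      if (any(inmask)) {
        nb <- nb[inmask, , drop = FALSE]
        labels[nb] <- current
        queue <- rbind(queue, nb)
      }
    }
  }
  labels
}

# Vectorised two-sample pooled-variance t per voxel.
# Y: subjects x voxels matrix; g: logical group-1 indicator.
voxel_t <- function(Y, g) {
  n1 <- sum(g); n2 <- sum(!g)
  m1 <- colMeans(Y[g, , drop = FALSE])
  m2 <- colMeans(Y[!g, , drop = FALSE])
  v1 <- colSums(sweep(Y[g, , drop = FALSE], 2, m1)^2)
  v2 <- colSums(sweep(Y[!g, , drop = FALSE], 2, m2)^2)
  sp2 <- (v1 + v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[se == 0] <- 0
  t
}

# Cluster masses of a t-map at a threshold; positive and negative
# suprathreshold voxels are clustered separately (sign-consistent
# clusters), statistic = sum of |t| over the cluster.
cluster_masses <- function(tmap, tcrit, mask) {
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- array(FALSE, dim(tmap))
    supra[mask] <- sgn * tmap[mask] > tcrit
    lab <- label_clusters_26(supra)
    k <- max(lab)
    if (k > 0) {
      for (ci in seq_len(k)) {
        vox <- lab == ci
        out[[length(out) + 1]] <- list(
          mass = sum(abs(tmap[vox])), size = sum(vox), sign = sgn,
          voxels = which(vox, arr.ind = TRUE))
      }
    }
  }
  out
}

#' Cluster-based permutation test for group differences in 3D maps
#'
#' Covariates of no interest are regressed out of every voxel once
#' (Freedman-Lane residualisation under the reduced, covariate-only
#' model); a pooled-variance two-sample t is computed per voxel;
#' suprathreshold voxels (|t| above the two-sided cluster-defining
#' quantile) are grouped under 26-connectivity into sign-consistent
#' clusters scored by cluster mass (sum of |t|). The familywise-error
#' null is the maximum cluster mass over group-label permutations, and
#' each observed cluster's FWE p-value is the add-one tail proportion.
#'
#' @param maps list of per-subject 3D arrays on a common grid
#' @param groups two-level group labels, one per subject
#' @param covariates optional subjects x p matrix (age, education,
#'   mean FD, ...)
#' @param mask optional logical 3D array restricting analysis
#' @param cdt_p two-sided cluster-defining threshold (default 0.001)
#' @param n_perm number of permutations (default 10000)
#' @param alpha_fwe FWE significance threshold (default 0.05)
#' @param seed integer seed
#' @return list: \code{clusters} (data frame: mass, size, sign, p_fwe,
#'   significant), \code{t_map}, \code{t_threshold},
#'   \code{null_max_mass}, \code{n_permutations}
#' @export
cluster_perm_test <- function(maps, groups, covariates = NULL, mask = NULL,
                              cdt_p = 0.001, n_perm = 10000,
                              alpha_fwe = 0.05, seed = 1L) {
  dims <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) identical(dim(m), dims), logical(1))))
    stop_invalid("all maps must share the same grid")
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop_invalid("exactly two groups required")
  if (min(table(groups)) < 3) stop_invalid("need >= 3 subjects per group")
  if (is.null(mask)) mask <- array(TRUE, dims)
  n_sub <- length(maps)
  Y <- do.call(rbind, lapply(maps, function(m) m[mask]))  # subjects x voxels
  if (!is.null(covariates)) {
    X0 <- cbind(1, as.matrix(covariates))
    Y <- qr.resid(qr(X0), Y)
  }
  g <- groups == levels(groups)[1]
  df <- n_sub - 2
  tcrit <- stats::qt(1 - cdt_p / 2, df)
  to_map <- function(tv) {
    m <- array(0, dims)
    m[mask] <- tv
    m
  }
  t_obs <- to_map(voxel_t(Y, g))
  obs_clusters <- cluster_masses(t_obs, tcrit, mask)

  set.seed(seed)
  null_max <- vapply(seq_len(n_perm), function(b) {
    gp <- sample(g)
    tm <- to_map(voxel_t(Y, gp))
    cl <- cluster_masses(tm, tcrit, mask)
    if (length(cl)) max(vapply(cl, `[[`, numeric(1), "mass")) else 0
  }, numeric(1))

  if (length(obs_clusters)) {
    tab <- do.call(rbind, lapply(obs_clusters, function(cl) {
      p <- (1 + sum(null_max >= cl$mass)) / (n_perm + 1)
      data.frame(mass = cl$mass, size = cl$size, sign = cl$sign, p_fwe = p)
    }))
    tab$significant <- tab$p_fwe < alpha_fwe
    tab <- tab[order(tab$p_fwe, -tab$mass), ]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(mass = numeric(0), size = integer(0),
                      sign = numeric(0), p_fwe = numeric(0),
                      significant = logical(0))
  }
  list(clusters = tab, t_map = t_obs, t_threshold = tcrit,
       null_max_mass = null_max, n_permutations = n_perm)
}
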