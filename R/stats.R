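# Inferential layer: responder classification, outlier removal,
# permutation tests, FDR, Kendall-tau motion sensitivity, and the
# minimal-detectable-effect computation.

#' Classify treatment response from CAPS scores
#'
#' Responder if the total CAPS score was reduced by at least 30% (the
#' boundary is inclusive).
#'
#' @param caps_pre baseline total score (> 0)
#' @param caps_post post-treatment total score
#' @param threshold fractional reduction defining response (default 0.30)
#' @return logical (vectorised): \code{TRUE} = responder
#' @export
classify_response <- function(caps_pre, caps_post, threshold = 0.30) {
  if (any(caps_pre <= 0)) stop_invalid("caps_pre must be positive")
  (caps_pre - caps_post) / caps_pre >= threshold
}

#' Remove outliers beyond 3 x IQR
#'
#' Single-pass rule: a value is removed when it falls strictly below
#' Q1 - 3 IQR or strictly above Q3 + 3 IQR, with quartiles by linear
#' interpolation.
#'
#' @param values numeric vector (length >= 4)
#' @return list: \code{retained}, \code{removed_indices}
#' @export
remove_outliers_3iqr <- function(values) {
  if (length(values) < 4) stop_invalid("need at least 4 values")
  q <- quantile_li(values, c(0.25, 0.75))
  iqr <- q[2] - q[1]
  out <- values < q[1] - 3 * iqr | values > q[2] + 3 * iqr
  list(retained = values[!out], removed_indices = which(out))
}

perm_statistics <- list(
  mean_diff = function(x, y) mean(x) - mean(y),
  median_diff = function(x, y) stats::median(x) - stats::median(y),
  t = function(x, y) {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  }
)

#' Two-group permutation test
#'
#' Group labels are permuted uniformly; the two-sided p-value uses the
#' add-one estimator p = (1 + #{|stat*| >= |stat|}) / (n_perm + 1), so
#' p >= 1/(n_perm + 1) and p = 0 is impossible.
#'
#' @param x,y numeric samples (each length >= 2)
#' @param n_perm number of label permutations (default 10000)
#' @param seed integer seed
#' @param statistic \code{"mean_diff"} (default), \code{"median_diff"} or
#'   pooled-variance \code{"t"}
#' @return list of class \code{permutation_result}: \code{observed_stat},
#'   \code{p_value}, \code{n_permutations}, \code{seed},
#'   \code{statistic_name}
#' @export
perm_test_two_group <- function(x, y, n_perm = 10000, seed = 1L,
                                statistic = "mean_diff") {
  if (length(x) < 2 || length(y) < 2)
    stop_invalid("each group needs at least 2 observations")
  stat_fun <- perm_statistics[[statistic]]
  if (is.null(stat_fun)) stop_invalid("unknown statistic: ", statistic)
  obs <- stat_fun(x, y)
  pooled <- c(x, y)
  nx <- length(x); n <- length(pooled)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, nx)
    stat_fun(pooled[idx], pooled[-idx])
  }, numeric(1))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  structure(list(observed_stat = obs, p_value = p,
                 n_permutations = n_perm, seed = seed,
                 statistic_name = statistic),
            class = "permutation_result")
}

# Two-way (group x metric) F statistics on a long-format table.
# Sequential sums of squares: group, then metric, then interaction.
# .lm.fit keeps this cheap inside permutation loops.
two_way_f <- function(value, group, metric) {
  Xg <- stats::model.matrix(~group)
  Xm <- stats::model.matrix(~group + metric)
  Xi <- stats::model.matrix(~group * metric)
  rss <- function(X) sum(stats::.lm.fit(X, value)$residuals^2)
  rss0 <- sum((value - mean(value))^2)
  rss_g <- rss(Xg); rss_m <- rss(Xm); rss_i <- rss(Xi)
  df_err <- length(value) - ncol(Xi)
  mse <- rss_i / df_err
  safe_f <- function(num_ss, num_df) {
    if (mse <= 0 || num_df <= 0) return(0)
    (num_ss / num_df) / mse
  }
  dg <- length(levels(group)) - 1
  dm <- length(levels(metric)) - 1
  c(group = safe_f(rss0 - rss_g, dg),
    metric = safe_f(rss_g - rss_m, dm),
    interaction = safe_f(rss_m - rss_i, dg * dm))
}

#' Omnibus group-by-metric permutation test
#'
#' Each metric column is z-standardised across subjects, the table is
#' melted to long format, and F-type statistics for the group main
#' effect, metric main effect and interaction are referred to permutation
#' nulls. Group labels are permuted at the subject level for the group
#' and interaction effects; for the metric main effect, Freedman-Lane
#' residuals of the reduced (group-only) model are permuted across
#' metrics within each subject. All three p-values use the add-one
#' estimator.
#'
#' @param table subjects x metrics numeric matrix or data frame
#' @param groups subject group labels (2 levels)
#' @param n_perm permutations (default 10000)
#' @param seed integer seed
#' @return list: \code{p_group}, \code{p_metric}, \code{p_interaction},
#'   \code{observed} (the three F statistics), \code{n_permutations}
#' @export
omnibus_group_by_metric <- function(table, groups, n_perm = 10000,
                                    seed = 1L) {
  m <- as.matrix(table)
  if (ncol(m) < 2) stop_invalid("need at least 2 metrics")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop_invalid("constant metric column: ",
                 paste(colnames(m)[sds == 0], collapse = ", "))
  z <- scale(m)
  n_sub <- nrow(z); n_met <- ncol(z)
  group <- factor(rep(groups, times = n_met))
  metric <- factor(rep(seq_len(n_met), each = n_sub))
  value <- as.numeric(z)
  obs <- two_way_f(value, group, metric)

  set.seed(seed)
  count <- c(group = 0, metric = 0, interaction = 0)
  # Freedman-Lane residuals for the metric effect: remove the group-only
  # fit, then permute within subject across metrics
  fit_g <- stats::lm(value ~ group)
  res_g <- matrix(stats::resid(fit_g), nrow = n_sub)
  fitted_g <- matrix(stats::fitted(fit_g), nrow = n_sub)
  for (b in seq_len(n_perm)) {
    g_perm <- factor(rep(sample(groups), times = n_met))
    f_lab <- two_way_f(value, g_perm, metric)
    res_p <- t(apply(res_g, 1, sample))
    v_met <- as.numeric(fitted_g + res_p)
    f_met <- two_way_f(v_met, group, metric)["metric"]
    count["group"] <- count["group"] + (f_lab["group"] >= obs["group"])
    count["interaction"] <- count["interaction"] +
      (f_lab["interaction"] >= obs["interaction"])
    count["metric"] <- count["metric"] + (f_met >= obs["metric"])
  }
  p <- (1 + count) / (n_perm + 1)
  list(p_group = unname(p["group"]), p_metric = unname(p["metric"]),
       p_interaction = unname(p["interaction"]),
       observed = obs, n_permutations = n_perm)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up procedure: adjusted p for the k-th smallest p-value is
#' min over j >= k of m p_(j) / j, capped at 1; a hypothesis is rejected
#' when its adjusted p is at most \code{alpha}.
#'
#' @param p_values numeric vector in [0, 1]
#' @param alpha FDR level (default 0.05)
#' @return list: \code{rejected} (logical), \code{adjusted} (numeric)
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_invalid("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(rejected = !is.na(adj) & adj <= alpha, adjusted = adj)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected tau-b with an exact p-value for small samples without
#' ties and the normal approximation otherwise.
#'
#' @param x,y numeric vectors (length >= 3)
#' @return list: \code{tau}, \code{p_value}
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_invalid("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_invalid("undefined correlation: constant input")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall",
                    exact = length(x) <= 10 && !anyDuplicated(x) &&
                      !anyDuplicated(y)))
  list(tau = unname(ct$estimate), p_value = ct$p.value)
}

# Vectorised tau + normal-approximation p for one x against many columns.
# No tie correction (continuous inputs); p from
# z = 3 tau sqrt(n(n-1)) / sqrt(2(2n+5)).
kendall_tau_many <- function(x, ymat) {
  n <- length(x)
  tau <- suppressWarnings(as.numeric(stats::cor(x, ymat, method = "kendall")))
  z <- 3 * tau * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(tau = tau, p_value = p)
}

#' Residual-motion sensitivity suite
#'
#' Screens the analysis outputs for residual head-motion confounding:
#' (1) Kendall tau between mean FD and every edge's connectivity
#' strength, FDR-corrected, summarised as the percentage of significant
#' edges; (2) the distribution of those edgewise correlations and its
#' mean; (3) tau and uncorrected p between mean FD and each global
#' metric; (4) per-node tau for degree and betweenness centrality,
#' FDR-corrected. Edges or nodes with constant values across subjects are
#' reported as undefined rather than raising.
#'
#' @param matrices list of per-subject \code{connectivity_matrix} objects
#' @param nodal list of per-subject \code{\link{nodal_metrics}} tables
#' @param globals list of per-subject \code{\link{global_metrics}}
#' @param mean_fd per-subject mean FD
#' @param alpha significance level (default 0.05)
#' @return list: \code{edge_pct_significant}, \code{edge_tau_mean},
#'   \code{edge_tau} (all edgewise correlations), \code{n_edges_undefined},
#'   \code{global} (data frame metric/tau/p),
#'   \code{nodal} (data frame node/metric/tau/p/p_fdr),
#'   \code{leaf_fraction_gated} (whether leaf fraction correlates with FD
#'   at \code{alpha} and should be excluded from group testing)
#' @export
motion_sensitivity_suite <- function(matrices, nodal, globals, mean_fd,
                                     alpha = 0.05) {
  n_sub <- length(mean_fd)
  if (length(matrices) != n_sub || length(nodal) != n_sub ||
      length(globals) != n_sub)
    stop_invalid("subject counts differ across inputs")
  if (n_sub < 10) stop_invalid("need at least 10 subjects")

  ut <- upper.tri(matrices[[1]]$weights)
  edge_mat <- vapply(matrices, function(m) m$weights[ut],
                     numeric(sum(ut)))           # edges x subjects
  edge_sd <- apply(edge_mat, 1, stats::sd)
  defined <- edge_sd > 0
  edge_tau <- rep(NA_real_, length(edge_sd))
  if (any(defined)) {
    et <- kendall_tau_many(mean_fd, t(edge_mat[defined, , drop = FALSE]))
    fdr <- fdr_bh(et$p_value, alpha)
    edge_tau[defined] <- et$tau
    edge_pct <- 100 * sum(fdr$rejected) / sum(defined)
    edge_mean <- mean(et$tau)
  } else {
    # every edge constant across subjects: correlations undefined, reported
    edge_pct <- NA_real_
    edge_mean <- NA_real_
  }

  gnames <- c("avg_strength", "max_bc", "leaf_fraction",
              "diameter_norm", "avg_eccentricity_norm")
  gtab <- do.call(rbind, lapply(gnames, function(g) {
    v <- vapply(globals, `[[`, numeric(1), g)
    if (stats::sd(v) == 0)
      return(data.frame(metric = g, tau = NA_real_, p_value = NA_real_))
    kt <- kendall_tau(mean_fd, v)
    data.frame(metric = g, tau = kt$tau, p_value = kt$p_value)
  }))

  ntab <- do.call(rbind, lapply(c("degree", "bc"), function(metric) {
    vals <- vapply(nodal, `[[`, numeric(nrow(nodal[[1]])), metric)
    sds <- apply(vals, 1, stats::sd)
    def <- sds > 0
    out <- data.frame(node = seq_len(nrow(vals)), metric = metric,
                      tau = NA_real_, p_value = NA_real_)
    if (any(def)) {
      kt <- kendall_tau_many(mean_fd, t(vals[def, , drop = FALSE]))
      out$tau[def] <- kt$tau
      out$p_value[def] <- kt$p_value
    }
    out
  }))
  ntab$p_fdr <- NA_real_
  for (metric in c("degree", "bc")) {
    sel <- ntab$metric == metric & !is.na(ntab$p_value)
    ntab$p_fdr[sel] <- fdr_bh(ntab$p_value[sel], alpha)$adjusted
  }

  lf_p <- gtab$p_value[gtab$metric == "leaf_fraction"]
  list(edge_pct_significant = edge_pct,
       edge_tau_mean = edge_mean,
       edge_tau = edge_tau,
       n_edges_undefined = sum(!defined),
       global = gtab,
       nodal = ntab,
       leaf_fraction_gated = is.finite(lf_p) && lf_p < alpha)
}

#' Minimal detectable effect size
#'
#' Smallest Cohen's d at which a two-sided two-sample t-test reaches the
#' target power, from the noncentral-t distribution with
#' df = n1 + n2 - 2 and noncentrality d sqrt(n1 n2 / (n1 + n2)); solved
#' by bisection to 1e-4.
#'
#' @param n1,n2 group sizes (>= 2)
#' @param alpha two-sided significance level
#' @param power target power in (0, 1)
#' @return Cohen's d
#' @export
min_detectable_effect <- function(n1, n2, alpha = 0.05, power = 0.80) {
  if (n1 < 2 || n2 < 2) stop_invalid("group sizes must be >= 2")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop_invalid("alpha and power must lie in (0, 1)")
  df <- n1 + n2 - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  pow <- function(d) {
    ncp <- d * sqrt(n1 * n2 / (n1 + n2))
    stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tcrit, df, ncp = ncp)
  }
  lo <- 0; hi <- 1
  while (pow(hi) < power) {
    hi <- hi * 2
    if (hi > 100) stop_invalid("target power unattainable")
  }
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (pow(mid) >= power) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
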