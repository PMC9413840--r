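# Responder classification, outlier removal, permutation tests, FDR,
# Kendall tau, the sensitivity suite, and power.

test_that("responder classification is inclusive at the 30% boundary", {
  expect_true(classify_response(100, 70))    # exactly 30%
  expect_false(classify_response(100, 71))
  expect_true(classify_response(70.33, 32))  # 54.5% reduction
  expect_error(classify_response(0, 10), "positive")
})

test_that("motion summary metrics use linear-interpolation quantiles", {
  m <- motion_summary_metrics(c(0.1, 0.1, 0.3, 0.1))
  expect_equal(m$median_fd, 0.1)
  expect_equal(m$max_fd, 0.3)
  expect_equal(m$n_outliers, 1L)

  expect_equal(motion_summary_metrics(rep(0.05, 10))$iqr_fd, 0)
  expect_equal(motion_summary_metrics(c(0.1, 0.2, 0.3, 0.4))$iqr_fd, 0.15)
})

test_that("3*IQR outlier removal follows the stated convention", {
  r <- remove_outliers_3iqr(c(1, 2, 3, 4, 100))
  expect_equal(r$removed_indices, 5L)
  expect_equal(r$retained, c(1, 2, 3, 4))

  expect_length(remove_outliers_3iqr(rep(5, 6))$removed_indices, 0)
  set.seed(1)
  expect_length(remove_outliers_3iqr(rnorm(100))$removed_indices, 0)
  expect_error(remove_outliers_3iqr(c(1, 2, 3)), "4 values")
})

test_that("permutation test: degenerate and extreme-separation cases", {
  x <- rnorm(10)
  r <- perm_test_two_group(x, x, n_perm = 499, seed = 2)
  expect_equal(r$observed_stat, 0)
  expect_equal(r$p_value, 1)

  r2 <- perm_test_two_group(rep(0, 20), rep(10, 20), n_perm = 10000, seed = 3)
  expect_equal(r2$p_value, 1 / 10001)
  expect_gte(r2$p_value, 1 / (r2$n_permutations + 1))

  # statistic options
  r3 <- perm_test_two_group(rnorm(8), rnorm(8), n_perm = 99, seed = 4,
                            statistic = "median_diff")
  expect_equal(r3$statistic_name, "median_diff")
  expect_error(perm_test_two_group(1, rnorm(5)), "at least 2")
  expect_error(perm_test_two_group(rnorm(5), rnorm(5), statistic = "zzz"),
               "unknown")
})

test_that("permutation p-values are calibrated and uniform under the null", {
  set.seed(99)
  pvals <- vapply(1:400, function(i) {
    perm_test_two_group(rnorm(15), rnorm(15), n_perm = 199,
                        seed = 10000 + i)$p_value
  }, numeric(1))
  rate <- mean(pvals <= 0.05)
  band <- 1.96 * sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(rate - 0.05), band + 1e-9)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("vectorised many-outcome test agrees with the scalar test", {
  set.seed(5)
  X <- matrix(rnorm(30 * 4), 30)
  X[1:15, 2] <- X[1:15, 2] + 3
  groups <- rep(c("a", "b"), each = 15)
  many <- perm_test_many(X, groups, n_perm = 1999, seed = 6)
  for (j in 1:4) {
    single <- perm_test_two_group(X[1:15, j], X[16:30, j],
                                  n_perm = 1999, seed = 60 + j)
    expect_equal(many$observed[j], single$observed_stat)
    expect_lt(abs(many$p_value[j] - single$p_value), 0.05)
  }
  expect_lt(many$p_value[2], 0.01)
})

test_that("ties at the observed statistic do not produce spurious small p-values", {
  # a near-constant outcome: one deviating subject only
  X <- matrix(0.3939, 46, 1)
  X[8, 1] <- 0.422
  groups <- rep(c("a", "b"), c(24, 22))
  many <- perm_test_many(X, groups, n_perm = 999, seed = 1)
  expect_gt(many$p_value[1], 0.3)
})

test_that("BH-FDR reproduces the hand-computed step-up and its bounds", {
  r <- fdr_bh(c(0.01, 0.02, 0.04), alpha = 0.05)
  expect_equal(r$rejected, rep(TRUE, 3))
  expect_equal(r$adjusted, c(0.03, 0.03, 0.04))

  r1 <- fdr_bh(0.04)
  expect_true(r1$rejected)
  expect_equal(r1$adjusted, 0.04)

  rall <- fdr_bh(rep(1, 5))
  expect_false(any(rall$rejected))
  expect_equal(rall$adjusted, rep(1, 5))

  expect_error(fdr_bh(c(0.1, 1.2)), "0, 1")

  # Bonferroni rejections are a subset of BH rejections
  set.seed(7)
  for (i in 1:20) {
    p <- runif(20)^2
    bh <- fdr_bh(p, 0.05)$rejected
    bonf <- p <= 0.05 / length(p)
    expect_true(all(bh[bonf]))
  }
})

test_that("Kendall tau matches pair enumeration and handles errors", {
  expect_equal(kendall_tau(1:10, (1:10)^2)$tau, 1)
  expect_equal(kendall_tau(1:10, rev(1:10))$tau, -1)
  r <- kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$tau, 4 / 6, tolerance = 1e-12)
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")

  # tau-b equals exhaustive concordant/discordant counting for n <= 10
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    x <- rnorm(n); y <- rnorm(n)
    conc <- 0; disc <- 0
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      s <- sign(x[a] - x[b]) * sign(y[a] - y[b])
      if (s > 0) conc <- conc + 1 else disc <- disc + 1
    }
    expect_equal(kendall_tau(x, y)$tau, (conc - disc) / choose(n, 2),
                 tolerance = 1e-12)
  }
})

test_that("omnibus test is calibrated under the null and degenerate-safe", {
  set.seed(21)
  reject <- matrix(NA, 120, 3)
  for (i in 1:120) {
    tab <- matrix(rnorm(24 * 3), 24)
    groups <- rep(c("r", "n"), each = 12)
    o <- omnibus_group_by_metric(tab, groups, n_perm = 99, seed = 500 + i)
    reject[i, ] <- c(o$p_group, o$p_metric, o$p_interaction) <= 0.05
  }
  band <- 1.96 * sqrt(0.05 * 0.95 / 120) + 0.02
  for (j in 1:3) expect_lt(abs(mean(reject[, j]) - 0.05), band)

  expect_error(omnibus_group_by_metric(cbind(rnorm(10), rep(1, 10)),
                                       rep(c("a", "b"), 5), 10, 1),
               "constant")
  expect_error(omnibus_group_by_metric(matrix(rnorm(10), 10, 1),
                                       rep(c("a", "b"), 5), 10, 1),
               "2 metrics")
})

test_that("omnibus detects a planted group-by-metric interaction", {
  set.seed(22)
  detected <- vapply(1:10, function(i) {
    tab <- matrix(rnorm(46 * 4), 46)
    groups <- rep(c("r", "n"), c(24, 22))
    tab[groups == "r", 2] <- tab[groups == "r", 2] + 3
    o <- omnibus_group_by_metric(tab, groups, n_perm = 999, seed = 700 + i)
    o$p_interaction < 0.01
  }, logical(1))
  expect_gte(mean(detected), 0.9)
})

test_that("sensitivity suite: null, planted confound, and degenerate inputs", {
  set.seed(31)
  n_sub <- 46; n_nodes <- 15
  make_inputs <- function(confound = 0, constant = FALSE) {
    fd <- runif(n_sub, 0.02, 0.3)
    mats <- lapply(seq_len(n_sub), function(i) {
      if (constant) {
        # one subject duplicated: identical weights for everyone
        W <- outer(1:n_nodes, 1:n_nodes, function(a, b) 0.6^abs(a - b))
      } else {
        v <- matrix(rnorm(n_nodes * 40), n_nodes)
        W <- cor(t(v)) + confound * fd[i]
        W <- pmin(W, 1); diag(W) <- 1
      }
      structure(list(weights = W, roi_labels = as.character(1:n_nodes),
                     n_nodes = n_nodes), class = "connectivity_matrix")
    })
    trees <- lapply(seq_len(n_sub), function(i)
      tree_from_edges(random_spanning_tree(n_nodes,
                                           seed = if (constant) 1 else i), n_nodes))
    nodals <- lapply(trees, nodal_metrics)
    globals <- lapply(trees, function(tr) {
      g <- global_metrics(tr)
      # perturb avg_strength so global taus are defined
      g$avg_strength <- g$avg_strength + rnorm(1, sd = 0.01)
      g
    })
    list(mats = mats, nodals = nodals, globals = globals, fd = fd)
  }

  null_in <- make_inputs()
  s0 <- motion_sensitivity_suite(null_in$mats, null_in$nodals,
                                 null_in$globals, null_in$fd)
  expect_lt(s0$edge_pct_significant, 5)
  expect_lt(abs(s0$edge_tau_mean), 0.05)
  expect_equal(nrow(s0$global), 5)

  conf_in <- make_inputs(confound = 3)
  s1 <- motion_sensitivity_suite(conf_in$mats, conf_in$nodals,
                                 conf_in$globals, conf_in$fd)
  expect_gt(s1$edge_pct_significant, 50)

  const_in <- make_inputs(constant = TRUE)
  s2 <- motion_sensitivity_suite(const_in$mats, const_in$nodals,
                                 const_in$globals, const_in$fd)
  expect_gt(s2$n_edges_undefined, 0)   # reported, not raised

  expect_error(motion_sensitivity_suite(null_in$mats[1:5], null_in$nodals,
                                        null_in$globals, null_in$fd),
               "differ")
})

test_that("minimal detectable effect matches the noncentral-t solution", {
  d <- min_detectable_effect(24, 22, 0.05, 0.80)
  # the study's printed 0.84 is the truncation of the exact solution
  expect_equal(floor(d * 100) / 100, 0.84)
  pow <- function(d, n1 = 24, n2 = 22) {
    df <- n1 + n2 - 2
    tc <- qt(0.975, df)
    ncp <- d * sqrt(n1 * n2 / (n1 + n2))
    pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
  }
  expect_lt(pow(0.84), 0.80)
  expect_gt(pow(0.85), 0.80)
  expect_gte(pow(d), 0.80 - 1e-4)

  # large-sample normal-approximation limit at 50% power
  d50 <- min_detectable_effect(1000, 1000, 0.05, 0.5)
  expect_equal(d50, qnorm(0.975) * sqrt(2 / 1000), tolerance = 0.01)

  # doubling both group sizes strictly decreases d
  expect_lt(min_detectable_effect(48, 44), min_detectable_effect(24, 22))
  expect_error(min_detectable_effect(1, 5), ">= 2")
})
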