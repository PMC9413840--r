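# Framewise displacement, censoring, the 36-parameter nuisance model,
# detrending and band-pass filtering.

test_that("FD is zero for a still head and equals pure translations", {
  expect_equal(compute_fd_jenkinson(matrix(0, 5, 6)), rep(0, 5))

  p <- matrix(0, 2, 6)
  p[2, 1] <- 1.0
  expect_equal(compute_fd_jenkinson(p)[2], 1.0)

  # combined translation in two axes
  p2 <- matrix(0, 2, 6)
  p2[2, 1:2] <- c(3, 4)
  expect_equal(compute_fd_jenkinson(p2)[2], 5.0)
})

test_that("FD of a pure z-rotation matches the closed form", {
  theta <- 0.01
  p <- matrix(0, 3, 6)
  p[2, 6] <- theta
  fd <- compute_fd_jenkinson(p, head_radius = 80)
  expect_equal(fd[2], 80 * sqrt(4 * (1 - cos(theta)) / 5), tolerance = 1e-12)
  expect_equal(round(fd[2], 4), 0.5060)
  # frame 3 has the same parameters as frame 2: no displacement
  p[3, 6] <- theta
  expect_equal(compute_fd_jenkinson(p, 80)[3], 0)
})

test_that("FD equals the brute-force 4x4 oracle to 1e-10 on random tables", {
  set.seed(31)
  for (i in 1:20) {
    p <- cbind(matrix(rnorm(30 * 3, sd = 0.5), 30),
               matrix(rnorm(30 * 3, sd = 0.01), 30))
    expect_equal(compute_fd_jenkinson(p), fd_oracle(p), tolerance = 1e-10)
  }
})

test_that("FD is invariant to a constant translation offset and honors options", {
  set.seed(8)
  # translation-only motion: only the frame-to-frame change matters
  p <- cbind(matrix(rnorm(60, sd = 0.3), 20), matrix(0, 20, 3))
  shifted <- p
  shifted[, 1:3] <- shifted[, 1:3] + rep(c(5, -2, 11), each = 20)
  expect_equal(compute_fd_jenkinson(p), compute_fd_jenkinson(shifted),
               tolerance = 1e-10)
  # with a constant rotation shared by all volumes the offset still cancels
  p2 <- p; p2[, 6] <- 0.05
  s2 <- shifted; s2[, 6] <- 0.05
  expect_equal(compute_fd_jenkinson(p2), compute_fd_jenkinson(s2),
               tolerance = 1e-10)
  p <- cbind(p[, 1:3], matrix(rnorm(60, sd = 0.01), 20))

  # rotations-first dialect reproduces the same series
  expect_equal(compute_fd_jenkinson(p[, c(4:6, 1:3)], rotations_first = TRUE),
               compute_fd_jenkinson(p), tolerance = 1e-12)

  # moving the rotation centre changes FD for rotations but not translations
  prot <- matrix(0, 2, 6); prot[2, 6] <- 0.02
  expect_false(isTRUE(all.equal(
    compute_fd_jenkinson(prot, origin = c(50, 0, 0)),
    compute_fd_jenkinson(prot))))
  expect_error(compute_fd_jenkinson(rbind(rep(0, 6), c(NA, rep(0, 5)))),
               "volume 2")
})

test_that("spike flagging uses a strict threshold", {
  expect_equal(flag_spikes(c(0, 0.25, 0.1)), c(FALSE, TRUE, FALSE))
  expect_false(flag_spikes(0.2)[1])       # boundary: 0.2 is not flagged
  expect_equal(sum(flag_spikes(rep(0.19, 100))), 0)
  expect_error(flag_spikes(c(0.1), threshold = -1), "non-negative")
})

test_that("spike regressors zero out censored volumes after regression", {
  expect_equal(build_spike_regressors(c(FALSE, TRUE, FALSE)),
               matrix(c(0, 1, 0), ncol = 1),
               ignore_attr = TRUE)
  expect_equal(ncol(build_spike_regressors(rep(FALSE, 5))), 0)

  set.seed(2)
  T_n <- 60
  flags <- rep(FALSE, T_n); flags[c(10, 25, 40)] <- TRUE
  X <- cbind(1, rnorm(T_n), build_spike_regressors(flags))
  y <- rnorm(T_n)
  res <- regress_nuisance(y, X)
  expect_equal(res[flags], rep(0, 3), tolerance = 1e-10)
  expect_gt(max(abs(res[!flags])), 0)
})

test_that("retention rule is strict at the 4-minute boundary", {
  expect_true(retention_decision(310, 1.6))   # 496 s
  expect_true(retention_decision(150, 1.6))   # exactly 240 s: kept
  expect_false(retention_decision(149, 1.6))  # 238.4 s: excluded
})

test_that("the nuisance design has exactly 36 base columns and a 24-column motion block", {
  set.seed(5)
  T_n <- 50
  mp <- matrix(rnorm(T_n * 6, sd = 0.1), T_n)
  tissue <- data.frame(GM = rnorm(T_n), WM = rnorm(T_n), CSF = rnorm(T_n))
  flags <- rep(FALSE, T_n); flags[7] <- TRUE
  d <- build_design_36p(mp, tissue, include_trend = FALSE,
                        spike_regressors = build_spike_regressors(flags))
  expect_equal(d$n_base_params, 36L)
  expect_equal(ncol(d$columns), 36 + 1 + 1)   # base + intercept + 1 spike
  expect_equal(d$spike_columns, 1L)
  expect_equal(ncol(friston24(mp)), 24L)

  # trend column adds exactly one
  d2 <- build_design_36p(mp, tissue, include_trend = TRUE)
  expect_equal(ncol(d2$columns), 36 + 2)

  # constant tissue series has an all-zero difference column
  tissue$WM <- 3
  d3 <- build_design_36p(mp, tissue)
  expect_equal(unname(d3$columns[, "WM_diff"]), rep(0, T_n))

  expect_error(build_design_36p(mp, tissue[-1, ]), "does not match")
})

test_that("nuisance regression residuals are orthogonal to the design", {
  set.seed(6)
  T_n <- 120
  mp <- matrix(rnorm(T_n * 6, sd = 0.1), T_n)
  tissue <- data.frame(GM = rnorm(T_n), WM = rnorm(T_n), CSF = rnorm(T_n))
  d <- build_design_36p(mp, tissue)
  y <- rnorm(T_n)
  res <- regress_nuisance(y, d)
  dots <- abs(t(d$columns) %*% res)
  norms <- sqrt(colSums(d$columns^2)) * sqrt(sum(res^2))
  expect_true(all(dots <= 1e-8 * pmax(norms, 1)))

  # a series equal to a design column is annihilated
  res2 <- regress_nuisance(d$columns[, 3], d)
  expect_equal(res2, rep(0, T_n), tolerance = 1e-8)

  # intercept-only design demeans
  res3 <- regress_nuisance(y, matrix(1, T_n, 1))
  expect_equal(res3, y - mean(y))

  # duplicated columns (rank deficiency) are handled
  Xdup <- cbind(d$columns, d$columns[, 1:5])
  expect_equal(regress_nuisance(y, Xdup), res, tolerance = 1e-8)

  expect_error(regress_nuisance(rnorm(10), diag(10)), "degenerate")
})

test_that("linear detrending is exact, idempotent and preserves oscillations", {
  t <- seq_len(310)
  expect_equal(detrend_linear(2 * t + 5), rep(0, 310), tolerance = 1e-9)
  y <- sin(2 * pi * 0.05 * t * 1.6)
  once <- detrend_linear(y)
  expect_equal(detrend_linear(once), once, tolerance = 1e-10)
  amp <- function(v) sqrt(2 * mean(v^2))
  expect_lt(abs(amp(once) - amp(y)) / amp(y), 0.01)
})

test_that("band-pass keeps the passband, kills the stopband and DC", {
  t <- (0:309) * 1.6
  # amplitude via projection onto the quadrature pair at the frequency
  amp_at <- function(v, f) {
    s <- sin(2 * pi * f * t); c_ <- cos(2 * pi * f * t)
    2 * sqrt(mean(v * s)^2 + mean(v * c_)^2)
  }
  y05 <- sin(2 * pi * 0.05 * t)
  out05 <- bandpass(y05, 1.6)
  expect_lt(abs(amp_at(out05, 0.05) - 1), 0.05)

  y20 <- sin(2 * pi * 0.2 * t)
  expect_lt(amp_at(bandpass(y20, 1.6), 0.2), 0.10)

  expect_lt(max(abs(bandpass(rep(4, 310), 1.6))), 0.05)
  expect_error(bandpass(y05, 1.6, low_hz = 0.01, high_hz = 0.4), "Nyquist")

  # matrix input filters per column
  m <- cbind(y05, y20)
  bm <- bandpass(m, 1.6)
  expect_equal(bm[, 1], bandpass(y05, 1.6))
})

test_that("full preprocessing is deterministic and flags fully-censored subjects", {
  spec <- cohort_spec(n_group_a = 1, n_group_b = 1, n_rois = 6,
                      n_volumes = 60, seed = 13)
  cohort <- simulate_cohort(spec)
  p1 <- preprocess_subject(cohort[[1]], n_dummy = 5, min_minutes = 0.5)
  p2 <- preprocess_subject(cohort[[1]], n_dummy = 5, min_minutes = 0.5)
  expect_identical(p1, p2)
  expect_equal(length(p1$fd), 55)
  expect_equal(p1$fd[1], 0)
  # censored volumes have (near-)zero residuals in every ROI
  if (any(p1$flags))
    expect_lt(max(abs(p1$roi_ts$values[, p1$flags])), 1e-8)

  # absurd threshold: everything censored, subject unanalyzable, no crash
  p0 <- preprocess_subject(cohort[[1]], n_dummy = 5, fd_threshold = 0)
  expect_false(p0$keep)
  expect_null(p0$roi_ts)

  # deletion mode drops the flagged columns
  pd <- preprocess_subject(cohort[[1]], n_dummy = 5, min_minutes = 0.5,
                           delete_censored = TRUE)
  expect_equal(ncol(pd$roi_ts$values), sum(!p1$flags))
})
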