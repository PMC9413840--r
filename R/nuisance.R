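# Nuisance design construction, regression, detrending and band-pass
# filtering.

#' Build the 36-parameter nuisance design
#'
#' Base regressors: the 6 rigid-body motion parameters, the same 6 from
#' the previous volume, the 12 corresponding squares (Friston's
#' 24-parameter motion model), plus the GM/WM/CSF tissue means, their
#' first differences, and the squares of both (12 tissue regressors) — 36
#' base columns in total. An intercept is always appended, optionally a
#' linear trend, and any supplied spike-censoring columns. Lags and
#' differences at the first volume are set to 0.
#'
#' @param motion_params volumes x 6 motion-parameter matrix
#' @param tissue_ts data frame or matrix with columns GM, WM, CSF
#' @param include_trend append a linear trend column
#' @param spike_regressors matrix from \code{\link{build_spike_regressors}}
#'   (0 columns allowed)
#' @return list of class \code{nuisance_design}: \code{columns} (the full
#'   design matrix), \code{column_names}, \code{n_base_params} (36),
#'   \code{includes_trend}, \code{spike_columns}
#' @export
build_design_36p <- function(motion_params, tissue_ts,
                             include_trend = FALSE,
                             spike_regressors = NULL) {
  motion_params <- as.matrix(motion_params)
  tissue <- as.matrix(tissue_ts)
  T_n <- nrow(motion_params)
  if (nrow(tissue) != T_n)
    stop_invalid("tissue series length (", nrow(tissue),
                 ") does not match motion parameters (", T_n, ")")
  if (!all(c("GM", "WM", "CSF") %in% colnames(tissue)))
    stop_invalid("tissue_ts must have columns GM, WM, CSF")
  tissue <- tissue[, c("GM", "WM", "CSF"), drop = FALSE]
  if (is.null(spike_regressors))
    spike_regressors <- matrix(0, nrow = T_n, ncol = 0)
  spike_regressors <- as.matrix(spike_regressors)
  if (nrow(spike_regressors) != T_n && ncol(spike_regressors) > 0)
    stop_invalid("spike regressor length does not match motion parameters")

  lag1 <- function(m) rbind(0, m[-nrow(m), , drop = FALSE])
  diff1 <- function(m) rbind(0, diff(m))

  motion_lag <- lag1(motion_params)
  friston24 <- cbind(motion_params, motion_lag,
                     motion_params^2, motion_lag^2)
  colnames(friston24) <- c(paste0("mp_", 1:6), paste0("mp_lag_", 1:6),
                           paste0("mp_sq_", 1:6), paste0("mp_lag_sq_", 1:6))
  tissue_diff <- diff1(tissue)
  tissue12 <- cbind(tissue, tissue_diff, tissue^2, tissue_diff^2)
  colnames(tissue12) <- c(colnames(tissue),
                          paste0(colnames(tissue), "_diff"),
                          paste0(colnames(tissue), "_sq"),
                          paste0(colnames(tissue), "_diff_sq"))
  base <- cbind(friston24, tissue12)
  stopifnot(ncol(base) == 36L)

  extra <- cbind(intercept = rep(1, T_n))
  if (include_trend)
    extra <- cbind(extra, trend = seq_len(T_n) - (T_n + 1) / 2)
  X <- cbind(base, extra, spike_regressors)
  structure(list(columns = X, column_names = colnames(X),
                 n_base_params = 36L, includes_trend = include_trend,
                 spike_columns = ncol(spike_regressors)),
            class = "nuisance_design")
}

#' Friston 24-parameter motion block
#'
#' The motion-only sub-design: 6 parameters, their one-volume lags, and
#' both sets squared (24 columns, no intercept).
#'
#' @param motion_params volumes x 6 matrix
#' @return volumes x 24 matrix
#' @export
friston24 <- function(motion_params) {
  motion_params <- as.matrix(motion_params)
  lagm <- rbind(0, motion_params[-nrow(motion_params), , drop = FALSE])
  out <- cbind(motion_params, lagm, motion_params^2, lagm^2)
  colnames(out) <- c(paste0("mp_", 1:6), paste0("mp_lag_", 1:6),
                     paste0("mp_sq_", 1:6), paste0("mp_lag_sq_", 1:6))
  out
}

#' Regress nuisance design out of time series
#'
#' Ordinary least squares with a rank-deficiency-safe (pivoted QR) solve;
#' residuals are orthogonal to every retained design column.
#'
#' @param y numeric vector, or volumes x series matrix
#' @param design a \code{nuisance_design} or plain design matrix
#' @return residuals with the shape of \code{y}
#' @export
regress_nuisance <- function(y, design) {
  X <- if (inherits(design, "nuisance_design")) design$columns else as.matrix(design)
  ym <- as.matrix(y)
  if (nrow(ym) != nrow(X))
    stop_invalid("series length does not match design rows")
  qrX <- qr(X)
  if (qrX$rank >= nrow(X))
    stop_invalid("degenerate design: rank (", qrX$rank,
                 ") not below number of volumes (", nrow(X), ")")
  res <- qr.resid(qrX, ym)
  if (is.vector(y)) as.numeric(res) else res
}

#' Remove a linear trend
#'
#' Least-squares removal of intercept and slope; idempotent.
#'
#' @param y numeric vector or volumes x series matrix
#' @return detrended series, same shape
#' @export
detrend_linear <- function(y) {
  ym <- as.matrix(y)
  T_n <- nrow(ym)
  if (T_n < 3) stop_invalid("need at least 3 time points")
  X <- cbind(1, seq_len(T_n))
  res <- qr.resid(qr(X), ym)
  if (is.vector(y)) as.numeric(res) else res
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward application of a Butterworth band-pass design
#' (default order 4), giving zero phase shift and squared magnitude
#' response. The series is extended by odd reflection at both ends before
#' filtering to suppress edge transients, then trimmed.
#'
#' @param y numeric vector or volumes x series matrix
#' @param tr_seconds sampling interval in seconds
#' @param low_hz,high_hz passband edges (defaults 0.01 and 0.08 Hz)
#' @param order Butterworth order per edge
#' @return filtered series, same shape as \code{y}
#' @export
bandpass <- function(y, tr_seconds, low_hz = 0.01, high_hz = 0.08,
                     order = 4) {
  fs <- 1 / tr_seconds
  nyq <- fs / 2
  if (low_hz <= 0 || high_hz >= nyq || low_hz >= high_hz)
    stop_invalid("band must satisfy 0 < low < high < Nyquist (",
                 signif(nyq, 4), " Hz)")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  one <- function(v) {
    n <- length(v)
    pad <- min(n - 1L, max(3L * order * 10L, 100L))
    # odd reflection: 2*v[1] - v[pad+1 .. 2], series, 2*v[n] - v[n-1 .. n-pad]
    head_pad <- 2 * v[1] - v[seq(pad + 1L, 2L)]
    tail_pad <- 2 * v[n] - v[seq(n - 1L, n - pad)]
    ext <- c(head_pad, v, tail_pad)
    out <- signal::filtfilt(bf, ext)
    out[(pad + 1L):(pad + n)]
  }
  if (is.matrix(y)) apply(y, 2, one) else one(as.numeric(y))
}

#' Preprocess one subject
#'
#' Full per-subject stream: discard dummy volumes, compute Jenkinson FD,
#' flag high-motion volumes, decide retention, then detrend and regress
#' the 36-parameter + spike nuisance model out of every ROI series.
#' Censored volumes are retained in the residual series (their values are
#' driven to ~0 by the spike regressors) so that downstream correlations
#' see a common time axis; set \code{delete_censored = TRUE} to drop them
#' instead.
#'
#' @param subject a cohort subject record (see \code{\link{simulate_cohort}})
#' @param n_dummy leading volumes discarded for steady-state magnetisation
#' @param fd_threshold censoring threshold in mm
#' @param min_minutes retention floor
#' @param head_radius FD sphere radius in mm
#' @param delete_censored drop flagged columns instead of retaining them
#' @param fd_pre_censoring compute the mean-FD covariate over all volumes
#'   (default) rather than uncensored volumes only
#' @return list: \code{roi_ts} (residual \code{roi_timeseries} with censor
#'   flags), \code{fd}, \code{flags}, \code{n_retained}, \code{keep},
#'   \code{mean_fd}, \code{motion_metrics}, \code{design}
#' @export
preprocess_subject <- function(subject, n_dummy = 10, fd_threshold = 0.2,
                               min_minutes = 4, head_radius = 80,
                               delete_censored = FALSE,
                               fd_pre_censoring = TRUE) {
  keep_idx <- (n_dummy + 1L):nrow(subject$motion)
  motion <- subject$motion[keep_idx, , drop = FALSE]
  values <- subject$roi_ts$values[, keep_idx, drop = FALSE]
  tissue <- subject$tissue_ts[keep_idx, , drop = FALSE]
  tr <- subject$roi_ts$tr_seconds

  fd <- compute_fd_jenkinson(motion, head_radius = head_radius)
  flags <- flag_spikes(fd, threshold = fd_threshold)
  n_retained <- sum(!flags)
  keep <- retention_decision(n_retained, tr, min_minutes)
  mean_fd <- if (fd_pre_censoring) mean(fd) else mean(fd[!flags])

  spikes <- build_spike_regressors(flags)
  design <- build_design_36p(motion, tissue, include_trend = FALSE,
                             spike_regressors = spikes)
  roi_ts <- NULL
  if (ncol(design$columns) < ncol(values)) {
    y <- detrend_linear(t(values))
    resid <- regress_nuisance(y, design)
    values_out <- t(resid)
    censor <- flags
    if (delete_censored) {
      values_out <- values_out[, !flags, drop = FALSE]
      censor <- rep(FALSE, ncol(values_out))
    }
    roi_ts <- roi_timeseries(values_out, subject$roi_ts$roi_labels, tr,
                             censor_flags = censor,
                             excluded_rois = subject$roi_ts$excluded_rois)
  } else {
    # so many censored volumes that the design is saturated; the subject
    # is unanalysable (the retention rule will exclude it)
    keep <- FALSE
  }
  list(roi_ts = roi_ts, fd = fd, flags = flags,
       n_retained = n_retained, keep = keep, mean_fd = mean_fd,
       motion_metrics = motion_summary_metrics(fd, fd_threshold),
       design = design)
}
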