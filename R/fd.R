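# Framewise displacement (Jenkinson RMS formulation) and motion censoring.

# Rotation matrices about each axis; rigid transform is R_z %*% R_y %*% R_x
# applied about the coordinate origin, followed by translation.
rot_x <- function(a) matrix(c(1, 0, 0,
                              0, cos(a), -sin(a),
                              0, sin(a), cos(a)), 3, 3, byrow = TRUE)
rot_y <- function(a) matrix(c(cos(a), 0, sin(a),
                              0, 1, 0,
                              -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
rot_z <- function(a) matrix(c(cos(a), -sin(a), 0,
                              sin(a), cos(a), 0,
                              0, 0, 1), 3, 3, byrow = TRUE)

rigid_transform <- function(p) {
  # p = (tx, ty, tz, rx, ry, rz); translations mm, rotations radians
  R <- rot_z(p[6]) %*% rot_y(p[5]) %*% rot_x(p[4])
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- p[1:3]
  T
}

#' Framewise displacement (Jenkinson)
#'
#' RMS displacement between consecutive volumes, integrated over a sphere
#' of radius \code{head_radius}. For each volume t >= 2 the rigid
#' transforms T_t and T_{t-1} are composed into the relative motion
#' M = T_t T_{t-1}^{-1} - I with 3x3 part A and translation b, and
#' FD_t = sqrt((R^2/5) tr(A'A) + b'b). The first volume has FD = 0 by
#' convention.
#'
#' Rotation order is Rz Ry Rx about the coordinate origin (the rotation
#' centre is configurable via \code{origin}; realignment tools differ and
#' the source convention is rarely reported).
#'
#' @param params volumes x 6 matrix: translations (mm) then rotations
#'   (radians). Set \code{rotations_first = TRUE} for the alternate
#'   column dialect.
#' @param head_radius sphere radius in mm (default 80)
#' @param origin rotation centre offset in mm (length 3; default c(0,0,0))
#' @param rotations_first whether the file stores rotations in columns 1-3
#' @return numeric FD series in mm, one value per volume, first = 0
#' @export
compute_fd_jenkinson <- function(params, head_radius = 80,
                                 origin = c(0, 0, 0),
                                 rotations_first = FALSE) {
  params <- as.matrix(params)
  if (nrow(params) < 2) stop_invalid("need at least 2 volumes")
  if (ncol(params) != 6) stop_invalid("params must have 6 columns")
  if (any(!is.finite(params))) {
    bad <- which(!stats::complete.cases(params) |
                   apply(!is.finite(params), 1, any))[1]
    stop_invalid("non-finite motion parameters at volume ", bad)
  }
  if (rotations_first) params <- params[, c(4:6, 1:3), drop = FALSE]
  n <- nrow(params)
  # shift of rotation centre: conjugate transforms by a translation to
  # `origin` so rotations act about that point
  C <- diag(4); C[1:3, 4] <- origin
  Cinv <- diag(4); Cinv[1:3, 4] <- -origin
  fd <- numeric(n)
  T_prev <- C %*% rigid_transform(params[1, ]) %*% Cinv
  for (t in 2:n) {
    T_cur <- C %*% rigid_transform(params[t, ]) %*% Cinv
    M <- T_cur %*% solve(T_prev) - diag(4)
    A <- M[1:3, 1:3]
    b <- M[1:3, 4]
    fd[t] <- sqrt(head_radius^2 / 5 * sum(A * A) + sum(b * b))
    T_prev <- T_cur
  }
  fd
}

#' Flag high-motion volumes
#'
#' A volume is flagged when its FD strictly exceeds the threshold
#' (FD > 0.2 mm by default).
#'
#' @param fd FD series (mm)
#' @param threshold censoring threshold in mm
#' @return logical vector, one flag per volume
#' @export
flag_spikes <- function(fd, threshold = 0.2) {
  if (threshold < 0) stop_invalid("threshold must be non-negative")
  fd > threshold
}

#' Spike (censoring) regressors
#'
#' One indicator column per flagged volume: 1 at that volume, 0 elsewhere.
#' Including these in a least-squares nuisance model forces the residual
#' to zero at every censored volume.
#'
#' @param flags logical vector from \code{\link{flag_spikes}}
#' @return volumes x k numeric matrix (k = number of flags; 0 columns if none)
#' @export
build_spike_regressors <- function(flags) {
  flags <- as.logical(flags)
  idx <- which(flags)
  out <- matrix(0, nrow = length(flags), ncol = length(idx))
  for (j in seq_along(idx)) out[idx[j], j] <- 1
  if (length(idx))
    colnames(out) <- sprintf("spike_%04d", idx)
  out
}

#' Data-retention verdict after censoring
#'
#' A subject is excluded when strictly less than \code{min_minutes} of
#' uncensored data remain.
#'
#' @param n_retained_volumes uncensored volume count
#' @param tr_seconds repetition time
#' @param min_minutes retention floor in minutes (default 4)
#' @return logical: \code{TRUE} = keep, \code{FALSE} = exclude
#' @export
retention_decision <- function(n_retained_volumes, tr_seconds,
                               min_minutes = 4) {
  n_retained_volumes * tr_seconds >= min_minutes * 60
}

#' Motion summary metrics
#'
#' Median FD, maximum FD, number of motion outliers (volumes with
#' FD strictly above the threshold) and interquartile range of FD. Median
#' and IQR use linear-interpolation quantiles; the outlier count reuses
#' the strict censoring rule.
#'
#' @param fd FD series (mm)
#' @param threshold outlier threshold in mm
#' @return named list: \code{median_fd}, \code{max_fd}, \code{n_outliers},
#'   \code{iqr_fd}
#' @export
motion_summary_metrics <- function(fd, threshold = 0.2) {
  if (!length(fd)) stop_invalid("fd series is empty")
  q <- quantile_li(fd, c(0.25, 0.5, 0.75))
  list(median_fd = q[2], max_fd = max(fd),
       n_outliers = sum(fd > threshold), iqr_fd = q[3] - q[1])
}
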