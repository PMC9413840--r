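# Synthetic cohort generators: motion traces, tree-structured ROI time
# series, tissue signals and CAPS clinical scores.

# Innovation SDs at scale = 1; translations in mm, rotations in radians.
# With the AR(1) persistence below these give frame-to-frame displacements
# of a few hundredths of a millimetre, typical of a compliant adult.
.MOTION_INNOV_TRANS <- 0.03
.MOTION_INNOV_ROT <- 3e-4
.MOTION_AR1_PHI <- 0.95

#' Simulate rigid-body realignment parameters
#'
#' Generates the 6-column motion-parameter table a realignment step would
#' emit: three translations (mm) then three rotations (radians), each an
#' AR(1) process whose innovation SD is proportional to \code{scale}. At
#' each volume, with probability \code{spike_rate}, a sudden persistent
#' head jerk (magnitude at least 5 innovation SDs) is injected into one
#' translation axis.
#'
#' @param n_volumes number of volumes (>= 2)
#' @param scale non-negative motion magnitude multiplier; 0 gives an
#'   exactly still head
#' @param spike_rate per-volume spike probability
#' @param seed integer seed; identical seeds reproduce the table exactly
#' @return \code{n_volumes} x 6 matrix with columns
#'   \code{tx, ty, tz, rx, ry, rz}; injected spike volumes are recorded in
#'   attribute \code{"spikes"}
#' @export
simulate_motion <- function(n_volumes, scale, spike_rate = 0.02, seed = 1L) {
  if (n_volumes < 2) stop_invalid("n_volumes must be >= 2")
  if (!is.finite(scale) || scale < 0)
    stop_invalid("scale must be a non-negative real")
  if (spike_rate < 0 || spike_rate > 1)
    stop_invalid("spike_rate must lie in [0, 1]")
  set.seed(seed)
  innov_sd <- c(rep(.MOTION_INNOV_TRANS, 3), rep(.MOTION_INNOV_ROT, 3)) * scale
  params <- matrix(0, nrow = n_volumes, ncol = 6,
                   dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz")))
  innov <- matrix(stats::rnorm(n_volumes * 6), ncol = 6)
  innov <- sweep(innov, 2, innov_sd, `*`)
  for (t in 2:n_volumes) {
    params[t, ] <- .MOTION_AR1_PHI * params[t - 1, ] + innov[t, ]
  }
  spike_at <- which(stats::runif(n_volumes) < spike_rate)
  spike_at <- spike_at[spike_at > 1]
  for (t in spike_at) {
    axis <- sample.int(3L, 1L)
    jump <- sign(stats::rnorm(1)) * (5 + stats::rexp(1)) * innov_sd[axis]
    # persistent step: the head stays in the new position
    params[t:n_volumes, axis] <- params[t:n_volumes, axis] + jump
  }
  attr(params, "spikes") <- spike_at
  params
}

#' ROI time-series container
#'
#' @param values ROI x volume numeric matrix
#' @param roi_labels one label per row
#' @param tr_seconds repetition time
#' @param censor_flags per-volume logical censor flags
#' @param excluded_rois labels excluded from network analysis
#' @return object of class \code{roi_timeseries}
#' @export
roi_timeseries <- function(values, roi_labels, tr_seconds,
                           censor_flags = rep(FALSE, ncol(values)),
                           excluded_rois = character(0)) {
  values <- as.matrix(values)
  if (nrow(values) != length(roi_labels))
    stop_invalid("row count must equal number of ROI labels")
  if (length(censor_flags) != ncol(values))
    stop_invalid("censor_flags length must equal number of volumes")
  if (tr_seconds <= 0) stop_invalid("tr_seconds must be positive")
  rownames(values) <- roi_labels
  structure(list(values = values, roi_labels = roi_labels,
                 tr_seconds = tr_seconds,
                 censor_flags = as.logical(censor_flags),
                 excluded_rois = excluded_rois),
            class = "roi_timeseries")
}

#' Expected adjacent-pair correlation of the planted-tree generator
#'
#' The generator propagates a unit-variance latent signal along the planted
#' tree with attenuation \code{strength} per edge and adds white noise of
#' SD \code{noise_sd}. Two ROIs at tree distance d then have population
#' correlation \code{strength^d / (1 + noise_sd^2)}; this helper returns
#' the d = 1 value, the generator's closed-form target for planted edges.
#'
#' @param strength edge signal strength in [0, 1)
#' @param noise_sd observation noise SD
#' @return population Pearson correlation of a planted edge
#' @export
planted_adjacent_correlation <- function(strength, noise_sd) {
  strength / (1 + noise_sd^2)
}

#' Simulate tree-structured ROI time series
#'
#' A unit-variance latent signal is assigned to a root ROI and propagated
#' along the planted spanning tree: each child is
#' \code{a * parent + sqrt(1 - a^2) * fresh}, keeping unit variance, so the
#' population correlation decays as \code{a^distance}. White observation
#' noise is added per ROI. Planted edges therefore always have strictly
#' higher expected correlation than non-edges, making the planted tree the
#' unique maximum-weight spanning tree of the population correlation
#' matrix.
#'
#' @param planted_tree two-column edge matrix, a spanning tree
#' @param edge_signal_strength attenuation per edge, in [0, 1)
#' @param noise_sd white-noise SD
#' @param n_volumes number of time points
#' @param seed integer seed
#' @param tr_seconds repetition time for the returned object
#' @param roi_names optional labels (default \code{\link{roi_labels}})
#' @return a \code{\link{roi_timeseries}}
#' @export
simulate_roi_timeseries <- function(planted_tree, edge_signal_strength,
                                    noise_sd, n_volumes, seed = 1L,
                                    tr_seconds = 1.6, roi_names = NULL) {
  planted_tree <- as.matrix(planted_tree)
  n_rois <- max(planted_tree)
  if (!is_spanning_tree(planted_tree, n_rois))
    stop_invalid("planted_tree is not a spanning tree")
  if (edge_signal_strength < 0 || edge_signal_strength >= 1)
    stop_invalid("edge_signal_strength must lie in [0, 1)")
  set.seed(seed)
  a <- edge_signal_strength
  # adjacency list, then BFS from node 1 to get a parent ordering
  adj <- vector("list", n_rois)
  for (k in seq_len(nrow(planted_tree))) {
    i <- planted_tree[k, 1]; j <- planted_tree[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  order <- integer(n_rois); parent <- integer(n_rois)
  visited <- rep(FALSE, n_rois)
  queue <- 1L; visited[1L] <- TRUE; pos <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    pos <- pos + 1L; order[pos] <- v
    for (w in adj[[v]]) if (!visited[w]) {
      visited[w] <- TRUE; parent[w] <- v; queue <- c(queue, w)
    }
  }
  latent <- matrix(0, nrow = n_rois, ncol = n_volumes)
  latent[1L, ] <- stats::rnorm(n_volumes)
  for (v in order[-1]) {
    latent[v, ] <- a * latent[parent[v], ] +
      sqrt(1 - a^2) * stats::rnorm(n_volumes)
  }
  values <- latent + noise_sd * matrix(stats::rnorm(n_rois * n_volumes),
                                       nrow = n_rois)
  if (is.null(roi_names)) roi_names <- roi_labels(n_rois)
  roi_timeseries(values, roi_names, tr_seconds)
}

#' Simulate CAPS pre/post treatment scores
#'
#' Baseline scores are drawn from a normal law truncated at 0. With the
#' group's response fraction the fractional symptom reduction comes from
#' the responder law (mean reduction above 30%), otherwise from the
#' non-responder law (mean below 30%); negative reductions (worsening) are
#' allowed. Post scores are floored at 0.
#'
#' @param group \code{"A"} or \code{"B"}
#' @param spec a \code{\link{cohort_spec}}
#' @param seed integer seed
#' @param n number of subjects to draw
#' @return data frame with columns \code{caps_pre}, \code{caps_post}
#' @export
simulate_caps <- function(group, spec, seed = 1L, n = 1L) {
  stopifnot(inherits(spec, "cohort_spec"), group %in% c("A", "B"))
  set.seed(seed)
  caps_pre <- stats::rnorm(n, spec$caps_baseline_mean, spec$caps_baseline_sd)
  while (any(bad <- caps_pre < 0)) {  # truncation at 0 by redraw
    caps_pre[bad] <- stats::rnorm(sum(bad), spec$caps_baseline_mean,
                                  spec$caps_baseline_sd)
  }
  frac <- if (group == "A") spec$response_fraction_a else spec$response_fraction_b
  from_responder_law <- stats::runif(n) < frac
  reduction <- ifelse(
    from_responder_law,
    stats::rnorm(n, spec$responder_reduction_mean, spec$responder_reduction_sd),
    stats::rnorm(n, spec$nonresponder_reduction_mean,
                 spec$nonresponder_reduction_sd))
  caps_post <- pmax(0, caps_pre * (1 - reduction))
  data.frame(caps_pre = caps_pre, caps_post = caps_post)
}

# Tissue-mean signals (GM/WM/CSF): slow AR(1) drifts, independent of the
# ROI signals; enough structure for the nuisance model to have work to do.
simulate_tissue <- function(n_volumes, seed = 1L) {
  set.seed(seed)
  one <- function() as.numeric(stats::filter(stats::rnorm(n_volumes),
                                             0.9, method = "recursive"))
  data.frame(GM = one(), WM = one(), CSF = one())
}

#' Simulate a complete synthetic cohort
#'
#' Draws \code{n_group_a + n_group_b} subject records. Each group uses its
#' own motion scale, planted tree and response fraction; per-subject seeds
#' are derived deterministically from \code{spec$seed}, so identical specs
#' produce identical cohorts.
#'
#' @param spec a \code{\link{cohort_spec}}
#' @return list of subject records (class \code{synthetic_cohort}); each
#'   record holds \code{subject_id}, \code{group}, \code{motion} (6-column
#'   parameter matrix), \code{roi_ts}, \code{tissue_ts}, \code{caps_pre},
#'   \code{caps_post}, \code{age}, \code{education}
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- spec$n_group_a + spec$n_group_b
  labels <- roi_labels(spec$n_rois)
  cohort <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    grp <- if (i <= spec$n_group_a) "A" else "B"
    scale <- if (grp == "A") spec$motion_scale_a else spec$motion_scale_b
    tree <- if (grp == "A") spec$planted_tree_a else spec$planted_tree_b
    s <- derive_seed(spec$seed, i)
    motion <- simulate_motion(spec$n_volumes, scale, spec$spike_rate,
                              seed = derive_seed(s, 1L))
    roi_ts <- simulate_roi_timeseries(tree, spec$edge_signal_strength,
                                      spec$noise_sd, spec$n_volumes,
                                      seed = derive_seed(s, 2L),
                                      tr_seconds = spec$tr_seconds,
                                      roi_names = labels)
    tissue <- simulate_tissue(spec$n_volumes, seed = derive_seed(s, 3L))
    caps <- simulate_caps(grp, spec, seed = derive_seed(s, 4L), n = 1L)
    set.seed(derive_seed(s, 5L))
    cohort[[i]] <- list(
      subject_id = sprintf("sub-%03d", i),
      group = grp,
      motion = motion,
      roi_ts = roi_ts,
      tissue_ts = tissue,
      caps_pre = caps$caps_pre,
      caps_post = caps$caps_post,
      age = round(stats::runif(1, 25, 55)),
      education = sample.int(5L, 1L)
    )
  }
  structure(cohort, class = "synthetic_cohort", spec = spec)
}

#' Write a cohort to a subject-directory layout
#'
#' One directory per subject containing \code{motion.par} (whitespace
#' delimited, translations mm then rotations rad), \code{roi_ts.tsv}
#' (rows = labelled ROIs, columns = volumes), \code{tissue.tsv}
#' (GM, WM, CSF columns), plus one cohort-level \code{clinical.csv}.
#'
#' @param cohort output of \code{\link{simulate_cohort}}
#' @param dir output directory (created if missing)
#' @return \code{dir}, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  clin <- lapply(cohort, function(s) {
    data.frame(subject_id = s$subject_id, group = s$group,
               caps_pre = s$caps_pre, caps_post = s$caps_post,
               age = s$age, education = s$education)
  })
  utils::write.csv(do.call(rbind, clin),
                   file.path(dir, "clinical.csv"), row.names = FALSE)
  for (s in cohort) {
    sd <- file.path(dir, s$subject_id)
    dir.create(sd, showWarnings = FALSE)
    utils::write.table(format(s$motion, digits = 12, scientific = FALSE,
                              trim = TRUE),
                       file.path(sd, "motion.par"),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    ts <- data.frame(roi = s$roi_ts$roi_labels,
                     s$roi_ts$values, check.names = FALSE)
    colnames(ts) <- c("roi", sprintf("v%04d", seq_len(ncol(s$roi_ts$values))))
    utils::write.table(ts, file.path(sd, "roi_ts.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(s$tissue_ts, file.path(sd, "tissue.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a cohort from a subject-directory layout
#'
#' Inverse of \code{\link{write_cohort}}.
#'
#' @param dir directory written by \code{\link{write_cohort}}
#' @param tr_seconds repetition time to attach to the ROI series
#' @return list of subject records
#' @export
read_cohort <- function(dir, tr_seconds = 1.6) {
  clin <- utils::read.csv(file.path(dir, "clinical.csv"),
                          stringsAsFactors = FALSE)
  cohort <- lapply(seq_len(nrow(clin)), function(i) {
    sd <- file.path(dir, clin$subject_id[i])
    motion <- as.matrix(utils::read.table(file.path(sd, "motion.par")))
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    ts <- utils::read.table(file.path(sd, "roi_ts.tsv"), sep = "\t",
                            header = TRUE, check.names = FALSE)
    tissue <- utils::read.table(file.path(sd, "tissue.tsv"), sep = "\t",
                                header = TRUE)
    list(subject_id = clin$subject_id[i], group = clin$group[i],
         motion = motion,
         roi_ts = roi_timeseries(as.matrix(ts[, -1]), ts$roi, tr_seconds),
         tissue_ts = tissue,
         caps_pre = clin$caps_pre[i], caps_post = clin$caps_post[i],
         age = clin$age[i], education = clin$education[i])
  })
  structure(cohort, class = "synthetic_cohort")
}
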