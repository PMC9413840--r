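#' Specification of a synthetic resting-state cohort
#'
#' Collects every knob of the synthetic cohort generator: group sizes,
#' parcellation size, scan length, per-group head-motion magnitude, the
#' planted spanning trees that define each group's inter-ROI covariance,
#' and the clinical (CAPS) score model. Defaults emulate the study design
#' the package targets: 24 + 22 subjects, 246 ROIs, 320 volumes at
#' TR = 1.6 s, baseline CAPS 70.33 (SD 15.3).
#'
#' @param n_group_a,n_group_b subjects per group (group A = prospective
#'   responders, group B = non-responders)
#' @param n_rois number of parcellation regions
#' @param n_volumes volumes acquired per subject (before dummy discard)
#' @param tr_seconds repetition time in seconds
#' @param motion_scale_a,motion_scale_b multipliers on the motion
#'   innovation SD per group (mm scale); group A defaults lower,
#'   matching the direction of the responder/non-responder motion finding
#' @param spike_rate per-volume probability of an injected motion spike
#' @param planted_tree_a,planted_tree_b two-column edge matrices, each a
#'   spanning tree over \code{n_rois} nodes; default: one shared random
#'   tree (no planted group difference)
#' @param edge_signal_strength latent-signal attenuation per tree edge,
#'   in [0, 1)
#' @param noise_sd SD of additive white observation noise per ROI
#' @param caps_baseline_mean,caps_baseline_sd baseline CAPS total score law
#' @param response_fraction_a,response_fraction_b probability that a
#'   subject's CAPS reduction is drawn from the responder law
#' @param responder_reduction_mean,responder_reduction_sd,
#'   nonresponder_reduction_mean,nonresponder_reduction_sd normal laws for
#'   the fractional CAPS reduction of responders (mean > 0.30) and
#'   non-responders (mean < 0.30)
#' @param seed master integer seed; per-subject streams are derived from it
#' @return an object of class \code{cohort_spec}
#' @export
cohort_spec <- function(n_group_a = 24, n_group_b = 22,
                        n_rois = 246, n_volumes = 320, tr_seconds = 1.6,
                        motion_scale_a = 1.0, motion_scale_b = 1.5,
                        spike_rate = 0.02,
                        planted_tree_a = NULL, planted_tree_b = NULL,
                        edge_signal_strength = 0.6, noise_sd = 0.5,
                        caps_baseline_mean = 70.33, caps_baseline_sd = 15.3,
                        response_fraction_a = 1.0, response_fraction_b = 0.0,
                        responder_reduction_mean = 0.55,
                        responder_reduction_sd = 0.12,
                        nonresponder_reduction_mean = 0.12,
                        nonresponder_reduction_sd = 0.10,
                        seed = 1L) {
  if (n_rois < 3) stop_invalid("n_rois must be >= 3")
  if (n_volumes < 20) stop_invalid("n_volumes must be >= 20")
  if (tr_seconds <= 0) stop_invalid("tr_seconds must be positive")
  if (motion_scale_a < 0 || motion_scale_b < 0)
    stop_invalid("motion scales must be non-negative")
  probs <- c(spike_rate, response_fraction_a, response_fraction_b)
  if (any(probs < 0 | probs > 1))
    stop_invalid("spike_rate and response fractions must lie in [0, 1]")
  if (edge_signal_strength < 0 || edge_signal_strength >= 1)
    stop_invalid("edge_signal_strength must lie in [0, 1)")
  if (noise_sd < 0) stop_invalid("noise_sd must be non-negative")
  if (is.null(planted_tree_a))
    planted_tree_a <- random_spanning_tree(n_rois, seed = derive_seed(seed, 999983L))
  if (is.null(planted_tree_b)) planted_tree_b <- planted_tree_a
  if (!is_spanning_tree(planted_tree_a, n_rois))
    stop_invalid("planted_tree_a is not a spanning tree over n_rois nodes")
  if (!is_spanning_tree(planted_tree_b, n_rois))
    stop_invalid("planted_tree_b is not a spanning tree over n_rois nodes")
  structure(list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    n_rois = as.integer(n_rois), n_volumes = as.integer(n_volumes),
    tr_seconds = tr_seconds,
    motion_scale_a = motion_scale_a, motion_scale_b = motion_scale_b,
    spike_rate = spike_rate,
    planted_tree_a = planted_tree_a, planted_tree_b = planted_tree_b,
    edge_signal_strength = edge_signal_strength, noise_sd = noise_sd,
    caps_baseline_mean = caps_baseline_mean,
    caps_baseline_sd = caps_baseline_sd,
    response_fraction_a = response_fraction_a,
    response_fraction_b = response_fraction_b,
    responder_reduction_mean = responder_reduction_mean,
    responder_reduction_sd = responder_reduction_sd,
    nonresponder_reduction_mean = nonresponder_reduction_mean,
    nonresponder_reduction_sd = nonresponder_reduction_sd,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Synthetic parcellation labels
#'
#' Zero-padded labels \code{ROI_001 ...} standing in for an atlas
#' parcellation. The last regions are designated "occipital" so the
#' packaged exclusion presets have something to point at.
#'
#' @param n_rois number of regions
#' @return character vector of length \code{n_rois}
#' @export
roi_labels <- function(n_rois) sprintf("ROI_%03d", seq_len(n_rois))

#' Planted-hub tree pair for group-difference simulations
#'
#' Constructs two spanning trees over the same node set that differ only
#' in the centrality of a few designated hub nodes: in tree A the hubs
#' are leaves of a random tree over the remaining nodes (betweenness 0),
#' while in tree B the hubs form a chain and the remaining nodes are
#' divided among them as star leaves (hub betweenness high). Simulating
#' one group from each tree plants a nodal-centrality group difference
#' at the hubs with no difference elsewhere.
#'
#' @param n_rois number of nodes
#' @param n_hubs number of hub nodes (nodes 1..n_hubs; default 3)
#' @param seed integer seed for the random tree in A
#' @return list: \code{tree_a}, \code{tree_b} (edge matrices),
#'   \code{hubs} (node indices)
#' @export
planted_hub_trees <- function(n_rois, n_hubs = 3, seed = 1L) {
  if (n_rois < n_hubs + 2) stop_invalid("n_rois too small for n_hubs")
  set.seed(seed)
  hubs <- seq_len(n_hubs)
  others <- (n_hubs + 1L):n_rois
  base <- random_spanning_tree(length(others))
  tree_a <- rbind(cbind(others[base[, 1]], others[base[, 2]]),
                  cbind(hubs, sample(others, n_hubs)))
  tree_b <- rbind(cbind(hubs[-n_hubs], hubs[-1]),
                  cbind(rep(hubs, length.out = length(others)), others))
  if (!is_spanning_tree(tree_a, n_rois) || !is_spanning_tree(tree_b, n_rois))
    stop("internal error: constructed trees are not spanning trees")
  list(tree_a = tree_a, tree_b = tree_b, hubs = hubs)
}

#' Packaged ROI exclusion presets
#'
#' \code{occipital8} mirrors the study-style exclusion of 8 occipital
#' regions not covered by the field of view (3.3% of 246);
#' \code{occipital16} is the stricter control set of 16. Both are synthetic
#' stand-ins defined on the tail of the \code{\link{roi_labels}}
#' parcellation, since the real atlas is not shipped.
#'
#' @param preset \code{"occipital8"} or \code{"occipital16"}
#' @param n_rois parcellation size the preset applies to
#' @return character vector of excluded ROI labels
#' @export
roi_exclusion_preset <- function(preset = c("occipital8", "occipital16"),
                                 n_rois = 246) {
  preset <- match.arg(preset)
  k <- if (preset == "occipital8") 8L else 16L
  if (n_rois <= k) stop_invalid("parcellation too small for preset ", preset)
  roi_labels(n_rois)[(n_rois - k + 1L):n_rois]
}
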