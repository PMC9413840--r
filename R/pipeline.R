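# End-to-end orchestration: simulate -> preprocess -> connectome/ALFF ->
# stats, with a serialisable run configuration and a written report.

#' Pipeline run configuration
#'
#' Every analysis constant in one place: cohort generator settings plus
#' censoring, retention, band, permutation and correction thresholds.
#' The configuration round-trips through YAML unchanged
#' (\code{\link{write_run_config}} / \code{\link{read_run_config}}).
#'
#' @param n_group_a,n_group_b,n_rois,n_volumes,tr_seconds,motion_scale_a,
#'   motion_scale_b,spike_rate,edge_signal_strength,noise_sd cohort
#'   generator settings (see \code{\link{cohort_spec}})
#' @param n_dummy leading dummy volumes discarded
#' @param fd_threshold spike-censoring threshold (mm)
#' @param min_minutes minimum retained data (minutes)
#' @param head_radius_mm FD sphere radius
#' @param band_low_hz,band_high_hz connectome band-pass edges
#' @param fwhm_mm smoothing kernel for voxel maps
#' @param exclusion_preset ROI exclusion preset name ("occipital8",
#'   "occipital16" or "none")
#' @param n_perm permutations for group tests
#' @param n_perm_omnibus permutations for the omnibus test
#' @param alpha significance / FDR level
#' @param cdt_p cluster-defining threshold
#' @param seed master seed
#' @return list of class \code{run_config}
#' @export
run_config <- function(n_group_a = 24, n_group_b = 22, n_rois = 246,
                       n_volumes = 320, tr_seconds = 1.6,
                       motion_scale_a = 1.0, motion_scale_b = 1.5,
                       spike_rate = 0.02, edge_signal_strength = 0.6,
                       noise_sd = 0.5,
                       n_dummy = 10, fd_threshold = 0.2, min_minutes = 4,
                       head_radius_mm = 80,
                       band_low_hz = 0.01, band_high_hz = 0.08,
                       fwhm_mm = 8, exclusion_preset = "occipital8",
                       n_perm = 10000, n_perm_omnibus = 2000,
                       alpha = 0.05, cdt_p = 0.001, seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a \code{run_config}
#' @param path YAML file path
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Participant flow accounting
#'
#' Tabulates enrollment against per-reason exclusions and computes the
#' final analysable n.
#'
#' @param enrolled number initially enrolled
#' @param exclusions named integer vector of per-reason exclusion counts
#' @return list: \code{table} (data frame stage/n), \code{final_n}
#' @export
participant_flow <- function(enrolled, exclusions) {
  if (enrolled < 0 || any(exclusions < 0))
    stop_invalid("counts must be non-negative")
  final_n <- enrolled - sum(exclusions)
  if (final_n < 0)
    stop_invalid("exclusions (", sum(exclusions),
                 ") exceed enrollment (", enrolled, ")")
  reasons <- if (length(exclusions)) paste0("excluded: ", names(exclusions))
             else character(0)
  tab <- data.frame(
    stage = c("enrolled", reasons, "final"),
    n = c(enrolled, -as.integer(exclusions), final_n))
  list(table = tab, final_n = final_n)
}

#' Vectorised two-group permutation tests across many outcomes
#'
#' Mean-difference permutation tests over every column of an outcome
#' matrix at once (nodal degree/BC, per-ROI ALFF), sharing one set of
#' label permutations across columns so the joint dependence structure is
#' preserved. Two-sided add-one p-values.
#'
#' @param X subjects x outcomes numeric matrix
#' @param groups two-level group labels
#' @param n_perm number of permutations
#' @param seed integer seed
#' @return data frame: \code{observed}, \code{p_value} (one row per column)
#' @export
perm_test_many <- function(X, groups, n_perm = 10000, seed = 1L) {
  X <- as.matrix(X)
  g <- groups == unique(groups)[1]
  n1 <- sum(g); n2 <- sum(!g); n <- length(g)
  if (n1 < 2 || n2 < 2) stop_invalid("each group needs >= 2 subjects")
  colsum <- colSums(X)
  obs <- colSums(X[g, , drop = FALSE]) / n1 -
    colSums(X[!g, , drop = FALSE]) / n2
  set.seed(seed)
  P <- matrix(0, nrow = n_perm, ncol = n)
  for (b in seq_len(n_perm)) P[b, sample.int(n, n1)] <- 1
  S <- P %*% X                                  # n_perm x vars
  perm_stat <- S / n1 - sweep(-S, 2, colsum, `+`) / n2
  # tie tolerance: permutations reproducing the observed split must count
  # as exceedances despite floating-point accumulation differences
  tol <- 1e-9 * (1 + abs(obs))
  exceed <- colSums(abs(perm_stat) >= matrix(abs(obs) - tol, n_perm,
                                             ncol(X), byrow = TRUE))
  data.frame(observed = obs,
             p_value = (1 + exceed) / (n_perm + 1))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort from the configuration, preprocesses every subject
#' (dummy discard, Jenkinson FD, spike censoring, retention rule,
#' 36-parameter nuisance regression), classifies treatment response from
#' CAPS scores, builds the MST connectome and ROI-level ALFF, and runs
#' the inferential layer: motion-metric group tests, the residual-motion
#' sensitivity suite (which gates leaf fraction out of group testing when
#' it correlates with FD), average-strength and omnibus global tests,
#' FDR-corrected nodal and ALFF tests, and the minimal-detectable-effect
#' computation. All stage outputs, a human-readable report and an MD5
#' content manifest are written under \code{out_dir}; reruns with the
#' same configuration are bit-identical.
#'
#' @param config a \code{\link{run_config}}
#' @param out_dir output directory (created if needed)
#' @return list with the per-stage results (invisible copies of what was
#'   written): \code{cohort_table}, \code{global}, \code{nodal},
#'   \code{alff}, \code{motion}, \code{sensitivity}, \code{omnibus},
#'   \code{power_d}, \code{report_path}
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))

  spec <- cohort_spec(
    n_group_a = config$n_group_a, n_group_b = config$n_group_b,
    n_rois = config$n_rois, n_volumes = config$n_volumes,
    tr_seconds = config$tr_seconds,
    motion_scale_a = config$motion_scale_a,
    motion_scale_b = config$motion_scale_b,
    spike_rate = config$spike_rate,
    edge_signal_strength = config$edge_signal_strength,
    noise_sd = config$noise_sd, seed = config$seed)
  cohort <- simulate_cohort(spec)

  pre <- lapply(cohort, preprocess_subject,
                n_dummy = config$n_dummy,
                fd_threshold = config$fd_threshold,
                min_minutes = config$min_minutes,
                head_radius = config$head_radius_mm)
  analyzable <- vapply(pre, function(p) isTRUE(p$keep) &&
                         !is.null(p$roi_ts), logical(1))

  responder <- classify_response(
    vapply(cohort, `[[`, numeric(1), "caps_pre"),
    vapply(cohort, `[[`, numeric(1), "caps_post"))
  cohort_table <- data.frame(
    subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
    sim_group = vapply(cohort, `[[`, character(1), "group"),
    group = ifelse(responder, "responder", "non-responder"),
    caps_pre = vapply(cohort, `[[`, numeric(1), "caps_pre"),
    caps_post = vapply(cohort, `[[`, numeric(1), "caps_post"),
    age = vapply(cohort, `[[`, numeric(1), "age"),
    education = vapply(cohort, `[[`, numeric(1), "education"),
    mean_fd = vapply(pre, `[[`, numeric(1), "mean_fd"),
    median_fd = vapply(pre, function(p) p$motion_metrics$median_fd, numeric(1)),
    max_fd = vapply(pre, function(p) p$motion_metrics$max_fd, numeric(1)),
    n_outliers = vapply(pre, function(p) p$motion_metrics$n_outliers, numeric(1)),
    iqr_fd = vapply(pre, function(p) p$motion_metrics$iqr_fd, numeric(1)),
    n_retained = vapply(pre, `[[`, numeric(1), "n_retained"),
    analyzable = analyzable)
  utils::write.csv(cohort_table, file.path(out_dir, "cohort_table.csv"),
                   row.names = FALSE)

  exclude <- if (identical(config$exclusion_preset, "none")) character(0)
             else roi_exclusion_preset(config$exclusion_preset, config$n_rois)

  idx <- which(analyzable)
  results <- list(cohort_table = cohort_table, power_d = NA_real_)
  report <- c(
    "mstconnect pipeline report",
    "==========================",
    sprintf("subjects simulated: %d (group A %d, group B %d)",
            nrow(cohort_table), config$n_group_a, config$n_group_b),
    sprintf("analyzable after retention rule: %d (excluded: %s)",
            length(idx),
            if (all(analyzable)) "none" else
              paste(cohort_table$subject_id[!analyzable], collapse = ", ")),
    sprintf("responders: %d, non-responders: %d",
            sum(cohort_table$group[idx] == "responder"),
            sum(cohort_table$group[idx] == "non-responder")),
    sprintf("ROI exclusion preset: %s (%d ROIs excluded, %d nodes retained)",
            config$exclusion_preset, length(exclude),
            config$n_rois - length(exclude)))

  n_resp <- sum(cohort_table$group[idx] == "responder")
  n_nonr <- sum(cohort_table$group[idx] == "non-responder")
  if (n_resp >= 2 && n_nonr >= 2) {
    groups <- cohort_table$group[idx]
    seed0 <- config$seed

    # --- connectome + ALFF per analyzable subject ---
    mats <- list(); trees <- list(); globals <- list(); nodals <- list()
    alffs <- list()
    for (k in seq_along(idx)) {
      p <- pre[[idx[k]]]
      filt <- p$roi_ts
      filt$values <- t(bandpass(t(filt$values), filt$tr_seconds,
                                config$band_low_hz, config$band_high_hz))
      mats[[k]] <- connectivity_matrix(filt, exclude = exclude)
      trees[[k]] <- build_mst(mats[[k]])
      globals[[k]] <- global_metrics(trees[[k]])
      nodals[[k]] <- nodal_metrics(trees[[k]])
      alffs[[k]] <- alff_by_roi(p$roi_ts,
                                band = c(config$band_low_hz,
                                         config$band_high_hz))
    }

    gtab <- data.frame(
      subject_id = cohort_table$subject_id[idx], group = groups,
      t(vapply(globals, function(g) unlist(unclass(g)), numeric(5))))
    utils::write.csv(gtab, file.path(out_dir, "global_metrics.csv"),
                     row.names = FALSE)

    # --- motion metrics group comparison (3*IQR removal, BH across 4) ---
    motion_vars <- c("median_fd", "max_fd", "n_outliers", "iqr_fd")
    motion_res <- do.call(rbind, lapply(seq_along(motion_vars), function(i) {
      v <- motion_vars[i]
      vals <- cohort_table[[v]][idx]
      kept <- remove_outliers_3iqr(vals)
      sel <- setdiff(seq_along(vals), kept$removed_indices)
      r <- perm_test_two_group(vals[sel][groups[sel] == "responder"],
                               vals[sel][groups[sel] == "non-responder"],
                               n_perm = config$n_perm,
                               seed = derive_seed(seed0, 100 + i))
      data.frame(metric = v, observed = r$observed_stat,
                 p_value = r$p_value, n_removed = length(kept$removed_indices))
    }))
    motion_res$p_fdr <- fdr_bh(motion_res$p_value, config$alpha)$adjusted
    utils::write.csv(motion_res, file.path(out_dir, "motion_tests.csv"),
                     row.names = FALSE)
    results$motion <- motion_res

    # --- residual-motion sensitivity suite ---
    sens <- motion_sensitivity_suite(mats, nodals, globals,
                                     cohort_table$mean_fd[idx],
                                     alpha = config$alpha)
    utils::write.csv(sens$global, file.path(out_dir, "sensitivity_global.csv"),
                     row.names = FALSE)
    utils::write.csv(sens$nodal, file.path(out_dir, "sensitivity_nodal.csv"),
                     row.names = FALSE)
    results$sensitivity <- sens

    # --- global network tests ---
    strength_test <- perm_test_two_group(
      gtab$avg_strength[groups == "responder"],
      gtab$avg_strength[groups == "non-responder"],
      n_perm = config$n_perm, seed = derive_seed(seed0, 200))
    integration <- c("max_bc", "leaf_fraction", "diameter_norm",
                     "avg_eccentricity_norm")
    if (sens$leaf_fraction_gated)
      integration <- setdiff(integration, "leaf_fraction")
    omni <- omnibus_group_by_metric(gtab[, integration], groups,
                                    n_perm = config$n_perm_omnibus,
                                    seed = derive_seed(seed0, 201))
    results$omnibus <- omni
    results$strength_test <- strength_test

    # --- regional (nodal) tests, FDR across nodes per metric ---
    n_nodes <- nrow(nodals[[1]])
    deg <- t(vapply(nodals, `[[`, numeric(n_nodes), "degree"))
    bc <- t(vapply(nodals, `[[`, numeric(n_nodes), "bc"))
    nodal_res <- rbind(
      data.frame(roi = nodals[[1]]$roi, metric = "degree",
                 perm_test_many(deg, groups, config$n_perm,
                                derive_seed(seed0, 202))),
      data.frame(roi = nodals[[1]]$roi, metric = "bc",
                 perm_test_many(bc, groups, config$n_perm,
                                derive_seed(seed0, 203))))
    nodal_res$p_fdr <- NA_real_
    for (mm in c("degree", "bc")) {
      sel <- nodal_res$metric == mm
      nodal_res$p_fdr[sel] <- fdr_bh(nodal_res$p_value[sel],
                                     config$alpha)$adjusted
    }
    utils::write.csv(nodal_res, file.path(out_dir, "nodal_tests.csv"),
                     row.names = FALSE)
    results$nodal <- nodal_res

    # --- ROI-level ALFF tests ---
    alff_mat <- t(vapply(alffs, `[[`, numeric(config$n_rois), "alff_z"))
    alff_res <- data.frame(roi = alffs[[1]]$roi,
                           perm_test_many(alff_mat, groups, config$n_perm,
                                          derive_seed(seed0, 204)))
    alff_res$p_fdr <- fdr_bh(alff_res$p_value, config$alpha)$adjusted
    utils::write.csv(alff_res, file.path(out_dir, "alff_tests.csv"),
                     row.names = FALSE)
    results$alff <- alff_res
    results$global <- gtab

    results$power_d <- min_detectable_effect(n_resp, n_nonr,
                                             config$alpha, 0.80)
    report <- c(report,
      sprintf("motion tests (BH-corrected): %s",
              paste(sprintf("%s p=%.4f", motion_res$metric,
                            motion_res$p_fdr), collapse = "; ")),
      sprintf("edges significantly correlated with mean FD: %.2f%% (mean tau %.4f)",
              sens$edge_pct_significant, sens$edge_tau_mean),
      sprintf("leaf fraction gated out of group testing: %s",
              sens$leaf_fraction_gated),
      sprintf("avg strength group test: p=%.4f", strength_test$p_value),
      sprintf("omnibus: group p=%.4f, metric p=%.4f, interaction p=%.4f",
              omni$p_group, omni$p_metric, omni$p_interaction),
      sprintf("nodal tests FDR-significant: %d of %d",
              sum(nodal_res$p_fdr <= config$alpha, na.rm = TRUE),
              nrow(nodal_res)),
      sprintf("ALFF tests FDR-significant: %d of %d",
              sum(alff_res$p_fdr <= config$alpha, na.rm = TRUE),
              nrow(alff_res)),
      sprintf("minimal detectable effect (d, 80%% power, alpha %.2f): %.2f",
              config$alpha, results$power_d))
  } else {
    report <- c(report,
                "too few analyzable subjects per group; statistical stages skipped")
  }

  report_path <- file.path(out_dir, "report.txt")
  writeLines(report, report_path)

  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.csv"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  manifest <- manifest[order(manifest$file), ]
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  results$report_path <- report_path
  invisible(results)
}
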