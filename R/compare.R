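#' Default run configuration
#'
#' Collects every tunable of the comparative workflow with its default:
#' clustering cutoff 1.2 A (with a robustness sweep), grid spacing 1.0 A,
#' smoothing sigma 1.5 A, SD threshold 0.05, and — when the kinetics stage is
#' enabled — 150 microstates and an MSM lag expressed in frames.
#'
#' @param loop_selection selection expression for the analysed loop C-alpha
#'   atoms (clustering / 2D-RMSD / RMSF).
#' @param fit_selection selection for superposition; defaults to the scaffold
#'   complement of the loop so loop motion is not absorbed into the fit.
#' @param cutoff clustering cutoff (A).
#' @param sweep cutoffs for the robustness sweep (A).
#' @param spacing,sigma,threshold,probe plasticity grid parameters.
#' @param max_dist localization attribution radius (A).
#' @param msm_lag MSM/tICA lag in frames, or NULL to skip kinetics.
#' @param n_microstates,n_macrostates MSM coarse-graining sizes.
#' @param seed RNG seed for k-means stages.
#' @return named list of class `"run_config"`.
#' @export
run_config <- function(loop_selection = "chain H name CA",
                       fit_selection = "chain S name CA",
                       cutoff = 1.2,
                       sweep = c(0.8, 1.0, 1.2, 1.4, 1.6),
                       spacing = 1.0, sigma = 1.5, threshold = 0.05,
                       probe = 0, max_dist = 4.0,
                       msm_lag = NULL, n_microstates = 150L,
                       n_macrostates = 2L, seed = 1L) {
  stopifnot(cutoff > 0, spacing > 0, sigma >= 0)
  structure(list(loop_selection = loop_selection, fit_selection = fit_selection,
                 cutoff = cutoff, sweep = sweep, spacing = spacing,
                 sigma = sigma, threshold = threshold, probe = probe,
                 max_dist = max_dist, msm_lag = msm_lag,
                 n_microstates = as.integer(n_microstates),
                 n_macrostates = as.integer(n_macrostates),
                 seed = as.integer(seed)),
            class = "run_config")
}

# per-ensemble analysis in an already-aligned frame, against a shared grid spec
.analyze_one <- function(ens, spec, config) {
  mat <- rmsd_matrix(ens, config$loop_selection, fit = TRUE)
  cl <- average_linkage_cluster(mat, config$cutoff)
  sweep_tab <- cluster_count_sweep(mat, config$sweep)
  prof <- rmsf(ens, config$loop_selection)
  occ <- occupancy_stats(ens, spec, probe = config$probe)
  sd_sm <- gauss_filter(occ$sd, config$sigma)
  mean_sm <- gauss_filter(occ$mean, config$sigma)
  gp <- global_plasticity(sd_sm, config$threshold)
  loc <- localize_plasticity(sd_sm, ens, max_dist = config$max_dist,
                             threshold = config$threshold)
  loc$sigma_used <- config$sigma
  res <- list(n_clusters = cl$n_clusters, clusters = cl, sweep = sweep_tab,
              rmsf = prof, mean_loop_rmsf = mean(prof$rmsf),
              occupancy = occ, sd_smoothed = sd_sm, mean_smoothed = mean_sm,
              global_plasticity = gp, localization = loc)
  if (!is.null(config$msm_lag)) {
    feats <- psi_features(ens, config$loop_selection)
    tm <- tica(feats$features, lag = config$msm_lag)
    ncomp <- min(2L, ncol(tm$projected))
    dt <- kmeans_microstates(tm$projected[, seq_len(ncomp), drop = FALSE],
                             n_states = min(config$n_microstates, n_frames(ens)),
                             seed = config$seed)
    msm <- estimate_msm(dt, lag = config$msm_lag)
    mac <- pcca_macrostates(msm, min(config$n_macrostates,
                                     length(msm$active_set)),
                            seed = config$seed)
    res$tica <- tm
    res$msm <- msm
    res$macrostates <- mac
  }
  res
}

#' Run the comparative rigidification workflow on one or two ensembles
#'
#' Chains the full analysis the package exists for: pair alignment into a
#' common frame, loop 2D-RMSD, average-linkage clustering with a cutoff sweep,
#' RMSF/B-factors, occupancy mean/SD grids, Gaussian smoothing, global and
#' localized plasticity, a difference grid (two-ensemble mode), and an
#' optional tICA/MSM kinetics stage on psi-torsion features. With
#' `output_dir` set, grids (DX), tables (CSV), B-factor PDBs and a JSON
#' report are written; the returned report lists every metric, parameter and
#' output file.
#'
#' @param ens_a first (e.g. naive) ensemble, or a path to a multi-model PDB.
#' @param ens_b optional second (e.g. matured) ensemble or path.
#' @param config a [run_config()].
#' @param output_dir optional directory for artifacts.
#' @return report list of class `"compare_report"`.
#' @export
run_compare <- function(ens_a, ens_b = NULL, config = run_config(),
                        output_dir = NULL) {
  if (is.character(ens_a)) ens_a <- read_pdb_ensemble(ens_a)
  if (is.character(ens_b)) ens_b <- read_pdb_ensemble(ens_b)
  paired <- !is.null(ens_b)
  if (paired) {
    al <- pair_align(ens_a, ens_b, config$fit_selection)
    ens_list <- list(a = al$a, b = al$b)
  } else {
    ens_list <- list(a = align_ensemble(ens_a, config$fit_selection,
                                        reference = "mean"))
  }
  spec <- make_grid_spec(unname(ens_list), spacing = config$spacing)
  results <- lapply(ens_list, .analyze_one, spec = spec, config = config)
  report <- list(
    config = unclass(config),
    grid = list(origin = spec$origin, spacing = spec$spacing, dims = spec$dims),
    ensembles = lapply(results, function(r) list(
      n_clusters = r$n_clusters,
      cluster_sweep = r$sweep,
      mean_loop_rmsf = r$mean_loop_rmsf,
      mean_loop_bfactor = mean(r$rmsf$bfactor),
      global_plasticity = r$global_plasticity,
      top_residues = utils::head(
        sort(r$localization$per_residue, decreasing = TRUE), 5),
      msm = if (!is.null(r$msm)) list(
        n_active = length(r$msm$active_set),
        retained_fraction = r$msm$retained_fraction,
        stationary = as.numeric(r$msm$stationary),
        slowest_timescale = r$msm$timescales[1],
        macro_populations = r$macrostates$macro_populations) else NULL
    )),
    manifest = character(0))
  if (paired) {
    report$difference <- list(
      delta_n_clusters = results$a$n_clusters - results$b$n_clusters,
      delta_global_plasticity =
        results$a$global_plasticity - results$b$global_plasticity)
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(...) file.path(output_dir, paste0(...))
    nm <- names(ens_list)
    for (i in seq_along(ens_list)) {
      tag <- nm[i]; r <- results[[i]]
      write_dx_grid(r$occupancy$mean, out(tag, "_mean.dx"))
      write_dx_grid(r$occupancy$sd, out(tag, "_sd.dx"))
      write_dx_grid(r$sd_smoothed, out(tag, "_sd_smoothed.dx"))
      utils::write.csv(r$sweep, out(tag, "_cluster_sweep.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(r$rmsf), out(tag, "_rmsf.csv"),
                       row.names = FALSE)
      utils::write.csv(
        data.frame(residue = names(r$localization$per_residue),
                   plasticity = as.numeric(r$localization$per_residue)),
        out(tag, "_plasticity_profile.csv"), row.names = FALSE)
      write_bfactor_pdb(ens_list[[i]], r$localization$per_residue,
                        out(tag, "_plasticity.pdb"))
      report$manifest <- c(report$manifest,
                           out(tag, c("_mean.dx", "_sd.dx", "_sd_smoothed.dx",
                                      "_cluster_sweep.csv", "_rmsf.csv",
                                      "_plasticity_profile.csv",
                                      "_plasticity.pdb")))
    }
    if (paired) {
      diff_grid <- plasticity_difference(results$a$sd_smoothed,
                                         results$b$sd_smoothed)
      write_dx_grid(diff_grid, out("sd_difference.dx"))
      report$manifest <- c(report$manifest, out("sd_difference.dx"))
    }
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    report$manifest <- c(report$manifest, out("report.json"))
  }
  structure(report, class = "compare_report")
}

#' @export
print.compare_report <- function(x, ...) {
  nm <- names(x$ensembles)
  cat("Comparative rigidification report\n")
  for (i in seq_along(x$ensembles)) {
    e <- x$ensembles[[i]]
    cat(sprintf("  [%s] clusters at %.1f A: %d | loop RMSF %.3f A | global plasticity %.1f A^3\n",
                nm[i], x$config$cutoff, e$n_clusters, e$mean_loop_rmsf,
                e$global_plasticity))
  }
  if (!is.null(x$difference))
    cat(sprintf("  difference: delta clusters %+d, delta plasticity %+.1f A^3\n",
                x$difference$delta_n_clusters,
                x$difference$delta_global_plasticity))
  invisible(x)
}
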