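## Orchestration: generate -> segment -> extract -> fit -> cluster as one
## reproducible, seed-deterministic pipeline over synthetic experiments.

#' Pipeline configuration
#'
#' All analysis constants in one place, each at its standard default:
#' baseline window 15 frames, response window 5 frames, AUC window 40 frames,
#' 33.3 Hz notch, Hanning window 7, R^2 acceptance gate 0.7, cooperativity
#' grid -57..-17 mV with 25% release cutoff, reversal potential +47.6 mV,
#' vesicle conversions 40 aF/SV, 12 AZs, 0.23 a.u./SV, K = 3 clusters.
#'
#' @param n_cells number of cells in a synthetic run.
#' @param n_synapses_total total synapses across cells (distributed 1-2 per
#'   cell).
#' @param seed master integer seed.
#' @param gradient,acq generator settings ([default_gradient()],
#'   [default_acquisition()]).
#' @param step_levels_mV step potentials for the release protocol.
#' @param step_duration_ms step length, ms.
#' @param baseline_frames,response_frames,auc_frames analysis windows (frames).
#' @param notch_Hz,hanning_window,r2_gate,coop_grid_mV,coop_cutoff,v_r_mV,K
#'   analysis constants.
#' @param aF_per_sv,n_az,au_per_sv vesicle-unit conversions.
#' @param roi_filter filter spec for ROI detection (Gaussian sigma 2 for the
#'   dual-color data).
#' @param min_area_px minimum ROI area.
#' @param match_radius_px gate for pairing glutamate ROIs with calcium hot
#'   spots.
#' @param bg_size_px side length of the background-estimation square; 12 px
#'   for the compact synthetic frames (the 60 px convention applies to
#'   full-size camera frames).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_cells = 34, n_synapses_total = 55, seed = 1L,
                            gradient = default_gradient(),
                            acq = default_acquisition(),
                            step_levels_mV = c(-57, -49, -45, -41, -37,
                                               -33, -25, -17),
                            step_duration_ms = 50,
                            baseline_frames = 15, response_frames = 5,
                            auc_frames = 40, notch_Hz = 100 / 3,
                            hanning_window = 7, r2_gate = 0.7,
                            coop_grid_mV = seq(-57, -17, by = 1),
                            coop_cutoff = 0.25, v_r_mV = 47.6, K = 3,
                            aF_per_sv = 40, n_az = 12, au_per_sv = 0.23,
                            roi_filter = list(kind = "gaussian",
                                              size_or_sigma = 2),
                            min_area_px = 20, match_radius_px = 10,
                            bg_size_px = 12) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Generate and render one synthetic cell
#'
#' Samples a ground truth, renders the calcium (ramp) and glutamate (step)
#' channels and the patch-clamp traces.
#'
#' @param n_synapses synapses in this cell.
#' @param config a [pipeline_config()].
#' @param cell_seed integer seed for this cell.
#' @return list with `gt`, `rhod`, `iglu`, `ephys`, and the two protocols.
#' @export
generate_cell <- function(n_synapses, config, cell_seed) {
  gt <- sample_ground_truth(n_synapses, config$gradient, config$acq,
                            seed = cell_seed)
  ramp <- make_protocol("ramp", seed = cell_seed)
  steps <- make_protocol("step", levels_mV = config$step_levels_mV,
                         duration_ms = config$step_duration_ms,
                         seed = cell_seed)
  rhod <- render_movie(gt, ramp, seed = cell_seed + 1L)
  iglu <- render_movie(gt, steps, seed = cell_seed + 2L)
  ephys <- synth_ephys(gt, steps, seed = cell_seed + 3L)
  list(gt = gt, rhod = rhod, iglu = iglu, ephys = ephys,
       ramp = ramp, steps = steps)
}

# per-plane mean dF image of the ramp recording, averaged over planes;
# response = the 5 frames nearest the top of the calcium-influx curve
rhod_mean_df <- function(rhod, config) {
  v <- rhod$frame_voltage_mV
  resp <- order(abs(v - (-17)))[1:config$response_frames]
  resp <- sort(resp)
  base <- seq_len(config$baseline_frames)
  dfs <- lapply(rhod$movies, delta_f_image, baseline_frames = base,
                response_frames = resp)
  structure(Reduce(`+`, lapply(dfs, unclass)) / length(dfs),
            class = c("delta_f_image", "matrix"),
            baseline_frames = base, response_frames = resp)
}

#' Analyze one cell: movies to per-synapse fit records
#'
#' Calcium hot spots are detected on the plane-averaged ramp response image
#' and assigned their best plane; glutamate ROIs are detected on the
#' strongest-step response image and paired with the nearest hot spot within
#' the match radius. Traces are background-subtracted, normalized, notch
#' filtered (calcium channel), bleach corrected (glutamate channel) and
#' reduced to fit records: modified Boltzmann (calcium), Boltzmann (release),
#' power-law cooperativity, plus peak signal and axis position.
#'
#' @param cell a [generate_cell()] result (or equivalent bundle list with
#'   `rhod` and `iglu`).
#' @param config a [pipeline_config()].
#' @param cell_id identifier used in the output rows.
#' @return list with `profiles` (data.frame, one row per matched synapse),
#'   `rois` (calcium ROI set), `ellipse`, `errors` (character).
#' @export
analyze_cell <- function(cell, config = pipeline_config(), cell_id = "cell1") {
  rhod <- cell$rhod; iglu <- cell$iglu
  errors <- character()
  base <- seq_len(config$baseline_frames)

  ## --- calcium channel: hot spots, best planes, FV fits
  dfr <- rhod_mean_df(rhod, config)
  rois <- detect_rois(dfr, filter = config$roi_filter,
                      min_area_px = config$min_area_px)
  if (nrow(rois$rois) == 0)
    return(list(profiles = NULL, rois = rois, ellipse = NULL,
                errors = "no calcium hot spots detected"))
  resp <- attr(dfr, "response_frames")
  baseline_img <- apply(rhod$movies[[ceiling(length(rhod$movies) / 2)]][, , base],
                        c(1, 2), mean)
  ellipse <- tryCatch(fit_cell_ellipse(baseline_img, pillar = "left"),
                      error = function(e) { errors <<- c(errors,
                        conditionMessage(e)); NULL })
  bg_rect <- background_region(dim(dfr), rois$label_image, anchor = "left",
                               size = config$bg_size_px)

  ## --- glutamate channel: ROIs on the strongest step
  strongest <- which.max(iglu$levels_mV)
  dfi <- delta_f_image(iglu$movies[[strongest]], base,
                       iglu$stim_onset_frame:
                         (iglu$stim_onset_frame + config$response_frames - 1))
  irois <- detect_rois(dfi, filter = config$roi_filter,
                       min_area_px = config$min_area_px)
  ibg_rect <- background_region(dim(dfi), irois$label_image, anchor = "left",
                                size = config$bg_size_px)

  profiles <- list()
  for (r in seq_len(nrow(rois$rois))) {
    row <- tryCatch({
      roi <- rois$rois[r, ]
      px <- rois$label_image == roi$id
      plane <- best_plane(rhod$movies, px, base, resp)
      mov <- rhod$movies[[plane]]
      raw <- roi_trace(mov, px)
      bg <- roi_trace(mov, as.matrix(expand.grid(bg_rect$rows, bg_rect$cols)))
      raw_f <- bandstop_33(raw, rate_Hz = rhod$rate_Hz,
                           center_Hz = config$notch_Hz)
      bg_f <- bandstop_33(bg, rate_Hz = rhod$rate_Hz,
                          center_Hz = config$notch_Hz)
      dff <- normalize_dff(raw_f, bg_f, rate_Hz = rhod$rate_Hz,
                           baseline_window = base,
                           stim_onset_index = rhod$stim_onset_frame)
      v <- rhod$frame_voltage_mV
      expo <- rhod$protocol$ramp_rate_mV_per_ms * 1000 / rhod$rate_Hz
      ca_fit <- fit_ca_fv(v[is.finite(v)], dff$samples[is.finite(v)],
                          v_r_mV = config$v_r_mV, r2_gate = config$r2_gate,
                          exposure_mV = expo)
      peak <- rhodff_peak(dff$samples, v)

      ## matched glutamate ROI
      d2 <- (irois$rois$centroid_x - roi$centroid_x)^2 +
        (irois$rois$centroid_y - roi$centroid_y)^2
      if (nrow(irois$rois) == 0 || min(d2) > config$match_radius_px^2)
        stop("no glutamate ROI within the match radius")
      ir <- irois$rois[which.min(d2), ]
      ipx <- irois$label_image == ir$id
      step_res <- lapply(seq_along(iglu$levels_mV), function(j) {
        mv <- iglu$movies[[j]]
        rw <- roi_trace(mv, ipx)
        bgT <- roi_trace(mv, as.matrix(expand.grid(ibg_rect$rows,
                                                   ibg_rect$cols)))
        dd <- normalize_dff(rw, bgT, rate_Hz = iglu$rate_Hz,
                            baseline_window = base,
                            stim_onset_index = iglu$stim_onset_frame)
        bc <- bleach_correct(dd, response_frames = config$auc_frames)
        list(auc = auc_response(bc$trace, n_frames = config$auc_frames),
             bleach_tau_s = bc$fit$tau_s)
      })
      aucs <- vapply(step_res, `[[`, numeric(1), "auc")
      bleach_tau <- stats::median(vapply(step_res, `[[`, numeric(1),
                                         "bleach_tau_s"), na.rm = TRUE)
      ordV <- order(iglu$levels_mV)
      rel_fit <- fit_release_boltzmann(iglu$levels_mV[ordV], aucs[ordV],
                                       r2_gate = config$r2_gate)
      coop <- tryCatch(
        cooperativity(ca_fit, rel_fit, grid_mV = config$coop_grid_mV,
                      cutoff = config$coop_cutoff,
                      r2_gate = config$r2_gate),
        error = function(e) list(m = NA_real_, excluded = TRUE))
      pos <- if (is.null(ellipse)) NA_real_ else
        axis_position(ellipse, c(roi$centroid_x, roi$centroid_y))
      data.frame(
        cell_id = cell_id, synapse_id = roi$id,
        centroid_x = roi$centroid_x, centroid_y = roi$centroid_y,
        best_plane = plane,
        v_half_ca = ca_fit$v_half_mV, k_ca = ca_fit$k_mV,
        v10_ca = ca_fit$v_half_mV - ca_fit$k_mV * log(9),
        dr_ca = ca_fit$k_mV * log(81),
        peak_rhod = peak,
        v_half_rel = rel_fit$v_half_mV, k_rel = rel_fit$k_mV,
        v10_rel = rel_fit$v10_mV, dr_rel = rel_fit$dynamic_range_mV,
        max_auc_rel = max(aucs), m = coop$m,
        bleach_tau_s = bleach_tau,
        position_01 = pos,
        r2_ca = ca_fit$r_squared, r2_rel = rel_fit$r_squared,
        r2_m = if (is.null(coop$r_squared)) NA_real_ else coop$r_squared,
        excluded = isTRUE(ca_fit$excluded) || isTRUE(rel_fit$excluded) ||
          isTRUE(coop$excluded),
        stringsAsFactors = FALSE)
    }, error = function(e) {
      errors <<- c(errors, sprintf("roi %d: %s", r, conditionMessage(e)))
      NULL
    })
    if (!is.null(row)) profiles[[length(profiles) + 1]] <- row
  }
  list(profiles = if (length(profiles)) do.call(rbind, profiles) else NULL,
       rois = rois, ellipse = ellipse, errors = errors)
}

#' Run the full synthetic pipeline
#'
#' Generates `n_cells` synthetic cells, analyzes each, assembles the synapse
#' profile table, clusters it, projects it with PCA, computes the property
#' correlation matrix and pillar/modiolar group statistics, and (optionally)
#' writes everything plus a manifest to a run directory. Rerunning with the
#' same configuration is bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param run_dir output directory (`NULL` to skip writing).
#' @param progress print per-cell progress.
#' @return list with `table` (clustered profile table), `truth` (matched
#'   ground-truth records), `cluster`, `pca`, `correlation`, `stats`,
#'   `errors`, `config`, `run_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), run_dir = NULL,
                         progress = FALSE) {
  n_two <- config$n_synapses_total - config$n_cells
  if (n_two < 0 || n_two > config$n_cells)
    stop("n_synapses_total must be within [n_cells, 2 * n_cells]")
  per_cell <- c(rep(2L, n_two), rep(1L, config$n_cells - n_two))
  all_profiles <- list(); all_truth <- list(); all_errors <- list()
  for (ci in seq_len(config$n_cells)) {
    cell_seed <- config$seed * 1000L + ci * 7L
    cell <- generate_cell(per_cell[ci], config, cell_seed)
    res <- analyze_cell(cell, config, cell_id = sprintf("cell%02d", ci))
    if (progress)
      message(sprintf("cell %d/%d: %d synapses recovered", ci,
                      config$n_cells,
                      if (is.null(res$profiles)) 0 else nrow(res$profiles)))
    if (!is.null(res$profiles)) {
      tr <- match_ground_truth(res$profiles, cell$gt)
      all_profiles[[length(all_profiles) + 1]] <- res$profiles
      all_truth[[length(all_truth) + 1]] <- tr
    }
    if (length(res$errors))
      all_errors[[length(all_errors) + 1]] <-
        data.frame(cell = ci, error = res$errors)
  }
  profiles <- do.call(rbind, all_profiles)
  truth <- do.call(rbind, all_truth)
  tab <- build_table(profiles)
  clus <- tryCatch(cluster_synapses(tab, K = config$K, seed = config$seed),
                   error = function(e) NULL)
  if (!is.null(clus)) tab <- clus$table
  pca <- tryCatch(pca_project(tab), error = function(e) NULL)
  corr <- tryCatch(correlate_properties(tab), error = function(e) NULL)
  stats_rep <- tryCatch(compare_groups(tab, by = "position"),
                        error = function(e) NULL)
  out <- list(table = tab, truth = truth, cluster = clus, pca = pca,
              correlation = corr, stats = stats_rep,
              errors = if (length(all_errors)) do.call(rbind, all_errors)
                       else NULL,
              config = config, run_dir = run_dir)
  if (!is.null(run_dir)) write_run(out, run_dir)
  invisible(out)
}

#' Pair recovered synapse rows with their ground-truth records
#'
#' Matches each analyzed ROI to the nearest ground-truth hot spot (within
#' 10 px) and returns the truth rows aligned with the profile rows, for
#' recovery scoring.
#'
#' @param profiles data.frame from [analyze_cell()].
#' @param gt the cell's [sample_ground_truth()].
#' @param radius_px maximum pairing distance.
#' @return data.frame of ground-truth parameters (NA rows where unmatched).
#' @export
match_ground_truth <- function(profiles, gt, radius_px = 10) {
  syn <- gt$synapses
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    d2 <- (syn$hotspot_x - profiles$centroid_x[i])^2 +
      (syn$hotspot_y - profiles$centroid_y[i])^2
    j <- which.min(d2)
    if (d2[j] > radius_px^2) {
      out <- syn[1, ]; out[] <- NA
    } else out <- syn[j, ]
    out
  })
  do.call(rbind, rows)
}

write_run <- function(out, run_dir) {
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(out$table),
                   file.path(run_dir, "synapse_profiles.csv"),
                   row.names = FALSE)
  if (!is.null(out$correlation))
    utils::write.csv(out$correlation,
                     file.path(run_dir, "correlation_matrix.csv"))
  if (!is.null(out$pca)) {
    utils::write.csv(out$pca$scores, file.path(run_dir, "pca_scores.csv"))
    utils::write.csv(out$pca$loadings,
                     file.path(run_dir, "pca_loadings.csv"))
  }
  if (!is.null(out$stats))
    utils::write.csv(out$stats, file.path(run_dir, "group_statistics.csv"),
                     row.names = FALSE)
  if (!is.null(out$errors))
    utils::write.csv(out$errors, file.path(run_dir, "stage_errors.csv"),
                     row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ihcsynapse")),
    seed = out$config$seed,
    n_cells = out$config$n_cells,
    n_synapses_total = out$config$n_synapses_total,
    n_recovered = nrow(out$table),
    n_qc_pass = sum(out$table$qc_pass),
    constants = out$config[c("baseline_frames", "response_frames",
                             "auc_frames", "notch_Hz", "hanning_window",
                             "r2_gate", "coop_cutoff", "v_r_mV", "K",
                             "aF_per_sv", "n_az", "au_per_sv")])
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(run_dir)
}
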