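#' End-to-end synthetic array-comparison experiment
#'
#' Simulates a cohort of synthetic subjects, each measured with both the
#' sparse and the HD array on the same cortical ground truth, runs the full
#' processing chain (prune, optical density, motion correction, low-pass,
#' Beer-Lambert, GLM with short-separation regression), reconstructs
#' block-delta images, and compares the arrays in channel and image space
#' with paired statistics.
#'
#' @name experiment
NULL

#' Experiment configuration
#'
#' All stage thresholds default to the package's standard processing values.
#'
#' @param n_subjects number of synthetic subjects.
#' @param seed master seed; per-subject seeds are derived from it.
#' @param noise_params simulator noise parameters ([default_noise_params()]).
#' @param hbo_amplitude,hbr_amplitude condition amplitudes, uM.
#' @param roi_radius channel-to-center distance defining ROI channels, mm.
#' @param n_top_vertices image-space vertices averaged after max-t ranking.
#' @param alpha_spatial,alpha_meas reconstruction regularization.
#' @param intensity_min,snr_min pruning thresholds.
#' @param lowpass_fc low-pass cutoff, Hz.
#' @param head_spacing head-model lateral vertex spacing, mm.
#' @param run_glm fit the per-channel GLM and summarize the estimated HRF
#'   of each subject's selected ROI channel (default `TRUE`).
#' @param out_dir optional directory; when given, result tables and the
#'   configuration (with a content hash) are written there as text.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(n_subjects = 20, seed = 1,
                              noise_params = default_noise_params(),
                              hbo_amplitude = c(congruent = 5, incongruent = 10),
                              hbr_amplitude = c(congruent = -1.5, incongruent = -3),
                              roi_radius = 30, n_top_vertices = 25,
                              alpha_spatial = 0.001, alpha_meas = 0.001,
                              intensity_min = 0.001, snr_min = 5,
                              lowpass_fc = 0.5, head_spacing = 5,
                              run_glm = TRUE, out_dir = NULL) {
  structure(list(n_subjects = n_subjects, seed = seed,
                 noise_params = noise_params,
                 hbo_amplitude = hbo_amplitude, hbr_amplitude = hbr_amplitude,
                 roi_radius = roi_radius, n_top_vertices = n_top_vertices,
                 alpha_spatial = alpha_spatial, alpha_meas = alpha_meas,
                 intensity_min = intensity_min, snr_min = snr_min,
                 lowpass_fc = lowpass_fc, head_spacing = head_spacing,
                 run_glm = run_glm, out_dir = out_dir),
            class = "experiment_config")
}

#' Preprocess a raw intensity recording to concentration
#'
#' Runs the standard chain: prune, optical density, spline +
#' Savitzky-Golay motion correction, 0.5 Hz low-pass, Beer-Lambert.
#'
#' @param rec a `nirs_recording` with `stage = "intensity"`.
#' @param intensity_min,snr_min pruning thresholds.
#' @param fc low-pass cutoff, Hz.
#' @param ppf partial pathlength factor.
#' @return list with the concentration `rec` and the `prune` report.
#' @export
preprocess_recording <- function(rec, intensity_min = 0.001, snr_min = 5,
                                 fc = 0.5, ppf = 1) {
  prune <- prune_channels(rec, intensity_min, snr_min)
  out <- intensity_to_od(rec)
  out <- splinesg_correct(out)
  out <- lowpass(out, fc)
  out <- od_to_conc(out, ppf)
  list(rec = out, prune = prune)
}

# per-side ROI channel indices: unpruned long channels whose midpoint lies
# within radius of the side's activation center
roi_channels_for <- function(layout, centers, radius, keep) {
  mid <- channel_positions(layout)$mid
  lapply(centers, function(ctr) {
    d <- sqrt((mid[, 1] - ctr[1])^2 + (mid[, 2] - ctr[2])^2)
    which(d <= radius & !layout$channels$is_short & keep)
  })
}

# channel-space and image-space ROI statistics for one subject/array
subject_array_stats <- function(conc, prune, layout, ms, truth, config,
                                roi_vertices, mask = NULL,
                                roi_centers = truth$centers) {
  sched <- conc$schedule
  conds <- sort(unique(sched$blocks$condition))
  nch <- nrow(layout$channels)
  keep <- prune$keep
  sides <- names(roi_centers)
  if (is.null(sides)) sides <- paste0("side", seq_along(roi_centers))
  roi_ch <- roi_channels_for(layout, roi_centers, config$roi_radius, keep)
  names(roi_ch) <- sides

  # per-channel per-block deltas for both chromophores
  blocks <- sched$blocks
  deltas <- array(NA_real_, dim = c(nch, 2, nrow(blocks)))
  for (k in which(keep & !layout$channels$is_short))
    for (ci in 1:2)
      deltas[k, ci, ] <- vapply(seq_len(nrow(blocks)), function(i)
        block_delta(conc$data[k, ci, ], blocks$onset[i], conc$fs,
                    time = conc$time), numeric(1))

  chan_rows <- NULL
  for (side in sides) for (cn in conds) {
    bi <- which(blocks$condition == cn)
    cand <- roi_ch[[side]]
    if (length(cand) == 0) next
    ts <- vapply(cand, function(k) tstat(deltas[k, 1, bi])$t, numeric(1))
    names(ts) <- cand
    sel <- select_max_t(ts, "HbO")
    st <- tstat(deltas[sel, 1, bi])
    chan_rows <- rbind(chan_rows, data.frame(
      space = "channel", side = side, condition = cn, id = sel,
      delta = st$mean, t = st$t))
  }

  # block-wise images: channel concentration deltas -> OD -> one image per block
  nv <- nrow(ms$vertices)
  Y <- matrix(0, 2 * nch, nrow(blocks))
  sep <- layout$channels$separation
  for (k in which(keep & !layout$channels$is_short)) {
    od <- conc_to_od(rbind(deltas[k, 1, ], deltas[k, 2, ]), sep[k])
    Y[k, ] <- od[1, ]
    Y[nch + k, ] <- od[2, ]
  }
  img <- reconstruct(Y, ms, recon_config(config$alpha_spatial, config$alpha_meas))
  vd <- img$values[seq_len(nv), , drop = FALSE]  # HbO vertex x block

  img_rows <- NULL
  loc_rows <- NULL
  brain <- ms$vertices$surface == "brain"
  for (side in sides) {
    vids <- roi_vertices[[side]]
    rows <- match(vids, ms$vertices$vertex_id)
    for (cn in conds) {
      bi <- which(blocks$condition == cn)
      vt <- apply(vd[rows, bi, drop = FALSE], 1, function(z) tstat(z)$t)
      top <- order(vt, decreasing = TRUE)[seq_len(min(config$n_top_vertices,
                                                      length(vt)))]
      sel_rows <- rows[top]
      st <- tstat(colMeans(vd[sel_rows, bi, drop = FALSE]))
      img_rows <- rbind(img_rows, data.frame(
        space = "image", side = side, condition = cn, id = NA_integer_,
        delta = st$mean, t = st$t))
      # localization: peak brain vertex of the across-block t image (the
      # display statistic), searched inside the array's total-sensitivity
      # mask on the activation's hemisphere
      t_img <- apply(vd[, bi, drop = FALSE], 1, function(z) tstat(z)$t)
      t_img[!brain] <- -Inf
      if (!is.null(mask)) t_img[!mask] <- -Inf
      ctr <- truth$centers[[side]]
      half <- sign(ms$vertices$x - 0) == sign(ctr[1])
      t_img[!half] <- -Inf
      pk <- which.max(t_img)
      err <- sqrt((ms$vertices$x[pk] - ctr[1])^2 +
                    (ms$vertices$y[pk] - ctr[2])^2)
      loc_rows <- rbind(loc_rows, data.frame(side = side, condition = cn,
                                             loc_error = err))
    }
  }
  list(roi = rbind(chan_rows, img_rows), localization = loc_rows,
       n_kept = sum(keep), n_pruned = sum(!keep))
}

#' Run the full array-comparison experiment
#'
#' For each synthetic subject, simulates sparse and HD recordings on the
#' same ground truth, processes both, and accumulates paired ROI statistics
#' (channel and image space) plus peak-localization errors. Group-level
#' paired t tests compare the arrays per side, condition and space.
#'
#' @param config an [experiment_config()].
#' @return an `experiment_result`: list with `subject_table` (per subject,
#'   array, space, side, condition: delta and t), `paired` (group paired
#'   comparisons with the fraction of subjects where HD > sparse),
#'   `localization` (per-subject peak errors and their group means),
#'   `retention` (channels kept/pruned), `config`, `config_hash`, `timings`.
#' @export
run_experiment <- function(config = experiment_config()) {
  t0 <- proc.time()[["elapsed"]]
  layouts <- list(sparse = build_sparse_layout(), hd = build_hd_layout())
  head <- build_head_model(layouts, spacing = config$head_spacing)
  centers <- list(left = c(-70, 0), right = c(70, 0))
  S <- lapply(layouts, build_sensitivity, head = head)
  ms <- lapply(S, multispectral_sensitivity)
  masks <- lapply(S, total_sensitivity_mask)
  t_setup <- proc.time()[["elapsed"]] - t0

  # image ROI vertices from the HD array's sensitivity, shared by both
  keep_all <- rep(TRUE, nrow(layouts$hd$channels))
  hd_roi_ch <- roi_channels_for(layouts$hd, centers, config$roi_radius, keep_all)
  roi_vertices <- lapply(hd_roi_ch, function(chs)
    select_roi_vertices(S$hd, chs))
  names(roi_vertices) <- names(centers)

  subject_rows <- NULL
  loc_rows <- NULL
  retention <- NULL
  for (s in seq_len(config$n_subjects)) {
    sseed <- config$seed * 1000L + s
    # per-subject ground truth: activation centers jittered within 10 mm of
    # the nominal ROI centers (inter-subject anatomical variability), and a
    # subject-specific superficial gain field
    set.seed(sseed)
    r <- 10 * sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
    ctr_r <- centers$right + c(r * cos(th), r * sin(th))
    truth <- ground_truth(head,
                          centers = list(left = c(-ctr_r[1], ctr_r[2]),
                                         right = ctr_r),
                          hbo_amplitude = config$hbo_amplitude,
                          hbr_amplitude = config$hbr_amplitude,
                          seed = sseed)
    sched <- generate_schedule(sseed)
    for (arr in names(layouts)) {
      rec <- simulate_recording(layouts[[arr]], S[[arr]], truth, sched,
                                noise_params = config$noise_params,
                                seed = sseed + ifelse(arr == "hd", 500L, 0L))
      pp <- preprocess_recording(rec, config$intensity_min, config$snr_min,
                                 config$lowpass_fc)
      st <- subject_array_stats(pp$rec, pp$prune, layouts[[arr]], ms[[arr]],
                                truth, config, roi_vertices, masks[[arr]],
                                roi_centers = centers)
      if (isTRUE(config$run_glm)) {
        design <- build_design(sched, rec$fs)
        est <- fit_glm(pp$rec, design, keep = pp$prune$keep)
        chan_sel <- st$roi[st$roi$space == "channel", , drop = FALSE]
        st$roi$hrf_peak <- NA_real_
        for (r in seq_len(nrow(chan_sel))) {
          tr <- est$hrf[chan_sel$id[r], chan_sel$condition[r], "HbO", ]
          st$roi$hrf_peak[st$roi$space == "channel" &
                            st$roi$side == chan_sel$side[r] &
                            st$roi$condition == chan_sel$condition[r]] <-
            max(tr)
        }
      }
      subject_rows <- rbind(subject_rows,
                            cbind(subject = s, array = arr, st$roi))
      loc_rows <- rbind(loc_rows,
                        cbind(subject = s, array = arr, st$localization))
      retention <- rbind(retention, data.frame(subject = s, array = arr,
                                               kept = st$n_kept,
                                               pruned = st$n_pruned))
    }
  }

  paired <- NULL
  for (sp in unique(subject_rows$space))
    for (side in unique(subject_rows$side))
      for (cn in unique(subject_rows$condition)) {
        sel <- subject_rows$space == sp & subject_rows$side == side &
          subject_rows$condition == cn
        hd <- subject_rows$delta[sel & subject_rows$array == "hd"]
        sps <- subject_rows$delta[sel & subject_rows$array == "sparse"]
        if (length(hd) < 2 || length(hd) != length(sps)) next
        pt <- paired_ttest(hd, sps)
        paired <- rbind(paired, data.frame(
          space = sp, side = side, condition = cn,
          mean_hd = mean(hd), mean_sparse = mean(sps),
          t = pt$t, p = pt$p, frac_hd_greater = mean(hd > sps)))
      }

  loc_group <- stats::aggregate(loc_error ~ array + condition, loc_rows, mean)
  result <- structure(list(subject_table = subject_rows, paired = paired,
                           localization = loc_rows,
                           localization_group = loc_group,
                           retention = retention, config = config,
                           roi_vertices = roi_vertices,
                           timings = c(setup = t_setup,
                                       total = proc.time()[["elapsed"]] - t0)),
                      class = "experiment_result")
  result$config_hash <- config_hash(config)
  if (!is.null(config$out_dir)) write_experiment(result, config$out_dir)
  result
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[setdiff(names(config), "out_dir")], tmp,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$subject_table, file.path(dir, "subject_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$paired, file.path(dir, "paired_comparison.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$localization, file.path(dir, "localization.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- result$config[setdiff(names(result$config), "out_dir")]
  cfg$config_hash <- result$config_hash
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d subjects, hash %s\n",
              x$config$n_subjects, x$config_hash))
  print(x$paired)
  invisible(x)
}
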