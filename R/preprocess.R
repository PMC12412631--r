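#' Channel-space preprocessing chain
#'
#' Raw intensity to chromophore concentration in the standard order:
#' prune weak channels, convert to optical density, correct motion with a
#' spline + Savitzky-Golay step, low-pass filter, and apply the modified
#' Beer-Lambert law. Each step consumes and returns a `nirs_recording`,
#' whose `stage` tag enforces the order.
#'
#' @name preprocess
NULL

#' Prune channels on raw intensity level and SNR
#'
#' A channel is pruned when, at either wavelength, its mean raw intensity is
#' below `intensity_min` or its signal-to-noise ratio (mean divided by
#' standard deviation) is below `snr_min` (both strict). Channels with zero
#' standard deviation have infinite SNR and are kept.
#'
#' @param rec a `nirs_recording` with `stage = "intensity"`.
#' @param intensity_min minimum mean intensity (default 0.001).
#' @param snr_min minimum mean/SD ratio (default 5).
#' @return a `prune_report`: data frame with per-channel `keep` flag and
#'   `reason` (`"low_intensity"`, `"low_snr"` or `""`), plus kept/pruned
#'   counts as attributes.
#' @export
prune_channels <- function(rec, intensity_min = 0.001, snr_min = 5) {
  stopifnot(identical(rec$stage, "intensity"))
  if (length(rec$data) == 0) stop("empty recording")
  nch <- dim(rec$data)[1]
  keep <- rep(TRUE, nch)
  reason <- rep("", nch)
  for (k in seq_len(nch)) {
    for (i in seq_len(dim(rec$data)[2])) {
      x <- rec$data[k, i, ]
      m <- mean(x); s <- stats::sd(x)
      snr <- if (s == 0) Inf else m / s
      if (m < intensity_min) { keep[k] <- FALSE; reason[k] <- "low_intensity"; break }
      if (snr < snr_min) { keep[k] <- FALSE; reason[k] <- "low_snr"; break }
    }
  }
  rep <- data.frame(channel = seq_len(nch), keep = keep, reason = reason)
  attr(rep, "n_kept") <- sum(keep)
  attr(rep, "n_pruned") <- sum(!keep)
  class(rep) <- c("prune_report", class(rep))
  rep
}

#' Convert intensity to optical density
#'
#' `OD(t) = -log(I(t) / mean(I))` per channel and wavelength (natural log).
#'
#' @param rec a `nirs_recording` with `stage = "intensity"`.
#' @return the recording with `stage = "od"`.
#' @export
intensity_to_od <- function(rec) {
  stopifnot(identical(rec$stage, "intensity"))
  od <- rec$data
  for (k in seq_len(dim(od)[1])) {
    for (i in seq_len(dim(od)[2])) {
      x <- rec$data[k, i, ]
      if (any(x <= 0))
        stop(sprintf("non-positive intensity sample in channel %d", k))
      od[k, i, ] <- -log(x / mean(x))
    }
  }
  rec$data <- od
  rec$stage <- "od"
  rec
}

# flag motion samples: sample-to-sample jumps exceeding thresh_sd times a
# robust (median-based) estimate of the channel's jump scale, so smooth
# oscillations pass while spikes and baseline steps are caught
detect_motion <- function(x, fs, thresh_sd = 6) {
  d <- diff(x)
  sdref <- stats::mad(d)
  flag <- rep(FALSE, length(x))
  if (sdref == 0) return(flag)
  hit <- which(abs(d) > thresh_sd * sdref)
  flag[hit] <- TRUE
  flag[pmin(length(x), hit + 1L)] <- TRUE
  flag
}

# merge flagged samples into segments, pad by pad_s seconds
motion_segments <- function(flag, fs, pad_s = 0.5) {
  pad <- as.integer(round(pad_s * fs))
  idx <- which(flag)
  if (length(idx) == 0) return(NULL)
  starts <- idx[c(TRUE, diff(idx) > 1)]
  ends <- idx[c(diff(idx) > 1, TRUE)]
  starts <- pmax(1L, starts - pad)
  ends <- pmin(length(flag), ends + pad)
  # merge overlapping after padding
  keep_s <- starts[1]; segs <- NULL; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e) cur_e <- max(cur_e, ends[i])
    else { segs <- rbind(segs, c(keep_s, cur_e)); keep_s <- starts[i]; cur_e <- ends[i] }
  }
  rbind(segs, c(keep_s, cur_e))
}

# spline baseline correction within motion segments (smoothing-spline fit
# subtracted, segment re-anchored to the preceding baseline level)
spline_correct_channel <- function(x, fs, spar_p = 0.99) {
  flag <- detect_motion(x, fs)
  segs <- motion_segments(flag, fs)
  if (is.null(segs)) return(x)
  y <- x
  n <- length(y)
  w <- max(3L, as.integer(round(0.5 * fs)))
  for (r in seq_len(nrow(segs))) {
    a <- segs[r, 1]; b <- segs[r, 2]
    tt <- a:b
    pre_level <- if (a > 1) stats::median(y[max(1, a - w):(a - 1)]) else mean(y[tt])
    if (length(tt) >= 4) {
      fit <- try(stats::smooth.spline(tt, y[tt], spar = 1 - spar_p + 0.2),
                 silent = TRUE)
      trend <- if (inherits(fit, "try-error")) rep(mean(y[tt]), length(tt))
               else stats::predict(fit, tt)$y
      y[tt] <- y[tt] - trend + pre_level
    } else {
      y[tt] <- pre_level
    }
    # re-level the tail so a corrected baseline shift does not re-enter
    if (b < n) {
      post_level <- stats::median(y[(b + 1):min(n, b + w)])
      y[(b + 1):n] <- y[(b + 1):n] - (post_level - pre_level)
    }
  }
  y
}

#' Spline + Savitzky-Golay motion correction
#'
#' Detects motion-contaminated samples with a robust jump detector
#' (sample-to-sample differences beyond 6 robust SDs), removes baseline
#' shifts by subtracting a smoothing-spline trend inside each flagged
#' segment and re-anchoring the following baseline, then attenuates
#' residual spikes by replacing still-flagged samples with their
#' Savitzky-Golay smoothed value (order 3, window `frame_s` seconds, forced
#' odd). Samples never flagged are untouched, so clean channels pass
#' through unchanged.
#'
#' @param rec a `nirs_recording` with `stage = "od"`.
#' @param p spline smoothing parameter (close fit near 1; default 0.99).
#' @param frame_s Savitzky-Golay frame length, s (default 10).
#' @return the corrected recording, still `stage = "od"`.
#' @export
splinesg_correct <- function(rec, p = 0.99, frame_s = 10) {
  stopifnot(identical(rec$stage, "od"))
  win <- as.integer(round(frame_s * rec$fs))
  if (win < 3) stop("Savitzky-Golay frame shorter than 3 samples")
  if (win %% 2 == 0) win <- win + 1L
  out <- rec$data
  pad <- max(1L, as.integer(round(0.2 * rec$fs)))
  for (k in seq_len(dim(out)[1])) {
    for (i in seq_len(dim(out)[2])) {
      x <- spline_correct_channel(rec$data[k, i, ], rec$fs, p)
      flag <- detect_motion(x, rec$fs)
      if (any(flag)) {
        idx <- which(flag)
        idx <- unique(pmin(length(x), pmax(1L, rep(idx, each = 2 * pad + 1) +
                                             seq(-pad, pad))))
        sg <- signal::sgolayfilt(x, p = 3, n = min(win, length(x) - (length(x) + 1) %% 2))
        x[idx] <- sg[idx]
      }
      out[k, i, ] <- x
    }
  }
  rec$data <- out
  rec
}

#' Zero-phase low-pass filter
#'
#' Third-order Butterworth low-pass applied forward and backward
#' (zero phase), removing cardiac and other high-frequency content.
#'
#' @param rec a `nirs_recording` with `stage = "od"`.
#' @param fc cutoff frequency, Hz (default 0.5; must be below Nyquist).
#' @return the filtered recording.
#' @export
lowpass <- function(rec, fc = 0.5) {
  stopifnot(identical(rec$stage, "od"))
  if (fc >= rec$fs / 2) stop("cutoff at or above the Nyquist frequency")
  bf <- signal::butter(3, fc / (rec$fs / 2), type = "low")
  out <- rec$data
  nt <- dim(out)[3]
  pad <- min(nt - 1, as.integer(round(10 * rec$fs)))
  for (k in seq_len(dim(out)[1])) {
    for (i in seq_len(dim(out)[2])) {
      x <- rec$data[k, i, ]
      m <- mean(x)
      # reflect-pad around a zero-mean trace to suppress edge transients
      xp <- c(rev((x - m)[seq_len(pad)]), x - m,
              rev((x - m)[seq(nt - pad + 1, nt)]))
      yp <- signal::filtfilt(bf, xp)
      out[k, i, ] <- yp[pad + seq_len(nt)] + m
    }
  }
  rec$data <- out
  rec
}

#' Convert optical density to chromophore concentration
#'
#' Modified Beer-Lambert law: per channel,
#' `c(dHbO, dHbR) = solve(E, dOD / (L * ppf))` with `E` the 2 x 2 extinction
#' matrix (1/(mm*uM)), `L` the source-detector separation (mm) and `ppf` the
#' partial pathlength factor. Output concentrations are in micromolar.
#'
#' @param rec a `nirs_recording` with `stage = "od"` and two wavelengths.
#' @param ppf partial pathlength factor (scalar or per-channel; default 1).
#' @return the recording with `stage = "concentration"`; the second data
#'   dimension indexes `c("HbO", "HbR")`.
#' @export
od_to_conc <- function(rec, ppf = 1) {
  stopifnot(identical(rec$stage, "od"), dim(rec$data)[2] == 2)
  E <- extinction_coefficients(rec$wavelengths)
  if (abs(det(E)) < 1e-12) stop("singular extinction matrix")
  Einv <- solve(E)
  L <- rec$channels$separation
  ppf <- rep(ppf, length.out = length(L))
  conc <- rec$data
  for (k in seq_len(dim(conc)[1])) {
    od <- rbind(rec$data[k, 1, ], rec$data[k, 2, ]) / (L[k] * ppf[k])
    conc[k, , ] <- Einv %*% od
  }
  rec$data <- conc
  rec$stage <- "concentration"
  rec$chromophores <- c("HbO", "HbR")
  rec
}

#' Forward Beer-Lambert: concentration to optical density
#'
#' Inverse of [od_to_conc()]; used when projecting estimated HRFs back to
#' channel optical density for image reconstruction.
#'
#' @param conc matrix 2 x T (`HbO`, `HbR`) in micromolar.
#' @param separation channel separation, mm.
#' @param wavelengths two wavelengths, nm.
#' @param ppf partial pathlength factor.
#' @return matrix 2 x T of optical density (rows = wavelengths).
#' @export
conc_to_od <- function(conc, separation, wavelengths = c(760, 850), ppf = 1) {
  E <- extinction_coefficients(wavelengths)
  (E %*% conc) * separation * ppf
}

#' Reject noisy blocks and under-sampled subjects
#'
#' Drops blocks whose within-block concentration range exceeds
#' `range_max`, then excludes any subject left with fewer than `min_blocks`
#' blocks in either condition.
#'
#' @param block_table data frame with columns `subject`, `condition`,
#'   `block`, and `range` (within-block concentration range, uM).
#' @param min_blocks minimum retained blocks per condition (default 5, i.e.
#'   subjects with four or fewer are excluded).
#' @param range_max amplitude-threshold for block rejection, uM.
#' @return the filtered table, with excluded subjects' rows removed; the
#'   excluded subject ids are attached as attribute `"excluded_subjects"`.
#' @export
reject_blocks_and_subjects <- function(block_table, min_blocks = 5,
                                       range_max = 30) {
  kept <- block_table[block_table$range <= range_max, , drop = FALSE]
  counts <- stats::aggregate(block ~ subject + condition, kept, length)
  # a subject must reach min_blocks in every condition present in the input
  conds <- unique(block_table$condition)
  excluded <- unique(unlist(lapply(unique(block_table$subject), function(s) {
    for (cn in conds) {
      n <- counts$block[counts$subject == s & counts$condition == cn]
      if (length(n) == 0 || n < min_blocks) return(s)
    }
    NULL
  })))
  out <- kept[!(kept$subject %in% excluded), , drop = FALSE]
  attr(out, "excluded_subjects") <- excluded
  out
}
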