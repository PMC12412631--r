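#' Synthetic block-design recordings with known ground truth
#'
#' Generates paradigm schedules and two-wavelength intensity recordings that
#' emulate the statistical structure a block-design fNIRS analysis assumes:
#' cortical activation with a canonical hemodynamic response on chosen brain
#' vertices, a shared superficial (scalp) physiological signal picked up by
#' the short-separation channels, cardiac oscillation, slow drift, spike and
#' baseline-shift motion artifacts, and white measurement noise.
#'
#' @name synth
NULL

#' Generate a block-design paradigm schedule
#'
#' 18 task blocks of 18 s (9 congruent, 9 incongruent, order randomly
#' permuted), preceded by 20 s of rest, with inter-block rest jittered
#' uniformly between 10 and 15 s.
#'
#' @param seed integer seed; the schedule is reproducible from it.
#' @param n_blocks_per_condition blocks per condition (default 9).
#' @param block_duration block length, s.
#' @param initial_rest rest before the first block, s.
#' @param isi_range inter-stimulus rest range, s.
#' @return a `paradigm_schedule`: data frame `blocks` with `onset`,
#'   `duration`, `condition`, plus the run duration.
#' @export
generate_schedule <- function(seed, n_blocks_per_condition = 9,
                              block_duration = 18, initial_rest = 20,
                              isi_range = c(10, 15)) {
  set.seed(seed)
  n <- 2 * n_blocks_per_condition
  cond <- sample(rep(c("congruent", "incongruent"), n_blocks_per_condition))
  isi <- stats::runif(n - 1, isi_range[1], isi_range[2])
  onsets <- initial_rest + c(0, cumsum(block_duration + isi))
  blocks <- data.frame(onset = onsets, duration = block_duration,
                       condition = cond, stringsAsFactors = FALSE)
  structure(list(blocks = blocks,
                 duration = onsets[n] + block_duration + 25,
                 initial_rest = initial_rest, isi_range = isi_range,
                 seed = seed),
            class = "paradigm_schedule")
}

#' Canonical double-gamma hemodynamic response function
#'
#' Peak near 6 s with an undershoot near 16 s, normalized to unit peak.
#'
#' @param t time points, s (response is 0 for `t < 0`).
#' @param peak,undershoot gamma mode times, s.
#' @param ratio undershoot-to-peak amplitude ratio.
#' @return numeric vector of the same length as `t`.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  a1 <- peak; a2 <- undershoot; b <- 1
  h <- stats::dgamma(t, shape = a1 / b, rate = 1 / b) -
    ratio * stats::dgamma(t, shape = a2 / b, rate = 1 / b)
  h[t < 0] <- 0
  if (max(h) > 0) h <- h / max(h)
  h
}

# block regressor: boxcar convolved with the canonical HRF, unit peak
block_regressor <- function(time, onsets, duration, fs) {
  box <- rep(0, length(time))
  for (o in onsets) box[time >= o & time < o + duration] <- 1
  h <- canonical_hrf(seq(0, 30, by = 1 / fs))
  r <- stats::convolve(box, rev(h), type = "open")[seq_along(box)] / fs
  # unit peak for an isolated block so amplitudes are in micromolar
  box1 <- rep(0, length(time)); box1[time >= 0 & time < duration] <- 1
  r1 <- stats::convolve(box1, rev(h), type = "open")[seq_along(box1)] / fs
  r / max(r1)
}

#' Define the simulation ground truth
#'
#' Activation is a lateral Gaussian-edged disc of brain vertices around each
#' center; condition amplitudes are in micromolar with HbR opposite in sign
#' to HbO. The superficial signal is band-limited noise shared across every
#' scalp vertex.
#'
#' @param head a `head_model`.
#' @param centers list of `c(x, y)` activation centers, mm (one entry per
#'   activation site; all sites share the condition amplitudes).
#' @param radius activation disc radius, mm.
#' @param hbo_amplitude named vector of HbO amplitudes per condition, uM.
#' @param hbr_amplitude named vector of HbR amplitudes per condition, uM
#'   (typically negative).
#' @param superficial_amplitude scalp HbO-equivalent amplitude, uM.
#' @param superficial_spatial_sd relative SD of the smooth spatial gain
#'   field modulating the shared superficial time course across the scalp
#'   (0 gives a spatially uniform superficial signal).
#' @param seed seed for the superficial gain field, signal phases and
#'   artifact draws.
#' @return a `ground_truth` object.
#' @export
ground_truth <- function(head,
                         centers = list(c(-70, 0), c(70, 0)),
                         radius = 10,
                         hbo_amplitude = c(congruent = 5, incongruent = 10),
                         hbr_amplitude = c(congruent = -1.5, incongruent = -3),
                         superficial_amplitude = 0.4,
                         superficial_spatial_sd = 0.5,
                         seed = 1) {
  stopifnot(all(hbo_amplitude >= 0), all(hbr_amplitude <= 0))
  vtx <- head$vertices
  brain <- vtx[vtx$surface == "brain", ]
  w <- rep(0, nrow(vtx))
  for (ctr in centers) {
    d <- sqrt((brain$x - ctr[1])^2 + (brain$y - ctr[2])^2)
    wi <- exp(-d^2 / (2 * (radius / 2)^2))
    wi[d > radius] <- 0
    w[brain$vertex_id] <- pmax(w[brain$vertex_id], wi)
  }
  # superficial gain: every scalp vertex carries the same time course,
  # scaled by a smooth (20 mm correlation length) spatial gain field
  scalp <- vtx$surface == "scalp"
  sup_w <- as.numeric(scalp)
  if (superficial_spatial_sd > 0) {
    set.seed(seed)
    sv <- vtx[scalp, ]
    z <- stats::rnorm(nrow(sv))
    K <- exp(-(outer(sv$x, sv$x, "-")^2 + outer(sv$y, sv$y, "-")^2) /
               (2 * 20^2))
    field <- as.numeric(K %*% z)
    field <- (field - mean(field)) / stats::sd(field)
    sup_w[scalp] <- 1 + superficial_spatial_sd * field
  }
  structure(list(head = head, weights = w, centers = centers, radius = radius,
                 active_vertices = vtx$vertex_id[w > 0],
                 hbo_amplitude = hbo_amplitude, hbr_amplitude = hbr_amplitude,
                 superficial_amplitude = superficial_amplitude,
                 superficial_weights = sup_w,
                 superficial_spatial_sd = superficial_spatial_sd, seed = seed),
            class = "ground_truth")
}

#' Default noise and nuisance parameters for the simulator
#'
#' Optical-density amplitudes for cardiac (1.1 Hz, above the 0.5 Hz low-pass
#' so the filter is exercised), slow sinusoidal and linear drift, the
#' relative white-noise level on intensity, motion-artifact counts and
#' magnitudes, and the fraction of dead (low-intensity) channels. The
#' defaults give raw channel signal-to-noise ratios of roughly 40-60.
#'
#' @param i0 baseline detected intensity, V.
#' @param cardiac_od,drift_slow_od,drift_linear_od,white_frac,spike_od,shift_od
#'   nuisance magnitudes (optical density except `white_frac`, relative).
#' @param n_spikes,n_shifts motion artifact event counts per recording.
#' @param dead_frac fraction of channels rendered near-dark to exercise the
#'   intensity pruning threshold.
#' @return named list of simulator parameters.
#' @export
default_noise_params <- function(i0 = 0.02, cardiac_od = 0.02,
                                 drift_slow_od = 0.005, drift_linear_od = 0.005,
                                 white_frac = 0.005, n_spikes = 4,
                                 spike_od = 0.3, n_shifts = 2, shift_od = 0.1,
                                 dead_frac = 0) {
  list(i0 = i0, cardiac_od = cardiac_od, drift_slow_od = drift_slow_od,
       drift_linear_od = drift_linear_od, white_frac = white_frac,
       n_spikes = n_spikes, spike_od = spike_od, n_shifts = n_shifts,
       shift_od = shift_od, dead_frac = dead_frac)
}

#' @keywords internal
new_recording <- function(layout_name, fs, stage, data, wavelengths,
                          channels, schedule, time) {
  structure(list(layout_name = layout_name, fs = fs, stage = stage,
                 data = data, wavelengths = wavelengths, channels = channels,
                 schedule = schedule, time = time),
            class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf("<nirs_recording '%s'> stage=%s, %d channels x %d x %d samples @ %.1f Hz\n",
              x$layout_name, x$stage, dim(x$data)[1], dim(x$data)[2],
              dim(x$data)[3], x$fs))
  invisible(x)
}

# band-limited superficial signal: sum of low-frequency sinusoids with
# seeded random phases plus smoothed noise, unit-SD normalized
superficial_signal <- function(time, fs) {
  freqs <- c(0.04, 0.08, 0.1, 0.12)
  s <- rowSums(vapply(freqs, function(f)
    stats::rnorm(1) * sin(2 * pi * f * time + stats::runif(1, 0, 2 * pi)),
    numeric(length(time))))
  w <- stats::rnorm(length(time))
  k <- max(3L, as.integer(fs))  # ~1 s moving average
  w <- stats::filter(w, rep(1 / k, k), sides = 2)
  w[is.na(w)] <- 0
  s <- s + as.numeric(w) * 3
  as.numeric(s / stats::sd(s))
}

#' Simulate a two-wavelength intensity recording
#'
#' Places a canonical-HRF block response (scaled by condition amplitude) on
#' the active brain vertices and the shared superficial signal on all scalp
#' vertices, projects vertex chromophore changes to channel optical density
#' through the sensitivity matrix and extinction coefficients, and converts
#' to detected intensity `I = I0 * exp(-OD_total)` where `OD_total` also
#' carries cardiac, drift, and motion-artifact terms; white noise is added
#' on intensity.
#'
#' @param layout a `probe_layout`.
#' @param S a `sensitivity_matrix` built for `layout`.
#' @param truth a `ground_truth`.
#' @param schedule a `paradigm_schedule`.
#' @param noise_params see [default_noise_params()]; pass magnitudes of 0
#'   for a noiseless recording.
#' @param seed integer seed; the recording is reproducible from it.
#' @param fs sampling frequency, Hz (24.4 for the sparse layout, 17.5 for
#'   HD, following the acquisition rates the two arrays run at).
#' @return a `nirs_recording` with `stage = "intensity"`.
#' @export
simulate_recording <- function(layout, S, truth, schedule,
                               noise_params = default_noise_params(),
                               seed = 1,
                               fs = if (identical(layout$name, "hd")) 17.5 else 24.4) {
  np <- noise_params
  if (np$i0 <= 0) stop("non-positive baseline intensity I0")
  set.seed(seed)
  time <- seq(0, schedule$duration, by = 1 / fs)
  nt <- length(time)
  nch <- nrow(layout$channels)
  conds <- names(truth$hbo_amplitude)

  # low-rank vertex chromophore time courses: patterns (vertices x k) and
  # temporal factors (k x time)
  sup <- superficial_signal(time, fs) * truth$superficial_amplitude
  scalp_pat <- truth$superficial_weights
  pat_hbo <- cbind(sapply(conds, function(cn) truth$weights * truth$hbo_amplitude[[cn]]),
                   scalp_pat)
  pat_hbr <- cbind(sapply(conds, function(cn) truth$weights * truth$hbr_amplitude[[cn]]),
                   -0.25 * scalp_pat)
  temporal <- rbind(
    t(sapply(conds, function(cn) {
      b <- schedule$blocks
      block_regressor(time, b$onset[b$condition == cn], b$duration[1], fs)
    })),
    sup
  )

  E <- extinction_coefficients(as.numeric(names(S$values)))
  od <- array(0, dim = c(nch, length(S$values), nt))
  for (i in seq_along(S$values)) {
    mix <- E[i, "HbO"] * pat_hbo + E[i, "HbR"] * pat_hbr
    od[, i, ] <- (S$values[[i]] %*% mix) %*% temporal
  }

  # channel-wise nuisance terms in optical density: cardiac oscillation,
  # a smooth low-order instrument drift trend, and a linear drift
  u <- time / max(time)
  drift_basis <- cbind(u, u^2, u^3)
  for (k in seq_len(nch)) {
    cardiac <- np$cardiac_od * sin(2 * pi * 1.1 * time + stats::runif(1, 0, 2 * pi))
    slow <- drop(drift_basis %*% stats::rnorm(3))
    slow <- slow - mean(slow)
    if (stats::sd(slow) > 0) slow <- slow / stats::sd(slow) * np$drift_slow_od
    lin <- np$drift_linear_od * stats::runif(1, -1, 1) * u
    for (i in seq_len(dim(od)[2])) od[k, i, ] <- od[k, i, ] + cardiac + slow + lin
  }

  # motion artifacts: single-sample-scale spikes and baseline shifts
  if (np$n_spikes > 0) {
    for (e in seq_len(np$n_spikes)) {
      k <- sample.int(nch, 1)
      t0 <- stats::runif(1, 10, max(time) - 10)
      amp <- np$spike_od * stats::runif(1, 0.5, 1.5) * sample(c(-1, 1), 1)
      pulse <- amp * exp(-abs(time - t0) / 0.12)
      for (i in seq_len(dim(od)[2])) od[k, i, ] <- od[k, i, ] + pulse
    }
  }
  if (np$n_shifts > 0) {
    for (e in seq_len(np$n_shifts)) {
      k <- sample.int(nch, 1)
      t0 <- stats::runif(1, 10, max(time) - 10)
      amp <- np$shift_od * stats::runif(1, 0.5, 1.5) * sample(c(-1, 1), 1)
      for (i in seq_len(dim(od)[2])) od[k, i, ] <- od[k, i, ] + amp * (time >= t0)
    }
  }

  # baseline intensity falls off with source-detector separation
  # (effective attenuation ~0.14/mm plus inverse-square), normalized so a
  # 30 mm channel detects i0; short channels are therefore much brighter
  # and their optical-density noise correspondingly smaller, as in practice
  rho <- layout$channels$separation
  i0_ch <- np$i0 * exp(-0.14 * (rho - 30)) * (30 / rho)^2
  intensity <- array(0, dim = dim(od))
  for (k in seq_len(nch)) intensity[k, , ] <- i0_ch[k] * exp(-od[k, , ])
  if (np$white_frac > 0) {
    intensity <- intensity +
      array(stats::rnorm(length(intensity), 0, np$white_frac * np$i0),
            dim = dim(intensity))
    floor_i <- np$i0 * 1e-6
    intensity[intensity <= floor_i] <- floor_i
  }
  if (np$dead_frac > 0) {
    ndead <- floor(np$dead_frac * nch)
    if (ndead > 0) {
      dead <- sample.int(nch, ndead)
      for (k in dead)
        intensity[k, , ] <- intensity[k, , ] * 0.0005 / i0_ch[k]
    }
  }

  new_recording(layout$name, fs, "intensity", intensity,
                as.numeric(names(S$values)), layout$channels, schedule, time)
}
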