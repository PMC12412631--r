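#' Block-delta statistics, ROI selection, and the cluster permutation test
#'
#' The unit of analysis is the block delta: mean concentration between 7
#' and 18 s after block onset minus the mean over the 2 s preceding onset.
#' Per-channel (or per-vertex) t-statistics across blocks feed max-t
#' selection within regions of interest, paired array comparisons, and a
#' cluster-based sign-flip permutation test over channels.
#'
#' @name blockstats
NULL

#' Block delta of a concentration trace
#'
#' Mean over `[onset + 7, onset + 18)` minus mean over `[onset - 2, onset)`
#' seconds (windows include their start and exclude their end sample).
#'
#' @param trace numeric concentration trace.
#' @param onset block onset, s.
#' @param fs sampling frequency, Hz.
#' @param time optional time vector (defaults to `(0:(n-1))/fs`).
#' @param active,baseline window offsets relative to onset, s.
#' @return the delta (same units as the trace).
#' @export
block_delta <- function(trace, onset, fs, time = NULL,
                        active = c(7, 18), baseline = c(-2, 0)) {
  if (is.null(time)) time <- (seq_along(trace) - 1) / fs
  a <- time >= onset + active[1] & time < onset + active[2]
  b <- time >= onset + baseline[1] & time < onset + baseline[2]
  if (!any(a) || !any(b))
    stop("trace does not cover the block delta windows")
  mean(trace[a]) - mean(trace[b])
}

#' One-sample t statistic of block deltas
#'
#' `t = mean / (sd / sqrt(n))` with the n-1 sample standard deviation.
#' Zero-variance inputs give a signed infinite t, flagged by `degenerate`.
#'
#' @param deltas numeric vector, n >= 2.
#' @return list with `t`, `mean`, `se`, `n`, `degenerate`.
#' @export
tstat <- function(deltas) {
  n <- length(deltas)
  stopifnot(n >= 2)
  m <- mean(deltas)
  se <- stats::sd(deltas) / sqrt(n)
  if (se == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    return(list(t = t, mean = m, se = 0, n = n, degenerate = TRUE))
  }
  list(t = m / se, mean = m, se = se, n = n, degenerate = FALSE)
}

#' Two-tailed Student critical value
#'
#' @param n number of subjects (df = n - 1).
#' @param alpha two-tailed level (default 0.05).
#' @return the critical |t|.
#' @export
t_critical <- function(n, alpha = 0.05) {
  if (n < 2) stop("n must be at least 2")
  stats::qt(1 - alpha / 2, df = n - 1)
}

#' Select ROI vertices from HD channel sensitivity
#'
#' Stage 1 keeps vertices whose sensitivity summed over the ROI channels
#' exceeds `threshold` after the summed map is normalized to a maximum of
#' 1; stage 2 keeps those whose value strictly exceeds the stage-1 mean.
#' The returned vertex set is shared by both layouts.
#'
#' @param S a `sensitivity_matrix` (HD layout).
#' @param roi_channels channel row indices into `S$channels`.
#' @param threshold normalized sensitivity cutoff (default 0.01).
#' @param surface restrict to one surface (default `"brain"`).
#' @return vertex ids.
#' @export
select_roi_vertices <- function(S, roi_channels, threshold = 0.01,
                                surface = "brain") {
  tot <- Reduce(`+`, lapply(S$values, function(v)
    colSums(v[roi_channels, , drop = FALSE])))
  tot <- tot / max(tot)
  on_surface <- S$vertices$surface == surface
  stage1 <- which(tot > threshold & on_surface)
  if (length(stage1) == 0) stop("no vertices above the sensitivity threshold")
  keep <- stage1[tot[stage1] > mean(tot[stage1])]
  S$vertices$vertex_id[keep]
}

#' Max-t channel/vertex selection within an ROI
#'
#' For HbO the candidate with the highest t wins; for HbR the lowest
#' (activation decreases HbR). Ties break to the lowest id.
#'
#' @param t_values named numeric vector of t statistics (names = ids).
#' @param chromophore `"HbO"` or `"HbR"`.
#' @return the selected id (integer).
#' @export
select_max_t <- function(t_values, chromophore = "HbO") {
  if (length(t_values) == 0) stop("no unpruned ROI candidates")
  ids <- as.integer(names(t_values))
  ord <- order(ids)
  t_values <- t_values[ord]; ids <- ids[ord]
  pick <- if (chromophore == "HbR") which.min(t_values) else which.max(t_values)
  ids[pick]
}

#' Two-tailed paired Student's t test
#'
#' @param a,b paired measurements (equal length); pairs with a missing
#'   member are dropped.
#' @return list with `t`, `p`, `mean_diff`, `se`, `n`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  d <- a[ok] - b[ok]
  n <- length(d)
  if (n < 2) stop("fewer than two complete pairs")
  m <- mean(d); se <- stats::sd(d) / sqrt(n)
  if (se == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t <- m / se
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  list(t = t, p = p, mean_diff = m, se = se, n = n)
}

#' Per-channel group t map
#'
#' Group t = mean over subjects' block-averages divided by the standard
#' error across subjects. Channels with fewer than two contributing
#' subjects are marked unavailable (`NA`).
#'
#' @param subject_means matrix subjects x channels (NA = channel pruned for
#'   that subject).
#' @return data frame with `channel`, `mean`, `se`, `t`, `n`, `degenerate`.
#' @export
group_summary <- function(subject_means) {
  nch <- ncol(subject_means)
  out <- data.frame(channel = seq_len(nch), mean = NA_real_, se = NA_real_,
                    t = NA_real_, n = 0L, degenerate = FALSE)
  for (k in seq_len(nch)) {
    v <- subject_means[, k]
    v <- v[is.finite(v)]
    out$n[k] <- length(v)
    if (length(v) >= 2) {
      out$mean[k] <- mean(v)
      out$se[k] <- stats::sd(v) / sqrt(length(v))
      if (out$se[k] == 0) {
        out$degenerate[k] <- TRUE
        out$t[k] <- if (out$mean[k] == 0) 0 else sign(out$mean[k]) * Inf
      } else out$t[k] <- out$mean[k] / out$se[k]
    }
  }
  out
}

# connected components of channels under distance <= radius adjacency,
# restricted to the supplied members
spatial_clusters <- function(positions, members, radius) {
  if (length(members) == 0) return(list())
  comp <- rep(NA_integer_, length(members))
  nc <- 0
  for (i in seq_along(members)) {
    if (!is.na(comp[i])) next
    nc <- nc + 1
    queue <- i
    comp[i] <- nc
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      d <- sqrt(rowSums((positions[members, , drop = FALSE] -
                           matrix(positions[members[cur], ],
                                  length(members), ncol(positions),
                                  byrow = TRUE))^2))
      nb <- which(d <= radius & is.na(comp))
      comp[nb] <- nc
      queue <- c(queue, nb)
    }
  }
  split(members, comp)
}

#' Cluster-based sign-flip permutation test over channels
#'
#' Computes the observed per-channel group t from subject-level deltas,
#' thresholds at the two-tailed critical t, joins supra-threshold channels
#' into clusters by spatial adjacency (center distance `<= radius`), and
#' scores each cluster by its mass (sum of |t|). The null distribution of
#' the maximum cluster mass is built by randomly flipping the sign of whole
#' subjects; cluster p-values are `(1 + #null >= observed) / (1 + n_perm)`.
#' Channels outside significant clusters are masked.
#'
#' @param channel_positions matrix channels x 2 (or 3) of channel-center
#'   coordinates, mm.
#' @param subject_deltas matrix subjects x channels of per-subject deltas
#'   (e.g. block-averaged concentration changes).
#' @param radius adjacency radius, mm (default 33).
#' @param alpha level for both the channel threshold and cluster
#'   significance (default 0.05).
#' @param n_perm number of sign-flip permutations (default 5000).
#' @param seed RNG seed for the permutations.
#' @return list with `t` (observed per-channel t), `t_crit`, `clusters`
#'   (list of channel index vectors), `cluster_mass`, `cluster_p`, `mask`
#'   (logical; TRUE = channel inside a significant cluster), `n_perm`.
#' @export
cluster_permutation <- function(channel_positions, subject_deltas,
                                radius = 33, alpha = 0.05, n_perm = 5000,
                                seed = 1) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  ns <- nrow(subject_deltas)
  stopifnot(ns >= 2)
  set.seed(seed)
  tcrit <- t_critical(ns, alpha)

  col_t <- function(X) {
    m <- colMeans(X)
    se <- sqrt((colSums(X^2) - ns * m^2) / (ns - 1) / ns)
    ifelse(se == 0, sign(m) * Inf, m / se)
  }
  cluster_masses <- function(tv) {
    supra <- which(abs(tv) > tcrit)
    cl <- spatial_clusters(channel_positions, supra, radius)
    vapply(cl, function(idx) sum(abs(tv[idx])), numeric(1))
  }

  t_obs <- col_t(subject_deltas)
  supra <- which(abs(t_obs) > tcrit)
  clusters <- spatial_clusters(channel_positions, supra, radius)
  mass <- vapply(clusters, function(idx) sum(abs(t_obs[idx])), numeric(1))

  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    s <- sample(c(-1, 1), ns, replace = TRUE)
    mp <- cluster_masses(col_t(subject_deltas * s))
    null_max[p] <- if (length(mp) == 0) 0 else max(mp)
  }
  cluster_p <- vapply(mass, function(m)
    (1 + sum(null_max >= m)) / (1 + n_perm), numeric(1))
  mask <- rep(FALSE, ncol(subject_deltas))
  for (i in seq_along(clusters))
    if (cluster_p[i] <= alpha) mask[clusters[[i]]] <- TRUE
  list(t = t_obs, t_crit = tcrit, clusters = clusters,
       cluster_mass = mass, cluster_p = cluster_p, mask = mask,
       n_perm = n_perm)
}

#' Block deltas for every block of a recording
#'
#' @param rec a `nirs_recording` with `stage = "concentration"`.
#' @param channel channel index.
#' @param chromophore `"HbO"` or `"HbR"`.
#' @return data frame with `block`, `condition`, `delta`.
#' @export
recording_block_deltas <- function(rec, channel, chromophore = "HbO") {
  ci <- match(chromophore, c("HbO", "HbR"))
  trace <- rec$data[channel, ci, ]
  b <- rec$schedule$blocks
  data.frame(block = seq_len(nrow(b)), condition = b$condition,
             delta = vapply(seq_len(nrow(b)), function(i)
               block_delta(trace, b$onset[i], rec$fs, time = rec$time),
               numeric(1)))
}
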