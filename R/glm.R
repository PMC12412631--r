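#' Channel-space GLM with Gaussian temporal basis
#'
#' Per-channel ordinary-least-squares estimation of the hemodynamic
#' response from -2 to 23 s around block onset, using a consecutive
#' sequence of Gaussian basis functions (1 s width and step) per condition,
#' polynomial drift regressors of order 0-3, and one short-separation
#' nuisance regressor chosen per long channel by maximum correlation.
#'
#' @name glm
NULL

HRF_WINDOW <- c(-2, 23)

#' Select the short-separation regressor channel
#'
#' Returns the short-separation channel whose concentration trace has the
#' greatest Pearson correlation with the long channel's trace; ties break
#' to the lowest channel index.
#'
#' @param long_trace numeric vector, the long channel's concentration trace.
#' @param ss_traces matrix (channels x time) of short-separation traces.
#' @param ss_ids channel ids corresponding to the rows of `ss_traces`.
#' @return the selected id (element of `ss_ids`).
#' @export
select_ss_channel <- function(long_trace, ss_traces, ss_ids = seq_len(nrow(ss_traces))) {
  if (is.null(dim(ss_traces))) ss_traces <- matrix(ss_traces, nrow = 1)
  if (nrow(ss_traces) == 0) stop("no short channels")
  r <- apply(ss_traces, 1, function(s) {
    if (stats::sd(s) == 0 || stats::sd(long_trace) == 0) return(-Inf)
    stats::cor(long_trace, s)
  })
  ord <- order(ss_ids)
  r <- r[ord]; ids <- ss_ids[ord]
  ids[which.max(r)]  # which.max takes the first (lowest id) on ties
}

#' Build the GLM design matrix
#'
#' Per condition, Gaussian bumps (SD 1 s) centered at `onset + c` for
#' integer offsets c = -2, -1, ..., 23 (26 centers, both endpoints
#' included), summed over that condition's blocks; plus global polynomial
#' drift columns of order 0..`drift_order`. The per-channel
#' short-separation regressor is appended at fit time.
#'
#' @param schedule a `paradigm_schedule`.
#' @param fs sampling frequency, Hz.
#' @param duration run duration, s (defaults to the schedule's).
#' @param drift_order polynomial drift order (default 3).
#' @param basis_width Gaussian SD, s.
#' @param basis_step spacing of centers, s.
#' @return a `design_matrix`: list with `X` (time x columns), `labels`,
#'   `time`, `condition_columns` (named list of column indices),
#'   `basis_offsets`, and `empty_conditions` (conditions with no blocks).
#' @export
build_design <- function(schedule, fs, duration = schedule$duration,
                         drift_order = 3, basis_width = 1, basis_step = 1) {
  if (fs <= 0) stop("fs must be positive")
  time <- seq(0, duration, by = 1 / fs)
  offsets <- seq(HRF_WINDOW[1], HRF_WINDOW[2], by = basis_step)
  conds <- sort(unique(c(schedule$blocks$condition, schedule$condition_levels)))
  cols <- list(); labels <- character(0); cond_cols <- list()
  for (cn in conds) {
    onsets <- schedule$blocks$onset[schedule$blocks$condition == cn]
    block <- vapply(offsets, function(off) {
      col <- rep(0, length(time))
      for (o in onsets) col <- col + exp(-(time - (o + off))^2 / (2 * basis_width^2))
      col
    }, numeric(length(time)))
    cond_cols[[cn]] <- length(labels) + seq_along(offsets)
    cols[[cn]] <- block
    labels <- c(labels, sprintf("%s_g%+d", cn, offsets))
  }
  drift <- vapply(0:drift_order, function(d) (time / max(time))^d,
                  numeric(length(time)))
  labels <- c(labels, sprintf("drift_%d", 0:drift_order))
  X <- cbind(do.call(cbind, cols), drift)
  colnames(X) <- labels
  empty <- conds[vapply(conds, function(cn)
    sum(schedule$blocks$condition == cn) == 0, logical(1))]
  structure(list(X = X, labels = labels, time = time,
                 condition_columns = cond_cols, basis_offsets = offsets,
                 basis_width = basis_width, fs = fs,
                 drift_columns = ncol(X) - drift_order:0,
                 empty_conditions = empty),
            class = "design_matrix")
}

# solve OLS for y against [X, ss] via normal equations; all-zero columns
# (e.g. the basis of a condition with no blocks) are dropped and their
# coefficients reported as zero
ols_with_ss <- function(X, y, ss = NULL) {
  Xf <- if (is.null(ss)) X else cbind(X, ss = ss - mean(ss))
  zero <- colSums(abs(Xf)) == 0
  if (any(zero)) {
    sub <- ols_with_ss_core(Xf[, !zero, drop = FALSE], y)
    beta <- rep(0, ncol(Xf)); names(beta) <- colnames(Xf)
    beta[!zero] <- sub$beta
    return(list(beta = beta, resid = sub$resid, sigma2 = sub$sigma2))
  }
  ols_with_ss_core(Xf, y)
}

ols_with_ss_core <- function(Xf, y) {
  G <- crossprod(Xf)
  qrG <- qr(G)
  if (qrG$rank < ncol(Xf)) {
    d <- sqrt(diag(G))
    C <- G / outer(d, d)
    bad <- colnames(Xf)[colSums(abs(C) > 1 - 1e-8) > 1]
    stop("rank-deficient design; collinear columns: ",
         paste(unique(bad), collapse = ", "))
  }
  beta <- solve(qrG, crossprod(Xf, y))
  resid <- y - Xf %*% beta
  list(beta = drop(beta), resid = drop(resid),
       sigma2 = sum(resid^2) / (length(y) - ncol(Xf)))
}

#' Fit the channel-space GLM
#'
#' Ordinary least squares per channel and chromophore. For each long
#' channel the short-separation regressor is the concentration trace (same
#' chromophore) of the most-correlated unpruned short channel. The HRF is
#' reconstructed from the Gaussian basis coefficients on the -2..23 s grid.
#'
#' @param rec a `nirs_recording` with `stage = "concentration"`.
#' @param design a `design_matrix` built for the recording's schedule/fs.
#' @param use_ss logical; include the short-separation regressor
#'   (default `TRUE` when the layout has short channels).
#' @param keep optional logical vector of channels to fit (e.g. a prune
#'   report's `keep`); defaults to all.
#' @return an `hrf_estimate`: list with `hrf` (4-d array: channel x
#'   condition x chromophore x time), `hrf_time`, `coefficients`,
#'   `sigma2` (channel x chromophore residual variance), `ss_choice`,
#'   `conditions`, `chromophores`, `fs`.
#' @export
fit_glm <- function(rec, design, use_ss = TRUE, keep = NULL) {
  stopifnot(identical(rec$stage, "concentration"))
  nch <- dim(rec$data)[1]
  if (is.null(keep)) keep <- rep(TRUE, nch)
  is_short <- rec$channels$is_short
  ss_idx <- which(is_short & keep)
  long_idx <- which(!is_short & keep)
  if (use_ss && length(ss_idx) == 0) stop("no short channels")
  conds <- names(design$condition_columns)
  chrom <- c("HbO", "HbR")
  nt_hrf <- round(diff(HRF_WINDOW) * rec$fs) + 1
  hrf_time <- HRF_WINDOW[1] + (seq_len(nt_hrf) - 1) / rec$fs
  # basis evaluated on the output grid
  B <- vapply(design$basis_offsets, function(off)
    exp(-(hrf_time - off)^2 / (2 * design$basis_width^2)), numeric(nt_hrf))

  X <- design$X
  nt <- min(nrow(X), dim(rec$data)[3])
  X <- X[seq_len(nt), , drop = FALSE]
  zero_cols <- colSums(abs(X)) == 0
  Xn <- X[, !zero_cols, drop = FALSE]
  hrf <- array(NA_real_, dim = c(nch, length(conds), 2, nt_hrf),
               dimnames = list(NULL, conds, chrom, NULL))
  coefs <- array(NA_real_, dim = c(nch, 2, ncol(X) + as.integer(use_ss)))
  sigma2 <- matrix(NA_real_, nch, 2, dimnames = list(NULL, chrom))
  ss_choice <- rep(NA_integer_, nch)

  # shared Gram matrix; the per-channel short-separation column enters as a
  # rank-one border so each channel costs only a small solve
  G0 <- crossprod(Xn)
  if (qr(G0)$rank < ncol(Xn)) {
    d <- sqrt(diag(G0)); C <- G0 / outer(d, d)
    bad <- colnames(Xn)[colSums(abs(C) > 1 - 1e-8) > 1]
    stop("rank-deficient design; collinear columns: ",
         paste(unique(bad), collapse = ", "))
  }
  p_full <- ncol(Xn) + as.integer(use_ss)

  for (ci in 1:2) {
    Y <- t(matrix(rec$data[, ci, seq_len(nt)], nch, nt))  # time x channel
    CY <- crossprod(Xn, Y)
    if (use_ss) {
      ssY <- Y[, ss_idx, drop = FALSE]
      ssY <- sweep(ssY, 2, colMeans(ssY))
      Css <- suppressWarnings(stats::cor(Y, ssY))          # channel x ss
      Css[!is.finite(Css)] <- -Inf
      Vss <- crossprod(Xn, ssY)                            # cols x ss
      ss2 <- colSums(ssY^2)
    }
    for (k in long_idx) {
      y <- Y[, k]
      with_ss <- use_ss
      if (use_ss) {
        j <- which.max(Css[k, ])                            # ties: lowest id
        if (ss2[j] == 0) with_ss <- FALSE                   # flat short channel
      }
      beta <- NULL
      if (with_ss) {
        ss_choice[k] <- ss_idx[j]
        G <- rbind(cbind(G0, Vss[, j]), c(Vss[, j], ss2[j]))
        rhs <- c(CY[, k], sum(ssY[, j] * y))
        # a short channel trace (nearly) inside the design span adds nothing
        # and breaks the solve; fall back to the plain design
        beta <- tryCatch(solve(G, rhs), error = function(e) NULL)
        if (is.null(beta)) { with_ss <- FALSE; ss_choice[k] <- NA_integer_ }
      }
      if (!with_ss) {
        G <- G0
        rhs <- CY[, k]
        beta <- solve(G, rhs)
      }
      full_beta <- rep(0, ncol(X) + as.integer(use_ss))
      full_beta[c(!zero_cols, if (use_ss) with_ss)] <- beta
      coefs[k, ci, ] <- full_beta
      sigma2[k, ci] <- max(0, sum(y^2) - sum(beta * rhs)) / (nt - p_full)
      for (cn in conds)
        hrf[k, cn, ci, ] <- B %*% full_beta[design$condition_columns[[cn]]]
    }
  }
  structure(list(hrf = hrf, hrf_time = hrf_time, coefficients = coefs,
                 sigma2 = sigma2, ss_choice = ss_choice, conditions = conds,
                 chromophores = chrom, fs = rec$fs, channels = rec$channels,
                 long_channels = long_idx, layout_name = rec$layout_name),
            class = "hrf_estimate")
}

#' @export
print.hrf_estimate <- function(x, ...) {
  cat(sprintf("<hrf_estimate '%s'> %d channels x %d conditions x %d chromophores, %d samples (%.0f..%.0f s)\n",
              x$layout_name, dim(x$hrf)[1], dim(x$hrf)[2], dim(x$hrf)[3],
              dim(x$hrf)[4], min(x$hrf_time), max(x$hrf_time)))
  invisible(x)
}
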