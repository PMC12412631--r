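#' Spatially regularized brain + scalp image reconstruction
#'
#' Inverts the multispectral sensitivity matrix with spatially variant
#' rescaling plus Tikhonov regularization:
#' `x = L^-1 A_hat^T (A_hat A_hat^T + lambda I)^-1 y`, where
#' `L_vv = sqrt((A^T A)_vv + lambda_spatial)`,
#' `lambda_spatial = alpha_spatial * max(diag(A^T A))`,
#' `A_hat = A L^-1`, and
#' `lambda = alpha_meas * max(diag(A_hat A_hat^T))`.
#' The vertex-wise rescaling stops the inversion from piling all activity
#' onto the high-sensitivity superficial (scalp) vertices; `alpha_meas`
#' smooths the image. A "brain only" variant restricts the operator to
#' brain columns and skips the rescaling.
#'
#' @name recon
NULL

#' Reconstruction configuration
#'
#' @param alpha_spatial spatial regularization parameter (default 0.001);
#'   controls the reconstruction depth.
#' @param alpha_meas measurement regularization parameter (default 0.001);
#'   controls image smoothness.
#' @param mode `"brain_scalp"` (joint two-surface inversion) or
#'   `"brain_only"` (brain columns, no spatial rescaling).
#' @return a `recon_config` list.
#' @export
recon_config <- function(alpha_spatial = 0.001, alpha_meas = 0.001,
                         mode = c("brain_scalp", "brain_only")) {
  stopifnot(alpha_spatial > 0, alpha_meas > 0)
  list(alpha_spatial = alpha_spatial, alpha_meas = alpha_meas,
       mode = match.arg(mode))
}

#' Spatially variant rescaling of the sensitivity matrix
#'
#' @param A numeric matrix (measurements x vertex-chromophore columns).
#' @param alpha_spatial spatial regularization parameter (> 0).
#' @return list with `A_hat = A %*% diag(1/L)` and the diagonal `L` (vector
#'   over columns), `L_vv = sqrt((A^T A)_vv + alpha_spatial * max((A^T A)_vv))`.
#' @export
rescale_sensitivity <- function(A, alpha_spatial = 0.001) {
  if (alpha_spatial <= 0) stop("alpha_spatial must be positive")
  colsq <- colSums(A^2)            # diag(A^T A), one entry per vertex column
  lambda_spatial <- alpha_spatial * max(colsq)
  L <- sqrt(colsq + lambda_spatial)
  list(A_hat = sweep(A, 2, L, "/"), L = L)
}

# channel-space inverse operator: R = L^-1 A_hat^T (A_hat A_hat^T + lambda I)^-1
# returned as a function of y so repeated reconstructions share the solve
build_inverse_operator <- function(A, config) {
  rs <- rescale_sensitivity(A, config$alpha_spatial)
  A_hat <- rs$A_hat
  M <- tcrossprod(A_hat)
  lambda <- config$alpha_meas * max(diag(M))
  ch <- chol(M + lambda * diag(nrow(M)))
  function(y) {
    z <- backsolve(ch, forwardsolve(t(ch), y))
    drop(crossprod(A_hat, z)) / rs$L
  }
}

#' Reconstruct an image from channel measurements
#'
#' @param y numeric vector (or matrix, one column per frame) of channel
#'   optical-density measurements, stacked wavelength-major to match the
#'   multispectral operator's rows.
#' @param A the multispectral forward operator from
#'   [multispectral_sensitivity()], or a plain matrix (then `vertices` must
#'   be supplied).
#' @param config a [recon_config()].
#' @param vertices vertex table (`surface` tag per vertex) if `A` is a bare
#'   matrix.
#' @return a `brain_image`: list with `values` (vertex-chromophore vector or
#'   matrix of frames), `vertices`, `chromophores`, `mode`. Values are in
#'   micromolar under the package's multispectral stacking.
#' @export
reconstruct <- function(y, A, config = recon_config(), vertices = NULL) {
  if (is.list(A) && !is.null(A$A)) { vertices <- A$vertices; A <- A$A }
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  if (nrow(y) != nrow(A)) stop("measurement length does not match operator rows")
  if (any(!is.finite(y))) stop("non-finite measurement values")
  nv <- nrow(vertices)
  stopifnot(ncol(A) == 2 * nv)
  if (config$mode == "brain_only") {
    brain_cols <- c(which(vertices$surface == "brain"),
                    nv + which(vertices$surface == "brain"))
    Ab <- A[, brain_cols, drop = FALSE]
    M <- tcrossprod(Ab)
    lambda <- config$alpha_meas * max(diag(M))
    ch <- chol(M + lambda * diag(nrow(M)))
    xb <- crossprod(Ab, backsolve(ch, forwardsolve(t(ch), y)))
    x <- matrix(0, 2 * nv, ncol(y))
    x[brain_cols, ] <- xb
  } else {
    inv <- build_inverse_operator(A, config)
    x <- apply(y, 2, inv)
    if (is.null(dim(x))) x <- matrix(x, ncol = ncol(y))
  }
  structure(list(values = if (ncol(x) == 1) drop(x) else x,
                 vertices = vertices, chromophores = c("HbO", "HbR"),
                 mode = config$mode),
            class = "brain_image")
}

#' Split a brain_image into per-surface chromophore maps
#'
#' @param img a `brain_image` (single frame).
#' @return data frame: vertex columns plus `HbO`, `HbR`.
#' @export
image_table <- function(img) {
  nv <- nrow(img$vertices)
  v <- if (is.null(dim(img$values))) img$values else img$values[, 1]
  cbind(img$vertices, HbO = v[seq_len(nv)], HbR = v[nv + seq_len(nv)])
}

#' Reconstruct an image time course from HRF estimates
#'
#' Converts each channel's estimated HRF concentrations back to optical
#' density through the forward Beer-Lambert relation, then reconstructs one
#' image per second across the HRF window. Channels without estimates
#' (pruned or short) contribute zero measurements.
#'
#' @param est an `hrf_estimate`.
#' @param A the multispectral operator for the same layout.
#' @param config a [recon_config()].
#' @param condition condition name.
#' @param window time window in s within the HRF grid (default the full
#'   -2..23 s range); images are produced at 1 s steps.
#' @param ppf partial pathlength factor used in the concentration step.
#' @return list with `times` and `images` (vertex-chromophore matrix, one
#'   column per second).
#' @export
image_timecourse <- function(est, A, config = recon_config(), condition,
                             window = NULL, ppf = 1) {
  if (is.null(window)) window <- range(est$hrf_time)
  if (window[2] < window[1]) stop("empty window")
  secs <- seq(ceiling(window[1]), floor(window[2]), by = 1)
  if (length(secs) == 0) stop("empty window")
  nch <- dim(est$hrf)[1]
  sep <- est$channels$separation
  E <- extinction_coefficients(c(760, 850))
  Y <- matrix(0, 2 * nch, length(secs))
  idx <- vapply(secs, function(s) which.min(abs(est$hrf_time - s)), integer(1))
  for (k in est$long_channels) {
    conc <- rbind(est$hrf[k, condition, "HbO", idx],
                  est$hrf[k, condition, "HbR", idx])
    od <- conc_to_od(conc, sep[k], ppf = ppf)
    Y[k, ] <- od[1, ]
    Y[nch + k, ] <- od[2, ]
  }
  img <- reconstruct(Y, A, config)
  vals <- img$values
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = 1)
  list(times = secs, images = vals, vertices = img$vertices,
       chromophores = c("HbO", "HbR"))
}

#' Mean time course over a vertex set
#'
#' @param tc result of [image_timecourse()].
#' @param vertex_ids vertex ids to average.
#' @param chromophore `"HbO"` or `"HbR"`.
#' @return numeric vector over `tc$times`.
#' @export
vertex_mean_timecourse <- function(tc, vertex_ids, chromophore = "HbO") {
  nv <- nrow(tc$vertices)
  off <- if (chromophore == "HbO") 0 else nv
  rows <- off + match(vertex_ids, tc$vertices$vertex_id)
  colMeans(tc$images[rows, , drop = FALSE])
}
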