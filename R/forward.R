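#' Analytic diffusion forward model on a two-surface head patch
#'
#' The head is modeled as a homogeneous semi-infinite medium below the
#' optode plane, sampled on two congruent lateral grids: a shallow scalp
#' surface and a deeper brain (cortical) surface. Channel sensitivities are
#' Rytov photon-measurement-density functions assembled from the
#' semi-infinite diffusion Green's function with an extrapolated boundary.
#'
#' @name forward
NULL

#' Default optical properties per wavelength
#'
#' Effective adult-head absorption and reduced scattering coefficients
#' (1/mm) at 760 and 850 nm.
#' @return named list keyed by wavelength with elements `mu_a`, `mu_s_prime`.
#' @export
default_optical_properties <- function() {
  list(`760` = list(mu_a = 0.018, mu_s_prime = 1.1),
       `850` = list(mu_a = 0.019, mu_s_prime = 1.0))
}

#' Build a two-surface head model
#'
#' Lateral vertex grids (same sampling on both surfaces, so brain and scalp
#' images are vertex-wise comparable) covering the bounding box of one or
#' more layouts plus a margin.
#'
#' @param layouts a `probe_layout` or list of layouts; the union of their
#'   bounding boxes defines the patch.
#' @param spacing lateral vertex spacing, mm.
#' @param d_scalp,d_brain depths of the scalp and brain surfaces below the
#'   optode plane, mm (`d_brain > d_scalp > 0`).
#' @param margin lateral margin beyond the optode bounding box, mm.
#' @param optical_properties per-wavelength `mu_a` / `mu_s_prime`, 1/mm.
#' @return a `head_model` with a `vertices` data frame (`x`, `y`, `z` depth,
#'   `surface` tag) and the optical properties.
#' @export
build_head_model <- function(layouts, spacing = 5, d_scalp = 3, d_brain = 15,
                             margin = 10,
                             optical_properties = default_optical_properties()) {
  stopifnot(d_brain > d_scalp, d_scalp > 0)
  if (inherits(layouts, "probe_layout")) layouts <- list(layouts)
  xs <- unlist(lapply(layouts, function(l) l$optodes$x))
  ys <- unlist(lapply(layouts, function(l) l$optodes$y))
  gx <- seq(min(xs) - margin, max(xs) + margin, by = spacing)
  gy <- seq(min(ys) - margin, max(ys) + margin, by = spacing)
  lat <- expand.grid(x = gx, y = gy)
  vertices <- rbind(
    data.frame(lat, z = d_scalp, surface = "scalp"),
    data.frame(lat, z = d_brain, surface = "brain")
  )
  vertices$vertex_id <- seq_len(nrow(vertices))
  structure(list(vertices = vertices, spacing = spacing,
                 d_scalp = d_scalp, d_brain = d_brain,
                 optical_properties = optical_properties),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model> %d vertices per surface (%.0f mm spacing), scalp %.0f mm, brain %.0f mm\n",
              sum(x$vertices$surface == "brain"), x$spacing, x$d_scalp, x$d_brain))
  invisible(x)
}

#' Semi-infinite medium diffusion Green's function
#'
#' Fluence-like Green's function for a point source in a homogeneous
#' semi-infinite medium, with the extrapolated-boundary image source
#' (effective reflection coefficient 0.493, tissue-air index ~1.4).
#' Surface optodes are represented by an isotropic source at depth
#' `1/mu_s_prime` below their surface position.
#'
#' @param r_src source position, `c(x, y, z)` with z = depth (mm); a surface
#'   optode should be passed with its effective depth already applied (see
#'   [build_sensitivity()]).
#' @param r field point(s): a 3-vector or an n x 3 matrix with z = depth > 0.
#' @param mu_a absorption coefficient, 1/mm.
#' @param mu_s_prime reduced scattering coefficient, 1/mm.
#' @return fluence-like value(s), strictly positive, 1/mm scale.
#' @export
green_semi_infinite <- function(r_src, r, mu_a, mu_s_prime) {
  stopifnot(mu_a > 0, mu_s_prime > 0)
  if (is.null(dim(r))) r <- matrix(r, ncol = 3)
  D <- 1 / (3 * (mu_a + mu_s_prime))
  mu_eff <- sqrt(mu_a / D)
  reff <- 0.493
  zb <- 2 * D * (1 + reff) / (1 - reff)
  # image source mirrored through the extrapolated boundary at z = -zb
  z_img <- -(r_src[3] + 2 * zb)
  d1 <- sqrt((r[, 1] - r_src[1])^2 + (r[, 2] - r_src[2])^2 +
               (r[, 3] - r_src[3])^2)
  d2 <- sqrt((r[, 1] - r_src[1])^2 + (r[, 2] - r_src[2])^2 +
               (r[, 3] - z_img)^2)
  if (any(d1 < 1e-9)) stop("evaluation at source point")
  (exp(-mu_eff * d1) / d1 - exp(-mu_eff * d2) / d2) / (4 * pi * D)
}

#' Build the channel-by-vertex sensitivity matrix
#'
#' Assembles the Rytov sensitivity `S = G(rs, rv) * G(rv, rd) / G(rs, rd)`
#' times the vertex volume element for every channel and vertex, per
#' wavelength. Rows are indexed by channel within wavelength; columns by
#' vertex (scalp surface first, then brain). Entries have pathlength units
#' (mm), so that `delta_OD = S %*% (extinction * delta_conc)`.
#'
#' @param layout a `probe_layout`.
#' @param head a `head_model`.
#' @return a `sensitivity_matrix`: list with `values` (named list of
#'   channels x vertices matrices keyed by wavelength), `channels`,
#'   `vertices`.
#' @export
build_sensitivity <- function(layout, head) {
  pos <- channel_positions(layout)
  if (any(sqrt(rowSums((pos$src - pos$det)^2)) < 1e-9))
    stop("channel with coincident source and detector optodes")
  vtx <- as.matrix(head$vertices[, c("x", "y", "z")])
  vol <- head$spacing^2 * head$spacing  # lateral cell x effective thickness
  values <- list()
  for (wl in layout$wavelengths) {
    op <- head$optical_properties[[as.character(wl)]]
    z0 <- 1 / op$mu_s_prime
    S <- matrix(0, nrow(layout$channels), nrow(vtx))
    for (k in seq_len(nrow(layout$channels))) {
      rs <- pos$src[k, ]; rs[3] <- rs[3] + z0
      rd <- pos$det[k, ]; rd[3] <- rd[3] + z0
      g_sv <- green_semi_infinite(rs, vtx, op$mu_a, op$mu_s_prime)
      g_vd <- green_semi_infinite(rd, vtx, op$mu_a, op$mu_s_prime)
      g_sd <- green_semi_infinite(rs, matrix(rd, ncol = 3),
                                  op$mu_a, op$mu_s_prime)
      S[k, ] <- g_sv * g_vd / g_sd * vol
    }
    values[[as.character(wl)]] <- S
  }
  structure(list(values = values, channels = layout$channels,
                 vertices = head$vertices, layout_name = layout$name),
            class = "sensitivity_matrix")
}

#' Total-sensitivity mask
#'
#' Sums sensitivity over channels (and wavelengths), normalizes the summed
#' map to a maximum of 1, and flags vertices whose normalized value exceeds
#' the threshold (strict inequality); vertices at or below the threshold are
#' masked out.
#'
#' @param S a `sensitivity_matrix`.
#' @param threshold normalized sensitivity cutoff (default 0.01).
#' @return logical vector over vertices, `TRUE` where unmasked.
#' @export
total_sensitivity_mask <- function(S, threshold = 0.01) {
  tot <- Reduce(`+`, lapply(S$values, colSums))
  m <- max(tot)
  if (m <= 0) stop("degenerate sensitivity")
  (tot / m) > threshold
}

#' Hemoglobin extinction coefficients
#'
#' Molar extinction coefficients for HbO and HbR at the given wavelengths,
#' from the standard Gratzer/Prahl compilation, converted to base-e
#' absorptivity in 1/(mm * micromolar).
#'
#' @param wavelengths wavelengths in nm; 760 and 850 are tabulated.
#' @return 2 x 2 matrix, rows = wavelengths, columns = `c("HbO", "HbR")`.
#' @export
extinction_coefficients <- function(wavelengths = c(760, 850)) {
  # base-10 molar extinction, 1/(cm * M)
  tab <- list(`760` = c(HbO = 1486.5865, HbR = 3843.707),
              `850` = c(HbO = 2526.391, HbR = 1798.643))
  out <- t(vapply(as.character(wavelengths), function(w) {
    if (is.null(tab[[w]])) stop("extinction coefficients tabulated only at 760/850 nm")
    tab[[w]] * log(10) / 10 / 1e6  # -> base-e, 1/(mm*uM)
  }, numeric(2)))
  dimnames(out) <- list(as.character(wavelengths), c("HbO", "HbR"))
  out
}

#' Stack a sensitivity matrix over wavelengths and chromophores
#'
#' Builds the multispectral forward operator mapping per-vertex
#' `c(delta_HbO, delta_HbR)` (micromolar) to per-channel, per-wavelength
#' optical density. Rows are ordered wavelength-major (all channels at the
#' first wavelength, then the second); columns chromophore-major (all
#' vertices' HbO, then all vertices' HbR).
#'
#' @param S a `sensitivity_matrix`.
#' @return list with the stacked matrix `A`, `n_channels`, `n_vertices`,
#'   `wavelengths`, and the extinction matrix used.
#' @export
multispectral_sensitivity <- function(S) {
  wls <- as.numeric(names(S$values))
  E <- extinction_coefficients(wls)
  blocks <- lapply(seq_along(wls), function(i) {
    cbind(E[i, "HbO"] * S$values[[i]], E[i, "HbR"] * S$values[[i]])
  })
  A <- do.call(rbind, blocks)
  list(A = A, n_channels = nrow(S$channels), n_vertices = nrow(S$vertices),
       wavelengths = wls, extinction = E, vertices = S$vertices,
       channels = S$channels)
}
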