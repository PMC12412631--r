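test_that("semi-infinite Green's function matches its closed form", {
  mu_a <- 0.018; mu_s <- 1.1
  src <- c(0, 0, 1 / mu_s)
  pts <- rbind(c(10, 5, 12), c(-3, 8, 20), c(0, 0, 5))
  got <- green_semi_infinite(src, pts, mu_a, mu_s)
  # independent re-evaluation, term by term
  D <- 1 / (3 * (mu_a + mu_s))
  mu_eff <- sqrt(3 * mu_a * (mu_a + mu_s))
  zb <- 2 * D * (1 + 0.493) / (1 - 0.493)
  for (i in 1:3) {
    d1 <- sqrt(sum((pts[i, ] - src)^2))
    d2 <- sqrt(sum((pts[i, 1:2] - src[1:2])^2) + (pts[i, 3] + src[3] + 2 * zb)^2)
    ref <- (exp(-mu_eff * d1) / d1 - exp(-mu_eff * d2) / d2) / (4 * pi * D)
    expect_equal(got[i], ref, tolerance = 1e-12)
  }
  expect_true(all(got > 0))
})

test_that("Green's function is laterally isotropic and attenuates with mu_a", {
  src <- c(0, 0, 1)
  a <- green_semi_infinite(src, c(12, 0, 10), 0.018, 1.1)
  b <- green_semi_infinite(src, c(0, 12, 10), 0.018, 1.1)
  expect_equal(a, b, tolerance = 1e-12)
  expect_lt(green_semi_infinite(src, c(12, 0, 10), 0.036, 1.1), a)
  expect_error(green_semi_infinite(src, src, 0.018, 1.1),
               "evaluation at source point")
})

test_that("sensitivity matrix entries match a hand-built Rytov product", {
  # 2 channels, 2x2 vertex head: direct evaluation of G*G/G times volume
  opt <- data.frame(id = c(1L, 2L, 1L, 2L),
                    role = c("source", "source", "detector", "detector"),
                    x = c(0, 40, 30, 70), y = 0, z = 0)
  lay <- list(name = "toy", optodes = opt, wavelengths = c(760, 850),
              bins = list(c(30, 2)))
  lay$channels <- enumerate_channels(lay, lay$bins)
  class(lay) <- "probe_layout"
  head <- build_head_model(lay, spacing = 40, d_scalp = 3, d_brain = 15,
                           margin = 5)
  S <- build_sensitivity(lay, head)
  op <- head$optical_properties[["760"]]
  z0 <- 1 / op$mu_s_prime
  vol <- head$spacing^3
  pos <- channel_positions(lay)
  for (k in seq_len(nrow(lay$channels))) {
    rs <- pos$src[k, ] + c(0, 0, z0)
    rd <- pos$det[k, ] + c(0, 0, z0)
    for (v in seq_len(nrow(head$vertices))) {
      rv <- as.numeric(head$vertices[v, c("x", "y", "z")])
      ref <- green_semi_infinite(rs, rv, op$mu_a, op$mu_s_prime) *
        green_semi_infinite(rd, rv, op$mu_a, op$mu_s_prime) /
        green_semi_infinite(rs, matrix(rd, ncol = 3), op$mu_a, op$mu_s_prime) *
        vol
      expect_equal(S$values[["760"]][k, v], as.numeric(ref),
                   tolerance = 1e-10)
    }
  }
})

test_that("sensitivity obeys reciprocity and depth monotonicity", {
  S <- fx_small_S()
  lay <- fx_sparse()
  # reciprocity: swap all roles and rebuild; the channel set is the same
  swapped <- lay
  swapped$optodes$role <- ifelse(lay$optodes$role == "source",
                                 "detector", "source")
  # re-id within role
  swapped$optodes$id <- NA_integer_
  swapped$optodes$id[swapped$optodes$role == "source"] <-
    seq_len(sum(swapped$optodes$role == "source"))
  swapped$optodes$id[swapped$optodes$role == "detector"] <-
    seq_len(sum(swapped$optodes$role == "detector"))
  swapped$channels <- enumerate_channels(swapped, lay$bins)
  S2 <- build_sensitivity(swapped, fx_small_head())
  # match channels by optode positions (midpoint + separation)
  p1 <- channel_positions(lay); p2 <- channel_positions(swapped)
  key1 <- paste(round(p1$mid[, 1], 6), round(p1$mid[, 2], 6),
                round(S$channels$separation, 6))
  key2 <- paste(round(p2$mid[, 1], 6), round(p2$mid[, 2], 6),
                round(S2$channels$separation, 6))
  m <- match(key1, key2)
  expect_false(anyNA(m))
  expect_equal(S$values[["760"]], S2$values[["760"]][m, ], tolerance = 1e-10)

  # depth decay: at the channel midpoint, the scalp vertex outweighs the
  # brain vertex for every channel
  vtx <- S$vertices
  for (k in c(1, 20, 40)) {
    mid <- p1$mid[k, ]
    d2 <- (vtx$x - mid[1])^2 + (vtx$y - mid[2])^2
    sc <- which(vtx$surface == "scalp")[which.min(d2[vtx$surface == "scalp"])]
    br <- which(vtx$surface == "brain")[which.min(d2[vtx$surface == "brain"])]
    expect_gt(S$values[["760"]][k, sc], S$values[["760"]][k, br])
  }
  # structural invariants
  expect_true(all(S$values[["760"]] >= 0))
  expect_true(all(is.finite(S$values[["760"]])))
  rowmax_surface <- apply(S$values[["850"]], 1,
                          function(r) vtx$surface[which.max(r)])
  expect_true(all(rowmax_surface == "scalp"))
})

test_that("longer channels have larger brain-to-total sensitivity fraction", {
  S <- fx_small_S()
  brain <- S$vertices$surface == "brain"
  frac <- function(cls) {
    rows <- which(S$channels$distance_class == cls)
    v <- S$values[["760"]][rows, , drop = FALSE]
    mean(rowSums(v[, brain, drop = FALSE]) / rowSums(v))
  }
  expect_gt(frac("NN30"), frac("SS8"))
})

test_that("total sensitivity mask applies a strict normalized threshold", {
  fake <- list(values = list(`760` = rbind(c(0.02, 0.01, 0.5, 0),
                                           c(0, 0, 0.5, 0))),
               vertices = data.frame(vertex_id = 1:4,
                                     surface = rep("brain", 4)))
  # summed = c(0.02, 0.01, 1.0, 0) after normalization by max = 1
  m <- total_sensitivity_mask(fake, threshold = 0.01)
  expect_identical(m, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(total_sensitivity_mask(fake, threshold = 0),
                   c(TRUE, TRUE, TRUE, FALSE))
  fake$values[["760"]][] <- 0
  expect_error(total_sensitivity_mask(fake), "degenerate")
})

test_that("extinction coefficients have the expected wavelength ordering", {
  E <- extinction_coefficients(c(760, 850))
  expect_true(all(E > 0))
  expect_gt(E["760", "HbR"], E["760", "HbO"])  # HbR dominates below isosbestic
  expect_gt(E["850", "HbO"], E["850", "HbR"])
  expect_error(extinction_coefficients(c(700, 850)), "tabulated")
})

test_that("multispectral stacking is extinction-weighted block structure", {
  S <- fx_small_S()
  ms <- multispectral_sensitivity(S)
  E <- extinction_coefficients(c(760, 850))
  nch <- nrow(S$channels); nv <- nrow(S$vertices)
  expect_equal(dim(ms$A), c(2 * nch, 2 * nv))
  expect_equal(ms$A[1:nch, 1:nv], E["760", "HbO"] * S$values[["760"]],
               tolerance = 1e-12)
  expect_equal(ms$A[nch + 1:nch, nv + 1:nv],
               E["850", "HbR"] * S$values[["850"]], tolerance = 1e-12)
})
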