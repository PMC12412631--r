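intensity_rec <- function(traces, fs = 24.4) {
  nch <- nrow(traces)
  data <- array(NA_real_, dim = c(nch, 2, ncol(traces)))
  data[, 1, ] <- traces
  data[, 2, ] <- traces
  nirsarray:::new_recording("test", fs, "intensity", data, c(760, 850),
                            NULL, NULL, (seq_len(ncol(traces)) - 1) / fs)
}

test_that("pruning applies the intensity and SNR thresholds strictly", {
  set.seed(1)
  n <- 500
  good <- 0.02 * (1 + 0.001 * rnorm(n))
  dark <- 0.0009 * (1 + 0.001 * rnorm(n))           # mean below 0.001
  noisy <- 0.02 * (1 + rnorm(n))                     # SNR ~ 1
  noisy[noisy <= 0] <- 1e-6
  flat <- rep(0.02, n)                               # SD = 0, SNR = Inf
  # a channel with SNR exactly 5 must be kept (strict "less than")
  x <- rep(c(-1, 1), length.out = n); x <- x - mean(x)
  snr5 <- 0.02 + x * (0.02 / 5) / sqrt(mean(x^2) * n / (n - 1))
  rec <- intensity_rec(rbind(good, dark, noisy, flat, snr5))
  rep <- prune_channels(rec)
  expect_identical(rep$keep, c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_identical(rep$reason[2], "low_intensity")
  expect_identical(rep$reason[3], "low_snr")
  expect_equal(attr(rep, "n_kept") + attr(rep, "n_pruned"), 5)
  expect_error(prune_channels(intensity_rec(matrix(nrow = 0, ncol = 0))),
               "empty")
})

test_that("optical density conversion is the negative log ratio", {
  n <- 1000
  const <- intensity_rec(matrix(0.02, 1, n))
  od <- intensity_to_od(const)
  expect_equal(max(abs(od$data)), 0)
  expect_equal(od$stage, "od")

  x <- rep(0.02, n); x[500] <- 0.02 * exp(-0.1)
  od2 <- intensity_to_od(intensity_rec(matrix(x, 1)))
  expect_equal(od2$data[1, 1, 500], 0.1, tolerance = 1e-3)

  set.seed(2)
  y <- exp(rnorm(n, log(0.02), 0.1))
  od3 <- intensity_to_od(intensity_rec(matrix(y, 1)))
  expect_equal(od3$data[1, 1, ], -log(y / mean(y)), tolerance = 1e-12)

  bad <- matrix(0.02, 1, n); bad[7] <- -1
  expect_error(intensity_to_od(intensity_rec(bad)), "channel 1")
})

test_that("motion correction passes clean data and removes steps and spikes", {
  fs <- 24.4
  t <- seq(0, 300, by = 1 / fs)
  set.seed(2)
  clean <- 0.01 * sin(2 * pi * 0.1 * t) + rnorm(length(t), 0, 5e-4)
  sdc <- sd(clean)

  out <- splinesg_correct(make_od_recording(matrix(clean, 1), fs))
  expect_lt(sqrt(mean((out$data[1, 1, ] - clean)^2)) / sdc, 0.05)

  step <- clean + 10 * sdc * (t >= 150)
  out2 <- splinesg_correct(make_od_recording(matrix(step, 1), fs))
  stepmag <- function(x) abs(mean(x[t > 155 & t < 175]) -
                               mean(x[t > 125 & t < 145]))
  expect_lt(stepmag(out2$data[1, 1, ]), 0.2 * stepmag(step))

  spike <- clean
  i0 <- which.min(abs(t - 150))
  spike[i0] <- spike[i0] + 20 * sdc
  out3 <- splinesg_correct(make_od_recording(matrix(spike, 1), fs))
  peak <- function(x) max(abs(x - clean))
  expect_lt(peak(out3$data[1, 1, ]), 0.2 * peak(spike))

  expect_error(splinesg_correct(make_od_recording(matrix(clean, 1), fs = 0.2)),
               "frame")
})

test_that("the low-pass filter meets its response contract", {
  fs <- 24.4
  t <- seq(0, 200, by = 1 / fs)
  dc <- make_od_recording(matrix(0.3, 1, length(t)), fs)
  expect_equal(lowpass(dc)$data[1, 1, ], rep(0.3, length(t)),
               tolerance = 1e-9)

  tone <- function(f) sin(2 * pi * f * t)
  hi <- lowpass(make_od_recording(matrix(tone(1.1), 1), fs))
  expect_lt(sqrt(mean(hi$data[1, 1, ]^2)), sqrt(mean(tone(1.1)^2)) / 10)
  lo <- lowpass(make_od_recording(matrix(tone(0.05), 1), fs))
  expect_equal(sqrt(mean(lo$data[1, 1, ]^2)), sqrt(mean(tone(0.05)^2)),
               tolerance = 0.05)
  expect_error(lowpass(make_od_recording(matrix(0, 1, 100), fs), fc = 13),
               "Nyquist")
})

test_that("Beer-Lambert conversion round-trips and matches a direct solve", {
  channels <- data.frame(source_id = 1:2, detector_id = 1:2,
                         separation = c(30, 8),
                         distance_class = c("NN30", "SS8"),
                         is_short = c(FALSE, TRUE))
  E <- extinction_coefficients(c(760, 850))
  n <- 50
  set.seed(3)
  hbo <- 0.5 * sin(seq(0, 3, length.out = n)); hbr <- -0.2 * cos(seq(0, 3, length.out = n))
  data <- array(NA_real_, dim = c(2, 2, n))
  for (k in 1:2) {
    od <- conc_to_od(rbind(hbo, hbr), channels$separation[k])
    data[k, 1, ] <- od[1, ]; data[k, 2, ] <- od[2, ]
  }
  rec <- nirsarray:::new_recording("test", 10, "od", data, c(760, 850),
                                   channels, NULL, (0:(n - 1)) / 10)
  conc <- od_to_conc(rec)
  expect_equal(conc$stage, "concentration")
  for (k in 1:2) {
    expect_equal(conc$data[k, 1, ], hbo, tolerance = 1e-10)
    expect_equal(conc$data[k, 2, ], hbr, tolerance = 1e-10)
  }
  # zero OD maps to zero concentration
  rec0 <- rec; rec0$data[] <- 0
  expect_true(all(od_to_conc(rec0)$data == 0))
  # random OD pair equals an independent 2x2 solve
  od_pair <- c(0.013, -0.004)
  rec1 <- rec; rec1$data[1, 1, ] <- od_pair[1]; rec1$data[1, 2, ] <- od_pair[2]
  c1 <- od_to_conc(rec1)
  expect_equal(c(c1$data[1, 1, 1], c1$data[1, 2, 1]),
               as.numeric(solve(E, od_pair / 30)), tolerance = 1e-12)
})

test_that("block and subject rejection enforces the 5-block minimum", {
  tab <- expand.grid(subject = 1:3, condition = c("congruent", "incongruent"),
                     block = 1:9)
  tab$range <- 1
  # subject 2: five congruent blocks pushed over the range threshold -> only
  # four remain -> excluded
  tab$range[tab$subject == 2 & tab$condition == "congruent" & tab$block <= 5] <- 100
  # subject 3: exactly four rejected -> five remain -> retained
  tab$range[tab$subject == 3 & tab$condition == "incongruent" & tab$block <= 4] <- 100
  out <- reject_blocks_and_subjects(tab, min_blocks = 5, range_max = 30)
  expect_identical(sort(unique(out$subject)), c(1L, 3L))
  expect_identical(attr(out, "excluded_subjects"), 2L)
  expect_equal(sum(out$subject == 3 & out$condition == "incongruent"), 5)
  # all blocks clean -> nothing dropped
  clean <- tab; clean$range <- 1
  expect_equal(nrow(reject_blocks_and_subjects(clean)), nrow(clean))
})

test_that("the preprocessing chain is deterministic", {
  lay <- fx_sparse(); S <- fx_small_S()
  truth <- ground_truth(fx_small_head())
  rec <- simulate_recording(lay, S, truth, generate_schedule(5), seed = 6)
  a <- preprocess_recording(rec)
  b <- preprocess_recording(rec)
  expect_identical(a$rec$data, b$rec$data)
  expect_identical(a$prune$keep, b$prune$keep)
  expect_equal(a$rec$stage, "concentration")
})
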