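# shared fixtures, built once per test run and memoised

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

fx_sparse <- function() fixture("sparse", build_sparse_layout)
fx_hd <- function() fixture("hd", build_hd_layout)

# small single-array head model + sensitivity for cheap tests
fx_small_head <- function() fixture("small_head", function()
  build_head_model(fx_sparse(), spacing = 8))
fx_small_S <- function() fixture("small_S", function()
  build_sensitivity(fx_sparse(), fx_small_head()))

# full two-array head + sensitivities (used by heavier tests)
fx_head <- function() fixture("head", function()
  build_head_model(list(fx_sparse(), fx_hd())))
fx_S <- function() fixture("S", function()
  list(sparse = build_sensitivity(fx_sparse(), fx_head()),
       hd = build_sensitivity(fx_hd(), fx_head())))

noiseless_params <- function()
  default_noise_params(cardiac_od = 0, drift_slow_od = 0,
                       drift_linear_od = 0, white_frac = 0,
                       n_spikes = 0, n_shifts = 0)

# a tiny recording wrapper around a plain matrix of OD/conc traces
make_od_recording <- function(traces, fs = 24.4, stage = "od",
                              channels = NULL) {
  nch <- nrow(traces)
  data <- array(NA_real_, dim = c(nch, 2, ncol(traces)))
  data[, 1, ] <- traces
  data[, 2, ] <- traces
  nirsarray:::new_recording("test", fs, stage, data, c(760, 850),
                            channels, NULL,
                            (seq_len(ncol(traces)) - 1) / fs)
}
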