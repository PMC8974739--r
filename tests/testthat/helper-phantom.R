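# Shared fixtures, built once per test run. Tests use a 32x32x24 grid
# (the smallest that places every region comfortably) to keep the suite fast;
# the acceptance script exercises the full default grid.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

test_grid <- c(32L, 32L, 24L)

small_spec <- function(variant = "pre_fess", noise_sigma_hu = 0, seed = 7L,
                       ...) {
  phantom_spec(variant, grid_shape = test_grid,
               noise_sigma_hu = noise_sigma_hu, seed = seed, ...)
}

# noise-free pre-surgery experiment: protocol, spec, traces, series, ROIs
pre_noisefree <- function() fixture("pre_nf", function() {
  protocol <- build_protocol("pre_fess")
  spec <- small_spec("pre_fess")
  traces <- simulate_concentrations(spec, protocol)
  series <- render_series(spec, traces, protocol)
  rois <- rois_from_labels(build_label_map(spec))
  list(protocol = protocol, spec = spec, traces = traces,
       series = series, rois = rois)
})

post_noisefree <- function() fixture("post_nf", function() {
  protocol <- build_protocol("post_fess")
  spec <- small_spec("post_fess")
  traces <- simulate_concentrations(spec, protocol)
  series <- render_series(spec, traces, protocol)
  rois <- rois_from_labels(build_label_map(spec))
  list(protocol = protocol, spec = spec, traces = traces,
       series = series, rois = rois)
})

# exact single-compartment wash-in curve generated by the fit model itself
model_washin_curve <- function(tau, times = seq(34.5, 52.5, by = 1.5),
                               t0 = 34.5, css = 1, c0 = 0,
                               roi = "synthetic") {
  cc <- c0 + (css - c0) * (1 - exp(-(times - t0) / tau))
  structure(tibble::tibble(roi = roi, time_s = times, c = cc),
            class = c("xe_concentration", class(tibble::tibble())))
}

model_washout_curve <- function(tau, times = seq(63, 67.5, by = 1.5),
                                t0 = 63, c_peak = 0.9, roi = "synthetic") {
  cc <- c_peak * exp(-(times - t0) / tau)
  structure(tibble::tibble(roi = roi, time_s = times, c = cc),
            class = c("xe_concentration", class(tibble::tibble())))
}
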