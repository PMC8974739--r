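test_that("closed-form compartment solution matches hand-derived exponentials", {
  # sinus driven by a constant full-xenon nasal cavity for 18 s at k = 1/7
  proto <- new_protocol(tibble::tibble(
    start_s = 0, end_s = 18, gas = "xenon", flow = "pulsating"
  ), frame_interval_s = 1.5)
  spec <- small_spec("pre_fess", nasal_tau_s = 1e-6)  # nasal ~ instantaneous
  tr <- simulate_concentrations(spec, proto)
  maxL <- tr[tr$region == "maxillary_L", ]
  expect_equal(maxL$c[maxL$time_s == 16.5], 1 - exp(-16.5 / 7), tolerance = 1e-6)

  # nasal cavity itself: xenon from 10.5 s, tau 2.5 s -> 0.978 at 20 s
  pre <- build_protocol("pre_fess")
  tr2 <- simulate_concentrations(small_spec("pre_fess"), pre)
  nasal <- tr2[tr2$region == "nasal_left", ]
  # frame grid has no 20 s point; check the closed form at 19.5 s
  expect_equal(nasal$c[nasal$time_s == 19.5], 1 - exp(-9 / 2.5),
               tolerance = 1e-12)
  expect_gt(1 - exp(-9.5 / 2.5), 0.97)  # plateau essentially reached by ~20 s

  # zero-rate sinus is inert over a laminar phase
  maxR <- tr2[tr2$region == "maxillary_R", ]
  expect_true(all(maxR$c[maxR$time_s < 34.5] == 0))
})

test_that("closed-form solution agrees with the 1 ms explicit Euler oracle", {
  fx <- pre_noisefree()
  oracle <- euler_traces(fx$spec, fx$protocol, dt = 0.001)
  joined <- dplyr::inner_join(fx$traces, oracle, by = c("region", "time_s"),
                              suffix = c("", "_oracle"))
  expect_equal(nrow(joined), 8 * 46)
  expect_lt(max(abs(joined$c - joined$c_oracle)), 1e-4)
})

test_that("traces respect physical bounds and monotonicity under constant drivers", {
  for (fx in list(pre_noisefree(), post_noisefree())) {
    tr <- fx$traces
    expect_true(all(tr$c >= 0 & tr$c <= 1))
    expect_true(all(tr$c[tr$time_s == 0] == 0))
    # nasal cavities see a constant (gas-supply) driver in every phase
    for (p in seq_len(nrow(fx$protocol$phases))) {
      ph <- fx$protocol$phases[p, ]
      sub <- tr[tr$time_s >= ph$start_s & tr$time_s < ph$end_s &
                  tr$region %in% c("nasal_left", "nasal_right"), ]
      for (reg in unique(sub$region)) {
        dd <- diff(sub$c[sub$region == reg])
        expect_true(all(dd >= -1e-12) || all(dd <= 1e-12),
                    label = sprintf("monotone %s in phase %d", reg, p))
      }
    }
  }
  # sinuses are monotone per phase once their nasal driver is constant
  # (instantaneous nasal equilibration); with a decaying nasal driver a
  # low-concentration sinus can transiently keep absorbing, which is physical
  fast <- small_spec("pre_fess", nasal_tau_s = 1e-6)
  trf <- simulate_concentrations(fast, build_protocol("pre_fess"))
  for (p in seq_len(5)) {
    ph <- build_protocol("pre_fess")$phases[p, ]
    sub <- trf[trf$time_s >= ph$start_s & trf$time_s < ph$end_s &
                 trf$region %in% sinus_regions(), ]
    for (reg in unique(sub$region)) {
      dd <- diff(sub$c[sub$region == reg])
      expect_true(all(dd >= -1e-12) || all(dd <= 1e-12),
                  label = sprintf("monotone %s in phase %d", reg, p))
    }
  }
})

test_that("missing sinus kinetics is a configuration error", {
  spec <- small_spec("pre_fess")
  spec$kinetics <- spec$kinetics[spec$kinetics$region != "frontal_L", ]
  expect_error(simulate_concentrations(spec, build_protocol("pre_fess")),
               "frontal_L")
})

test_that("label map places all regions, mirror-symmetrically, deterministically", {
  spec <- phantom_spec("pre_fess")  # default 64x64x48
  lab <- build_label_map(spec)
  labs <- region_labels()
  expect_setequal(unique(as.vector(lab)), unname(labs))
  counts <- vapply(labs, function(code) sum(lab == code), 0)
  expect_equal(counts[["maxillary_L"]], counts[["maxillary_R"]])
  expect_equal(counts[["sphenoid_L"]], counts[["sphenoid_R"]])
  expect_equal(counts[["frontal_L"]], counts[["frontal_R"]])
  expect_equal(counts[["nasal_left"]], counts[["nasal_right"]])
  expect_identical(lab, build_label_map(spec))
  expect_error(build_label_map(phantom_spec("pre_fess",
                                            grid_shape = c(6L, 6L, 4L))),
               "too small")
})

test_that("rendering follows the linear enhancement model with exact anchors", {
  fx <- pre_noisefree()
  lab <- build_label_map(fx$spec)
  labs <- region_labels()

  # background air stays at -1000 HU at every frame (sigma = 0)
  bg <- which(lab == labs[["background_air"]])[1]
  bg_idx <- arrayInd(bg, dim(lab))
  expect_true(all(fx$series$volumes$mixed[bg_idx[1], bg_idx[2], bg_idx[3], ]
                  == -1000))

  # nasal voxel at full xenon reads -750 HU on the mixed image
  nas <- arrayInd(which(lab == labs[["nasal_left"]])[1], dim(lab))
  c_nasal <- fx$traces$c[fx$traces$region == "nasal_left"]
  hu_nasal <- fx$series$volumes$mixed[nas[1], nas[2], nas[3], ]
  expect_equal(hu_nasal, -1000 + 250 * c_nasal, tolerance = 1e-12)
  expect_equal(max(hu_nasal), -750, tolerance = 1e-4)

  # doubling e100 doubles the noise-free enhancement of every gas voxel
  spec2 <- small_spec("pre_fess")
  spec2$e100_hu <- spec2$e100_hu * 2
  ser2 <- render_series(spec2, fx$traces, fx$protocol, channels = "mixed")
  gas_mask <- array(lab %in% labs[gas_regions()], dim = dim(lab))
  pick <- which(gas_mask)
  n3 <- prod(dim(lab))
  for (fr in c(1L, 25L, 46L)) {
    e1 <- fx$series$volumes$mixed[pick + (fr - 1L) * n3] + 1000
    e2 <- ser2$volumes$mixed[pick + (fr - 1L) * n3] + 1000
    expect_equal(e2, 2 * e1, tolerance = 1e-12)
  }

  # all-zero kinetics leaves gas spaces at baseline
  spec0 <- small_spec("pre_fess")
  spec0$kinetics[c("k_laminar_in", "k_pulsating_in",
                   "k_laminar_out", "k_pulsating_out")] <- 0
  tr0 <- simulate_concentrations(spec0, fx$protocol)
  expect_true(all(tr0$c[tr0$region != "nasal_left" &
                          tr0$region != "nasal_right"] == 0))
})

test_that("noise stream is reproducible from the spec seed", {
  fx <- pre_noisefree()
  spec <- small_spec("pre_fess", noise_sigma_hu = 5, seed = 11L)
  a <- render_series(spec, fx$traces, fx$protocol, channels = "mixed")
  b <- render_series(spec, fx$traces, fx$protocol, channels = "mixed")
  expect_identical(a$volumes$mixed, b$volumes$mixed)
  spec2 <- small_spec("pre_fess", noise_sigma_hu = 5, seed = 12L)
  c <- render_series(spec2, fx$traces, fx$protocol, channels = "mixed")
  expect_false(identical(a$volumes$mixed, c$volumes$mixed))
})

test_that("series round trip through NIfTI + sidecar is lossless", {
  fx <- post_noisefree()
  dir <- withr::local_tempdir()
  write_series(fx$series, dir)
  back <- read_series(dir)
  expect_equal(back$frame_times, fx$series$frame_times)
  for (ch in names(fx$series$volumes)) {
    expect_equal(back$volumes[[ch]], fx$series$volumes[[ch]],
                 ignore_attr = TRUE)
  }
  expect_equal(back$provenance$variant, "post_fess")

  file.remove(file.path(dir, "series.json"))
  expect_error(read_series(dir), "sidecar")

  # corrupt sidecar frame count
  dir2 <- withr::local_tempdir()
  write_series(fx$series, dir2)
  sc <- jsonlite::read_json(file.path(dir2, "series.json"),
                            simplifyVector = TRUE)
  sc$frame_times <- sc$frame_times[-1]
  jsonlite::write_json(sc, file.path(dir2, "series.json"), auto_unbox = TRUE)
  expect_error(read_series(dir2), "does not match")
})
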