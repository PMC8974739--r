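#' Render a dual-energy CT series from concentration traces
#'
#' Voxel HU model: for a voxel with label `l` at frame time `t`,
#' `HU_ch = baseline_hu(l) + C_l(t) * e100_hu(ch) + eps`, where the xenon
#' term applies only to gas-space labels (nasal cavities and sinuses) and
#' `eps ~ N(0, noise_sigma_hu^2)` independently per voxel, frame and
#' channel. The noise stream is seeded from `spec$seed`, so two renders of
#' the same spec are bit-identical; the caller's RNG state is untouched.
#'
#' @param spec An [phantom_spec()] object.
#' @param traces Concentration traces from [simulate_concentrations()],
#'   sampled at the protocol frame times.
#' @param protocol The protocol used to generate `traces`.
#' @param channels Channels to render (default all three).
#' @return An `xe_series`: list with `frame_times`, `volumes` (named list
#'   of 4-D HU arrays, one per channel, last dimension = frame), and
#'   `provenance` (variant, grid, voxel size, channel enhancement, noise,
#'   seed).
#' @export
render_series <- function(spec, traces, protocol,
                          channels = c("low_kv", "high_kv", "mixed")) {
  stopifnot(inherits(spec, "xe_phantom_spec"), inherits(protocol, "xe_protocol"))
  channels <- match.arg(channels, several.ok = TRUE)
  ft <- frame_times(protocol)
  n_frames <- length(ft)

  tr <- tidyr_pivot_traces(traces)
  if (!isTRUE(all.equal(tr$time_s, ft, tolerance = 1e-9))) {
    stop("traces are not sampled at the protocol frame times", call. = FALSE)
  }

  lab <- build_label_map(spec)
  labs <- region_labels()
  base <- array(NA_real_, dim = dim(lab))
  base[lab == labs[["soft_tissue"]]] <- spec$baseline_hu[["soft_tissue"]]
  base[lab == labs[["bone"]]] <- spec$baseline_hu[["bone"]]
  base[lab == labs[["background_air"]]] <- spec$baseline_hu[["background_air"]]
  gas_hu <- spec$baseline_hu[["gas_space"]]
  gas_idx <- lapply(gas_regions(), function(r) which(lab == labs[[r]]))
  names(gas_idx) <- gas_regions()
  for (r in gas_regions()) base[gas_idx[[r]]] <- gas_hu

  nvox <- prod(dim(lab))
  volumes <- lapply(channels, function(ch) {
    array(NA_real_, dim = c(dim(lab), n_frames))
  })
  names(volumes) <- channels

  with_phantom_rng(spec$seed, {
    for (ch in channels) {
      e100 <- spec$e100_hu[[ch]]
      for (i in seq_len(n_frames)) {
        v <- base
        for (r in gas_regions()) {
          v[gas_idx[[r]]] <- v[gas_idx[[r]]] + tr[[r]][i] * e100
        }
        if (spec$noise_sigma_hu > 0) {
          v <- v + stats::rnorm(nvox, sd = spec$noise_sigma_hu)
        }
        volumes[[ch]][, , , i] <- v
      }
    }
  })

  structure(
    list(frame_times = ft, volumes = volumes,
         provenance = list(variant = spec$variant, grid_shape = spec$grid_shape,
                           voxel_mm = spec$voxel_mm, e100_hu = as.list(spec$e100_hu),
                           noise_sigma_hu = spec$noise_sigma_hu, seed = spec$seed,
                           frame_interval_s = protocol$frame_interval_s)),
    class = "xe_series"
  )
}

# wide frame x region concentration table aligned to frame times
tidyr_pivot_traces <- function(traces) {
  stopifnot(all(c("region", "time_s", "c") %in% names(traces)))
  regs <- unique(traces$region)
  times <- sort(unique(traces$time_s))
  out <- tibble::tibble(time_s = times)
  for (r in regs) {
    sub <- traces[traces$region == r, ]
    sub <- sub[order(sub$time_s), ]
    if (!isTRUE(all.equal(sub$time_s, times, tolerance = 1e-9))) {
      stop("trace for region '", r, "' is not aligned with the frame clock",
           call. = FALSE)
    }
    out[[r]] <- sub$c
  }
  miss <- setdiff(gas_regions(), regs)
  if (length(miss) > 0) {
    stop("traces missing gas region(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out
}

# run code with a private RNG stream; restores the caller's state
with_phantom_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' @export
print.xe_series <- function(x, ...) {
  cat("<xe_series> ", length(x$frame_times), " frames, channels: ",
      paste(names(x$volumes), collapse = ", "), ", grid ",
      paste(utils::head(dim(x$volumes[[1]]), 3), collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' Write / read a dual-energy series
#'
#' Stores one 4-D NIfTI file per channel (`<channel>.nii.gz`) plus a JSON
#' sidecar (`series.json`) holding frame times, channel names and
#' provenance. The round trip is lossless up to float32 NIfTI storage;
#' `datatype = "double"` is used so arrays survive exactly.
#'
#' @param series An `xe_series`.
#' @param dir Directory to write into (created if needed).
#' @return `write_series` returns `dir` invisibly; `read_series` an
#'   `xe_series`. Reading fails with a clear error when the sidecar is
#'   missing or its frame count disagrees with the 4-D extent.
#' @export
write_series <- function(series, dir) {
  stopifnot(inherits(series, "xe_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(series$volumes)) {
    RNifti::writeNifti(series$volumes[[ch]],
                       file.path(dir, paste0(ch, ".nii.gz")),
                       datatype = "double")
  }
  sidecar <- list(
    frame_times = series$frame_times,
    channels = names(series$volumes),
    grid_shape = utils::head(dim(series$volumes[[1]]), 3),
    provenance = series$provenance
  )
  jsonlite::write_json(sidecar, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_series
#' @export
read_series <- function(dir) {
  sidecar_path <- file.path(dir, "series.json")
  if (!file.exists(sidecar_path)) {
    stop("series sidecar not found: ", sidecar_path, call. = FALSE)
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  volumes <- lapply(sc$channels, function(ch) {
    f <- file.path(dir, paste0(ch, ".nii.gz"))
    if (!file.exists(f)) stop("missing channel file: ", f, call. = FALSE)
    arr <- as.array(RNifti::readNifti(f))
    if (length(dim(arr)) != 4 || dim(arr)[4] != length(sc$frame_times)) {
      stop("channel '", ch, "': 4-D extent (", paste(dim(arr), collapse = "x"),
           ") does not match the sidecar frame count (",
           length(sc$frame_times), ")", call. = FALSE)
    }
    arr
  })
  names(volumes) <- sc$channels
  structure(
    list(frame_times = as.numeric(sc$frame_times), volumes = volumes,
         provenance = sc$provenance),
    class = "xe_series"
  )
}
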