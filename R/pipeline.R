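#' Default pipeline configuration
#'
#' A single nested list governing the phantom, protocol, analysis channel,
#' enhancement mode and fit windows. Serializable to YAML; any field can
#' be overridden in the file or via [run_simulate()] arguments.
#'
#' @param variant `"pre_fess"` or `"post_fess"`.
#' @param seed Integer seed for all randomness.
#' @return Named list.
#' @export
default_config <- function(variant = c("pre_fess", "post_fess"), seed = 42L) {
  variant <- match.arg(variant)
  list(
    variant = variant,
    seed = as.integer(seed),
    phantom = list(
      grid_shape = c(64L, 64L, 48L),
      voxel_mm = c(3, 3, 3),
      nasal_tau_s = 2.5,
      noise_sigma_hu = 5,
      e100_hu = list(low_kv = 330, high_kv = 175, mixed = 250)
    ),
    analysis = list(
      channel = "mixed",
      enhancement_mode = "constant",
      input_side = "left",
      erode_voxels = 0L
    )
  )
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file path.
#' @param config Configuration list.
#' @return `read_config` returns the validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("failed to parse config '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  validate_config(cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_config <- function(cfg) {
  v <- cfg$variant %||% "pre_fess"
  if (!is.character(v) || length(v) != 1 || !v %in% c("pre_fess", "post_fess")) {
    stop("config: variant must be 'pre_fess' or 'post_fess' (got '",
         paste(v, collapse = ","), "')", call. = FALSE)
  }
  base <- default_config(v, cfg$seed %||% 42L)
  cfg$phantom <- utils::modifyList(base$phantom, cfg$phantom %||% list())
  cfg$analysis <- utils::modifyList(base$analysis, cfg$analysis %||% list())
  cfg$variant <- cfg$variant %||% base$variant
  cfg$seed <- as.integer(cfg$seed %||% base$seed)
  if (!cfg$variant %in% c("pre_fess", "post_fess")) {
    stop("config: variant must be 'pre_fess' or 'post_fess' (got '",
         cfg$variant, "')", call. = FALSE)
  }
  if (!cfg$analysis$channel %in% c("low_kv", "high_kv", "mixed")) {
    stop("config: analysis.channel must be low_kv, high_kv or mixed",
         call. = FALSE)
  }
  if (!cfg$analysis$enhancement_mode %in% c("constant", "frame")) {
    stop("config: analysis.enhancement_mode must be 'constant' or 'frame'",
         call. = FALSE)
  }
  cfg
}

config_to_spec <- function(cfg) {
  kin <- if (!is.null(cfg$kinetics)) {
    purrr::map_dfr(cfg$kinetics, tibble::as_tibble)
  } else {
    default_kinetics(cfg$variant)
  }
  phantom_spec(
    variant = cfg$variant,
    grid_shape = unlist(cfg$phantom$grid_shape),
    voxel_mm = unlist(cfg$phantom$voxel_mm),
    nasal_tau_s = cfg$phantom$nasal_tau_s,
    kinetics = kin,
    e100_hu = unlist(cfg$phantom$e100_hu),
    noise_sigma_hu = cfg$phantom$noise_sigma_hu,
    seed = cfg$seed
  )
}

pipeline_log <- function(out_dir, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  cat(msg, "\n", file = file.path(out_dir, "pipeline.log"), append = TRUE)
}

#' Simulate an experiment and write it to disk
#'
#' Generates the phantom series for the configured protocol variant and
#' writes the dual-energy volumes (NIfTI + JSON sidecar), ground-truth
#' concentration traces (CSV), ROI label volume, the effective
#' configuration (YAML echo) and a log with the seed.
#'
#' @param config Config list or path to a YAML config.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `series`, `traces`, `spec`, `protocol`,
#'   `rois`.
#' @export
run_simulate <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pipeline_log(out_dir, "simulate: variant=", config$variant,
               " seed=", config$seed,
               " sinusvent=", as.character(utils::packageVersion("sinusvent")))

  protocol <- build_protocol(config$variant,
                             input_side = config$analysis$input_side)
  spec <- config_to_spec(config)
  traces <- simulate_concentrations(spec, protocol)
  series <- render_series(spec, traces, protocol)

  write_series(series, file.path(out_dir, "series"))
  utils::write.csv(traces, file.path(out_dir, "traces.csv"), row.names = FALSE)
  rois <- rois_from_labels(build_label_map(spec),
                           erode_voxels = config$analysis$erode_voxels)
  write_rois(rois, file.path(out_dir, "rois"))
  write_config(config, file.path(out_dir, "config.yaml"))
  pipeline_log(out_dir, "simulate: wrote ", length(series$frame_times),
               " frames to ", out_dir)
  invisible(list(series = series, traces = traces, spec = spec,
                 protocol = protocol, rois = rois))
}

#' Analyze a dual-energy series against an ROI set
#'
#' In-memory core of the analysis: enhancement (constant -1000 HU baseline
#' on the mixed image by default, or temporal-baseline mode), time-density
#' extraction per ROI, normalization to fractional concentration against
#' the input-nostril reference, wash-in/wash-out fits over the protocol's
#' default windows, and the per-sinus summary.
#'
#' @param series An `xe_series`.
#' @param rois An `xe_roi_set` including the input nostril.
#' @param config Config list (or YAML path).
#' @param protocol Protocol; defaults to the variant's published schedule.
#' @return List: `tdcs` (long tibble), `concentrations` (long tibble),
#'   `e100_hu`, `fits` (list of `xe_kinetic_fit`), `summary` (tibble).
#' @export
analyze_experiment <- function(series, rois, config = default_config(),
                               protocol = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  protocol <- protocol %||% build_protocol(config$variant)
  channel <- config$analysis$channel
  mode <- config$analysis$enhancement_mode

  tdcs_long <- extract_tdcs(series, rois, channel = channel)
  nostril <- paste0("nasal_", config$analysis$input_side)
  if (!nostril %in% tdcs_long$roi) {
    stop("input nostril ROI '", nostril, "' is missing from the ROI set",
         call. = FALSE)
  }

  # per-ROI curves; in frame mode, subtract the pre-xenon temporal baseline
  # at the curve level (equivalent to voxel-level for a mean statistic)
  curves <- split(tdcs_long, tdcs_long$roi)
  if (mode == "frame") {
    bw <- default_baseline_window(protocol)
    curves <- lapply(curves, function(cv) {
      base_idx <- cv$time_s >= bw[1] & cv$time_s < bw[2]
      cv$hu <- cv$hu - mean(cv$hu[base_idx]) - 1000
      cv
    })
  }
  e100 <- reference_enhancement(curves[[nostril]])
  conc <- lapply(curves, to_concentration, e100 = e100)

  windows <- default_fit_windows(config$variant)
  windows <- windows[windows$roi %in% names(conc), ]
  fits <- purrr::pmap(windows, function(roi, direction, start_s, end_s, t0_s) {
    f <- if (direction == "wash_in") fit_washin else fit_washout
    f(conc[[roi]], c(start_s, end_s), t0 = t0_s)
  })
  conc_long <- purrr::map_dfr(conc, tibble::as_tibble)
  list(
    tdcs = tdcs_long,
    concentrations = conc_long,
    e100_hu = as.numeric(e100),
    fits = fits,
    summary = summarize_kinetics(fits, conc_long)
  )
}

#' Run the analysis stage on files and write results
#'
#' @param series_dir Directory written by [write_series()].
#' @param rois_dir Directory written by [write_rois()].
#' @param config Config list or YAML path.
#' @param out_dir Output directory for CSV tables and figures.
#' @return Invisibly, the [analyze_experiment()] result list.
#' @export
run_analyze <- function(series_dir, rois_dir, config = default_config(),
                        out_dir) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  if (!dir.exists(series_dir)) {
    stop("series directory not found: ", series_dir, call. = FALSE)
  }
  if (!dir.exists(rois_dir)) {
    stop("ROI directory not found: ", rois_dir, call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pipeline_log(out_dir, "analyze: variant=", config$variant,
               " channel=", config$analysis$channel,
               " mode=", config$analysis$enhancement_mode)

  series <- read_series(series_dir)
  rois <- read_rois(rois_dir)
  res <- analyze_experiment(series, rois, config)

  conc_pct <- dplyr::mutate(res$concentrations,
                            concentration_pct = 100 * .data$c)
  utils::write.csv(conc_pct, file.path(out_dir, "concentrations.csv"),
                   row.names = FALSE)
  fit_tab <- purrr::map_dfr(res$fits, tidy)
  fit_tab$channel <- config$analysis$channel
  utils::write.csv(fit_tab, file.path(out_dir, "fits.csv"), row.names = FALSE)
  summary_pct <- dplyr::mutate(res$summary,
                               level_pct = 100 * .data$level,
                               peak_pct = 100 * .data$peak_c)
  utils::write.csv(summary_pct, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)

  write_sinus_panels(res$concentrations, out_dir)

  # fused color overlay: axial slice through the nasal cavities at the frame
  # of maximal nostril enhancement
  ch <- config$analysis$channel
  vol <- series$volumes[[ch]]
  nostril <- paste0("nasal_", config$analysis$input_side)
  ntdc <- res$tdcs[res$tdcs$roi == nostril, ]
  fr <- which.max(ntdc$hu)
  z <- max(1L, round(dim(vol)[3] * 0.4))
  xen <- temporal_enhancement(series, ch, "constant")
  png::writePNG(fuse_overlay(xen[, , z, fr], vol[, , z, fr]),
                file.path(out_dir, "overlay.png"))

  pipeline_log(out_dir, "analyze: e100=", signif(res$e100_hu, 5),
               " HU; wrote tables to ", out_dir)
  invisible(res)
}

# one panel per sinus pair plus the nasal cavities, mirroring the usual
# left/right presentation; failures to open a PNG device are non-fatal
write_sinus_panels <- function(conc_long, out_dir) {
  pairs <- list(nasal = c("nasal_left", "nasal_right"),
                maxillary = c("maxillary_L", "maxillary_R"),
                sphenoid = c("sphenoid_L", "sphenoid_R"),
                frontal = c("frontal_L", "frontal_R"))
  for (nm in names(pairs)) {
    sub <- conc_long[conc_long$roi %in% pairs[[nm]], ]
    if (nrow(sub) == 0) next
    p <- plot_concentration_curves(sub) +
      ggplot2::ggtitle(paste0(nm, " xenon concentration"))
    tryCatch(
      ggplot2::ggsave(file.path(out_dir, paste0(nm, ".png")), p,
                      width = 6, height = 4, dpi = 120),
      error = function(e) {
        warning("could not write figure '", nm, ".png': ",
                conditionMessage(e), call. = FALSE)
      }
    )
  }
  invisible(NULL)
}

#' End-to-end report: simulate then analyze with one config
#'
#' @param config Config list or YAML path.
#' @param out_dir Output directory (`simulate/` and `analysis/` subdirs).
#' @return Invisibly, the analysis result list.
#' @export
run_report <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  sim_dir <- file.path(out_dir, "simulate")
  ana_dir <- file.path(out_dir, "analysis")
  run_simulate(config, sim_dir)
  res <- run_analyze(file.path(sim_dir, "series"), file.path(sim_dir, "rois"),
                     config, ana_dir)
  invisible(res)
}
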