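#' Voxel-wise xenon enhancement over time
#'
#' Enhancement is the HU increase attributable to xenon. Two baselines are
#' supported: `"frame"` subtracts each voxel's mean over a pre-xenon
#' baseline window (any temporally stable tissue then reads ~0, whatever
#' its HU), and `"constant"` subtracts the -1000 HU of room air (correct
#' only inside gas spaces, but it is the arithmetic behind the printed
#' -750 HU = 100% xenon anchor).
#'
#' @param series An `xe_series`.
#' @param channel Channel to use (`"mixed"`, `"low_kv"`, `"high_kv"`).
#' @param mode `"frame"` or `"constant"`.
#' @param baseline_window Numeric length-2 `c(start_s, end_s)`; frames with
#'   `start_s <= t < end_s` form the baseline (frame mode only). See
#'   [default_baseline_window()].
#' @return 4-D array of enhancements (HU), same shape as the channel.
#' @export
temporal_enhancement <- function(series, channel = "mixed",
                                 mode = c("frame", "constant"),
                                 baseline_window = NULL) {
  stopifnot(inherits(series, "xe_series"))
  mode <- match.arg(mode)
  if (!channel %in% names(series$volumes)) {
    stop("channel '", channel, "' not present in series", call. = FALSE)
  }
  vol <- series$volumes[[channel]]
  if (mode == "constant") return(vol + 1000)

  if (is.null(baseline_window) || length(baseline_window) != 2) {
    stop("frame mode requires baseline_window = c(start_s, end_s)",
         call. = FALSE)
  }
  idx <- which(series$frame_times >= baseline_window[1] &
                 series$frame_times < baseline_window[2])
  if (length(idx) < 1) {
    stop("baseline window [", baseline_window[1], ", ", baseline_window[2],
         ") contains no frames", call. = FALSE)
  }
  nd <- dim(vol)
  baseline <- apply_frame_mean(vol, idx)
  sweep(vol, 1:3, baseline, "-")
}

# mean over selected frames of a 4-D array, returned as 3-D
apply_frame_mean <- function(vol, idx) {
  nd <- dim(vol)
  sub <- vol[, , , idx, drop = FALSE]
  array(rowMeans(matrix(sub, nrow = prod(nd[1:3]))), dim = nd[1:3])
}

#' Default pre-xenon baseline window of a protocol
#'
#' All frames before the first xenon phase (pre-surgery schedule: t < 10.5
#' s, 7 frames).
#'
#' @param protocol An `xe_protocol`.
#' @return `c(0, first_xenon_start_s)`.
#' @export
default_baseline_window <- function(protocol) {
  stopifnot(inherits(protocol, "xe_protocol"))
  xe <- protocol$phases[protocol$phases$gas == "xenon", ]
  if (nrow(xe) == 0) stop("protocol has no xenon phase", call. = FALSE)
  c(0, min(xe$start_s))
}

#' Dual-energy xenon signal map
#'
#' Weighted difference of the frame-mode temporal enhancements of the two
#' spectral channels: `X = dE_low - alpha * dE_high`. Under the linear
#' rendering model this equals `C * (e100_low - alpha * e100_high)`,
#' proportional to xenon concentration for any `alpha` away from the
#' degenerate ratio `e100_low / e100_high`, and independent of baseline
#' tissue HU. It replaces the scanner vendor's proprietary color-coding
#' step with an explicit rule.
#'
#' @param series An `xe_series` containing both spectral channels.
#' @param alpha Spectral weight (default 1).
#' @param baseline_window Pre-xenon window, as in [temporal_enhancement()].
#' @return 4-D array of xenon signal (HU-scaled).
#' @export
spectral_xenon_map <- function(series, alpha = 1, baseline_window) {
  stopifnot(inherits(series, "xe_series"))
  for (ch in c("low_kv", "high_kv")) {
    if (!ch %in% names(series$volumes)) {
      stop("spectral map requires channel '", ch, "'", call. = FALSE)
    }
  }
  e_low <- temporal_enhancement(series, "low_kv", "frame", baseline_window)
  e_high <- temporal_enhancement(series, "high_kv", "frame", baseline_window)
  e_low - alpha * e_high
}

#' Fuse a xenon map slice with a grayscale CT slice
#'
#' Windowed grayscale base with a monotone warm color ramp (black-red-
#' yellow) alpha-blended over positive xenon signal. Deterministic: equal
#' inputs yield identical bytes.
#'
#' @param xenon_slice 2-D matrix of xenon signal.
#' @param gray_slice 2-D matrix of HU, same shape.
#' @param window HU display window `c(lo, hi)` for the grayscale base.
#' @param max_signal Xenon signal mapped to full color saturation.
#' @param blend Maximum overlay opacity in `[0, 1]`.
#' @return `height x width x 3` RGB array in `[0, 1]` (writable with
#'   `png::writePNG`).
#' @export
fuse_overlay <- function(xenon_slice, gray_slice, window = c(-1000, 500),
                         max_signal = 250, blend = 0.7) {
  if (!identical(dim(xenon_slice), dim(gray_slice))) {
    stop("xenon and grayscale slices must share the same shape", call. = FALSE)
  }
  g <- pmin(pmax((gray_slice - window[1]) / diff(window), 0), 1)
  a <- pmin(pmax(xenon_slice / max_signal, 0), 1)
  # warm ramp: red rises first, then green (yellow at saturation)
  col_r <- pmin(2 * a, 1)
  col_g <- pmin(pmax(2 * a - 1, 0), 1)
  w <- blend * a
  rgb <- array(0, dim = c(dim(g), 3))
  rgb[, , 1] <- (1 - w) * g + w * col_r
  rgb[, , 2] <- (1 - w) * g + w * col_g
  rgb[, , 3] <- (1 - w) * g
  rgb
}
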