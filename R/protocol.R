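#' Gas-delivery protocols and the frame clock
#'
#' A protocol describes one dynamic xenon CT experiment as an ordered,
#' contiguous sequence of phases. Each phase carries the supplied gas
#' (`air` or `xenon`) and the flow regime (`laminar`, or `pulsating`,
#' i.e. laminar supply superimposed with a 45 Hz / 25 mbar pressure
#' oscillation). Frames are acquired on a fixed clock (default 1.5 s),
#' with the first frame at t = 0.
#'
#' Two published schedules are built in:
#' \describe{
#'   \item{`pre_fess`}{69 s, 46 frames: room air to 10.5 s, laminar xenon
#'     10.5--34.5 s, pulsating xenon 34.5--52.5 s, laminar room-air washout
#'     52.5--63 s, pulsating room-air washout 63--69 s.}
#'   \item{`post_fess`}{49.5 s, 33 frames: room air to 10.5 s, laminar
#'     xenon 10.5--34.5 s, pulsating xenon until the end; no washout is
#'     recorded.}
#' }
#'
#' @param variant `"pre_fess"` or `"post_fess"`.
#' @param frame_interval_s Frame spacing in seconds (default 1.5).
#' @param input_side Nostril receiving the gas supply, `"left"` or `"right"`.
#'
#' @return An object of class `xe_protocol`: a list with elements
#'   `phases` (tibble with columns `start_s`, `end_s`, `gas`, `flow`),
#'   `frame_interval_s`, and `metadata` (pulsation frequency/amplitude,
#'   supply flow rate, input side; descriptive only — the kinetics depend
#'   solely on the flow enum).
#' @examples
#' p <- build_protocol("pre_fess")
#' length(frame_times(p)) # 46
#' phase_at(p, 20)        # laminar xenon
#' @export
build_protocol <- function(variant = c("pre_fess", "post_fess"),
                           frame_interval_s = 1.5,
                           input_side = c("left", "right")) {
  if (!is.character(variant) || !all(variant %in% c("pre_fess", "post_fess"))) {
    stop("unknown protocol variant: ", paste(variant, collapse = ", "),
         call. = FALSE)
  }
  variant <- match.arg(variant)
  input_side <- match.arg(input_side)

  phases <- switch(variant,
    pre_fess = tibble::tribble(
      ~start_s, ~end_s, ~gas,    ~flow,
      0,        10.5,   "air",   "laminar",
      10.5,     34.5,   "xenon", "laminar",
      34.5,     52.5,   "xenon", "pulsating",
      52.5,     63,     "air",   "laminar",
      63,       69,     "air",   "pulsating"
    ),
    post_fess = tibble::tribble(
      ~start_s, ~end_s, ~gas,    ~flow,
      0,        10.5,   "air",   "laminar",
      10.5,     34.5,   "xenon", "laminar",
      34.5,     49.5,   "xenon", "pulsating"
    )
  )

  new_protocol(
    phases = phases,
    frame_interval_s = frame_interval_s,
    metadata = list(
      variant = variant,
      pulsation_frequency_hz = 45,
      pulsation_amplitude_mbar = 25,
      supply_flow_lpm = 7,
      input_side = input_side
    )
  )
}

#' Construct a protocol from a phase table
#'
#' Lower-level constructor validating the phase invariants: phases are
#' contiguous half-open intervals `[start_s, end_s)` starting at 0.
#'
#' @param phases Data frame with columns `start_s`, `end_s`, `gas`
#'   (`air`/`xenon`), `flow` (`laminar`/`pulsating`).
#' @param frame_interval_s Frame spacing in seconds, > 0.
#' @param metadata Named list of descriptive constants.
#' @return An `xe_protocol`.
#' @export
new_protocol <- function(phases, frame_interval_s = 1.5, metadata = list()) {
  phases <- tibble::as_tibble(phases)
  required <- c("start_s", "end_s", "gas", "flow")
  if (!all(required %in% names(phases))) {
    stop("phase table must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(phases) > 0) {
    if (!all(is.finite(phases$start_s)) || !all(is.finite(phases$end_s)) ||
        any(phases$start_s < 0)) {
      stop("phase times must be non-negative finite numbers", call. = FALSE)
    }
    if (any(phases$start_s >= phases$end_s)) {
      stop("each phase must satisfy start_s < end_s", call. = FALSE)
    }
    if (abs(phases$start_s[1]) > 1e-9) {
      stop("first phase must start at 0", call. = FALSE)
    }
    if (nrow(phases) > 1 &&
        any(abs(phases$end_s[-nrow(phases)] - phases$start_s[-1]) > 1e-9)) {
      stop("phases must be contiguous (each end_s equals the next start_s)",
           call. = FALSE)
    }
    if (!all(phases$gas %in% c("air", "xenon"))) {
      stop("gas must be 'air' or 'xenon'", call. = FALSE)
    }
    if (!all(phases$flow %in% c("laminar", "pulsating"))) {
      stop("flow must be 'laminar' or 'pulsating'", call. = FALSE)
    }
  }
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1 ||
      !is.finite(frame_interval_s) || frame_interval_s <= 0) {
    stop("frame_interval_s must be a single positive number", call. = FALSE)
  }
  structure(
    list(phases = phases, frame_interval_s = frame_interval_s,
         metadata = metadata),
    class = "xe_protocol"
  )
}

#' Total duration of a protocol in seconds
#' @param protocol An `xe_protocol`.
#' @return Duration in seconds (0 for an empty phase list).
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "xe_protocol"))
  if (nrow(protocol$phases) == 0) return(0)
  max(protocol$phases$end_s)
}

#' Frame acquisition times
#'
#' Times `k * frame_interval_s` for `k = 0 ... N-1` with
#' `N = floor(duration / frame_interval_s)`; each timestamp marks the start
#' of its acquisition interval. The pre-surgery schedule yields 46 frames
#' (last at 67.5 s), the post-surgery schedule 33.
#'
#' @param protocol An `xe_protocol`.
#' @return Numeric vector of frame times (s); empty for an empty protocol.
#' @export
frame_times <- function(protocol) {
  stopifnot(inherits(protocol, "xe_protocol"))
  dur <- protocol_duration(protocol)
  n <- floor(dur / protocol$frame_interval_s + 1e-9)
  if (n < 1) return(numeric(0))
  (seq_len(n) - 1) * protocol$frame_interval_s
}

#' Look up the phase active at a time point
#'
#' Phase intervals are half-open `[start_s, end_s)`: an event time such as
#' the pulsation onset belongs to the phase it starts.
#'
#' @param protocol An `xe_protocol`.
#' @param t Time in seconds, `0 <= t < protocol_duration(protocol)`.
#' @return One-row tibble (`start_s`, `end_s`, `gas`, `flow`).
#' @export
phase_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "xe_protocol"))
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t)) {
    stop("t must be a single finite number", call. = FALSE)
  }
  dur <- protocol_duration(protocol)
  if (t < 0 || t >= dur) {
    stop("time ", t, " s is outside the protocol range [0, ", dur, ")",
         call. = FALSE)
  }
  ph <- protocol$phases
  i <- which(ph$start_s <= t & t < ph$end_s)
  ph[i, ]
}

#' @export
print.xe_protocol <- function(x, ...) {
  v <- x$metadata$variant %||% "custom"
  cat("<xe_protocol> ", v, ": ", protocol_duration(x), " s, ",
      length(frame_times(x)), " frames @ ", x$frame_interval_s, " s\n",
      sep = "")
  print(x$phases)
  invisible(x)
}

#' Write / read a protocol as a YAML config block
#'
#' @param protocol An `xe_protocol`.
#' @param path File path for the YAML document.
#' @return `write_protocol` returns `path` invisibly; `read_protocol`
#'   returns an `xe_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "xe_protocol"))
  yaml::write_yaml(protocol_to_list(protocol), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  protocol_from_list(yaml::read_yaml(path))
}

protocol_to_list <- function(protocol) {
  list(
    phases = purrr::pmap(protocol$phases, function(start_s, end_s, gas, flow) {
      list(start_s = start_s, end_s = end_s, gas = gas, flow = flow)
    }),
    frame_interval_s = protocol$frame_interval_s,
    metadata = protocol$metadata
  )
}

protocol_from_list <- function(x) {
  phases <- purrr::map_dfr(x$phases, tibble::as_tibble)
  new_protocol(phases,
               frame_interval_s = x$frame_interval_s %||% 1.5,
               metadata = x$metadata %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
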