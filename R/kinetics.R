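#' Xenon enhancement of a Hounsfield-unit reading
#'
#' The HU increase over room air: `hu - (-1000)`. Room air reads 0,
#' a nasal cavity filled with ~100% xenon (-750 HU on the mixed image)
#' reads 250 HU.
#'
#' @param hu Numeric HU value(s).
#' @return Enhancement in HU.
#' @examples
#' enhancement(c(-1000, -875, -750)) # 0, 125, 250
#' @export
enhancement <- function(hu) {
  stopifnot(is.numeric(hu))
  hu + 1000
}

#' Full-xenon reference enhancement from the input-nostril curve
#'
#' The 100%-xenon reference `E100` is defined as the maximum enhancement
#' observed in the input nostril over the whole series. A non-positive
#' maximum (e.g. a curve stuck at -1000 HU) cannot serve as a reference
#' and is flagged with a warning.
#'
#' @param nostril_curve An `xe_tdc` (or any tibble with an `hu` column)
#'   for the input nostril.
#' @return `E100` in HU, with attribute `valid` (`FALSE` when <= 0).
#' @export
reference_enhancement <- function(nostril_curve) {
  hu <- nostril_curve$hu
  hu <- hu[is.finite(hu)]
  if (length(hu) == 0) stop("nostril curve has no finite HU values", call. = FALSE)
  e100 <- max(enhancement(hu))
  if (e100 <= 0) {
    warning("nostril maximum enhancement is ", signif(e100, 3),
            " HU; not a valid 100% xenon reference", call. = FALSE)
    attr(e100, "valid") <- FALSE
  } else {
    attr(e100, "valid") <- TRUE
  }
  e100
}

#' Convert a time-density curve to fractional xenon concentration
#'
#' `c(t) = enhancement(hu(t)) / e100`: the ratio of the ROI's xenon
#' enhancement to that of 100% xenon. Noise can push readings slightly
#' above the reference; values are capped at 1.1 so outliers cannot
#' dominate subsequent fits.
#'
#' @param curve An `xe_tdc` tibble (`roi`, `time_s`, `hu`).
#' @param e100 Positive reference enhancement (HU), e.g. from
#'   [reference_enhancement()].
#' @return Tibble of class `xe_concentration` with columns `roi`,
#'   `time_s`, `c` and attribute `e100_hu`.
#' @export
to_concentration <- function(curve, e100) {
  if (!is.numeric(e100) || length(e100) != 1 || !is.finite(e100) || e100 <= 0) {
    stop("e100 must be a single positive enhancement (HU)", call. = FALSE)
  }
  out <- tibble::tibble(
    roi = curve$roi,
    time_s = curve$time_s,
    c = pmin(enhancement(curve$hu) / e100, 1.1)
  )
  attr(out, "e100_hu") <- as.numeric(e100)
  class(out) <- c("xe_concentration", class(out))
  out
}

#' Fit first-order wash-in / wash-out kinetics to a concentration curve
#'
#' Wash-in model: `c(t) = c0 + (c_ss - c0) * (1 - exp(-(t - t0)/tau))`,
#' with `c0` anchored to the observed frame nearest `t0` (free anchors are
#' ill-conditioned on the short windows these protocols allow). Wash-out
#' model: `c(t) = c_peak * exp(-(t - t0)/tau)` with `c_peak` anchored the
#' same way. `tau` (and `c_ss` for wash-in) is estimated by bounded
#' Levenberg-Marquardt least squares, `tau` in `[0.1, 1000]` s,
#' initialized from a log-linear regression of the residual amplitude.
#' Optimizer failure or a flat/empty curve yields `converged = FALSE`
#' rather than an error.
#'
#' @param curve An `xe_concentration` tibble.
#' @param window `c(start_s, end_s)`; frames with
#'   `start_s <= t <= end_s` enter the fit (at least 3 required).
#' @param t0 Onset time of the driving event (phase start); must not
#'   exceed the window start.
#' @return Object of class `xe_kinetic_fit`; see [tidy.xe_kinetic_fit()].
#' @examples
#' tt <- seq(34.5, 52.5, by = 1.5)
#' cc <- 1 - exp(-(tt - 34.5) / 7)
#' curve <- structure(tibble::tibble(roi = "maxillary_L", time_s = tt, c = cc),
#'                    class = c("xe_concentration", class(tibble::tibble())))
#' fit_washin(curve, c(34.5, 52.5), t0 = 34.5)$tau_s # ~7
#' @export
fit_washin <- function(curve, window, t0) {
  fit_kinetic(curve, window, t0, direction = "wash_in")
}

#' @rdname fit_washin
#' @export
fit_washout <- function(curve, window, t0) {
  fit_kinetic(curve, window, t0, direction = "wash_out")
}

fit_kinetic <- function(curve, window, t0, direction) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (t0 > window[1] + 1e-9) {
    stop("t0 (", t0, ") must not exceed the window start (", window[1], ")",
         call. = FALSE)
  }
  tt <- curve$time_s
  # window must overlap the sampled curve (it may extend past the last frame:
  # the published washout window runs to 69 s while the last frame is 67.5 s)
  if (window[1] < min(tt) - 1e-9 || window[1] > max(tt) + 1e-9) {
    stop("fit window [", window[1], ", ", window[2],
         "] lies outside the curve support", call. = FALSE)
  }
  sel <- tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9
  t_fit <- tt[sel]
  c_fit <- pmin(curve$c[sel], 1.1)
  if (length(t_fit) < 3) {
    stop("fewer than 3 frames in the fit window", call. = FALSE)
  }
  roi_name <- if (length(curve$roi) > 0) curve$roi[[1]] else "roi"
  anchor <- pmin(curve$c[which.min(abs(tt - t0))], 1.1)

  base <- list(roi_name = roi_name, direction = direction,
               window = as.numeric(window), t0 = t0,
               tau_s = NA_real_, level = NA_real_, rmse = NA_real_,
               n_points = length(t_fit), converged = FALSE,
               data = tibble::tibble(time_s = t_fit, c = c_fit))

  flat <- diff(range(c_fit)) < 1e-9
  if (direction == "wash_in") {
    if (flat) return(new_kinetic_fit(base))
    # initial values: amplitude from the data, tau from log-linear decay of
    # the gap to a slightly inflated plateau guess
    css0 <- max(c_fit) + 0.05 * diff(range(c_fit)) + 1e-6
    gap <- css0 - c_fit
    ok <- gap > 0
    tau0 <- init_tau(t_fit[ok] - t0, gap[ok], fallback = diff(window) / 3)
    fit <- try_nls(
      c_fit ~ anchor + (css - anchor) * (1 - exp(-(t_fit - t0) / tau)),
      data = list(c_fit = c_fit, t_fit = t_fit, anchor = anchor, t0 = t0),
      start = list(tau = tau0, css = max(c_fit)),
      lower = c(tau = 0.1, css = -0.1),
      upper = c(tau = 1000, css = 1.2)
    )
    if (is.null(fit)) return(new_kinetic_fit(base))
    est <- stats::coef(fit)
    base$tau_s <- unname(est[["tau"]])
    base$level <- unname(est[["css"]])
  } else {
    if (flat || anchor <= 1e-9) return(new_kinetic_fit(base))  # flat or all-zero
    pos <- c_fit > 0
    tau0 <- init_tau(t_fit[pos] - t0, c_fit[pos], fallback = diff(window) / 2)
    fit <- try_nls(
      c_fit ~ anchor * exp(-(t_fit - t0) / tau),
      data = list(c_fit = c_fit, t_fit = t_fit, anchor = anchor, t0 = t0),
      start = list(tau = tau0),
      lower = c(tau = 0.1), upper = c(tau = 1000)
    )
    if (is.null(fit)) return(new_kinetic_fit(base))
    base$tau_s <- unname(stats::coef(fit)[["tau"]])
    base$level <- anchor
  }
  base$rmse <- sqrt(mean(stats::resid(fit)^2))
  base$converged <- TRUE
  new_kinetic_fit(base)
}

# log-linear slope of amplitude ~ time gives a deterministic tau start value
init_tau <- function(dt, amp, fallback) {
  keep <- amp > 0 & is.finite(amp)
  if (sum(keep) >= 2) {
    sl <- stats::coef(stats::lm(log(amp[keep]) ~ dt[keep]))[2]
    if (is.finite(sl) && sl < -1e-12) return(min(max(-1 / sl, 0.1), 1000))
  }
  min(max(fallback, 0.1), 1000)
}

try_nls <- function(formula, data, start, lower, upper) {
  tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      formula, data = data, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )),
    error = function(e) NULL
  )
}

new_kinetic_fit <- function(x) structure(x, class = "xe_kinetic_fit")

#' @export
print.xe_kinetic_fit <- function(x, ...) {
  cat("<xe_kinetic_fit> ", x$roi_name, " ", x$direction, ": ", sep = "")
  if (x$converged) {
    cat("tau = ", signif(x$tau_s, 4), " s, level = ",
        signif(x$level, 3), ", rmse = ", signif(x$rmse, 3),
        " (", x$n_points, " frames)\n", sep = "")
  } else {
    cat("not converged (", x$n_points, " frames)\n", sep = "")
  }
  invisible(x)
}

#' Tidy a kinetic fit
#'
#' @param x An `xe_kinetic_fit`.
#' @param ... Unused.
#' @return One-row tibble: `roi`, `direction`, `tau_s`, `level`, `rmse`,
#'   `n_points`, `converged`, `t0_s`, `window_start_s`, `window_end_s`.
#' @method tidy xe_kinetic_fit
#' @export
tidy.xe_kinetic_fit <- function(x, ...) {
  tibble::tibble(
    roi = x$roi_name, direction = x$direction, tau_s = x$tau_s,
    level = x$level, rmse = x$rmse, n_points = x$n_points,
    converged = x$converged, t0_s = x$t0,
    window_start_s = x$window[1], window_end_s = x$window[2]
  )
}

#' Glance at a kinetic fit
#'
#' @inheritParams tidy.xe_kinetic_fit
#' @return One-row tibble of fit diagnostics.
#' @method glance xe_kinetic_fit
#' @export
glance.xe_kinetic_fit <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, n_points = x$n_points,
                 converged = x$converged)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Summarize kinetic fits across ROIs
#'
#' One row per ROI and direction: the fitted time constant and level, the
#' peak concentration over the whole series, fit RMSE and convergence.
#' Duplicate ROI/direction entries keep the last fit, with a warning.
#'
#' @param fits List of `xe_kinetic_fit` objects.
#' @param curves List of `xe_concentration` tibbles (or one long tibble
#'   with `roi`, `time_s`, `c`) used for the series-wide peak.
#' @return Tibble: `roi`, `direction`, `tau_s`, `level`, `peak_c`,
#'   `rmse`, `converged`.
#' @export
summarize_kinetics <- function(fits, curves) {
  if (length(fits) == 0) {
    return(tibble::tibble(roi = character(), direction = character(),
                          tau_s = numeric(), level = numeric(),
                          peak_c = numeric(), rmse = numeric(),
                          converged = logical()))
  }
  tab <- purrr::map_dfr(fits, tidy)
  dup <- duplicated(tab[, c("roi", "direction")], fromLast = TRUE)
  if (any(dup)) {
    warning("duplicate ROI/direction fit(s) for ",
            paste(unique(tab$roi[dup]), collapse = ", "),
            "; keeping the last", call. = FALSE)
    tab <- tab[!dup, ]
  }
  if (inherits(curves, "data.frame")) {
    long <- tibble::as_tibble(curves)
  } else {
    long <- purrr::map_dfr(curves, tibble::as_tibble)
  }
  peaks <- dplyr::summarise(dplyr::group_by(long, .data$roi),
                            peak_c = max(.data$c), .groups = "drop")
  out <- dplyr::left_join(tab, peaks, by = "roi")
  dplyr::select(out, "roi", "direction", "tau_s", "level", "peak_c",
                "rmse", "converged")
}

#' Default fit windows for a protocol variant
#'
#' Encodes which protocol event drives each sinus: before surgery,
#' pulsation onset (34.5 s) is the wash-in origin for every sinus except
#' the left sphenoid (already ventilated under laminar xenon from 10.5 s),
#' and the pulsating room-air phase (63 s to end) is the wash-out window;
#' after surgery all sinuses wash in from the xenon onset at 10.5 s and no
#' wash-out is recorded.
#'
#' @param variant `"pre_fess"` or `"post_fess"`.
#' @return Tibble: `roi`, `direction`, `start_s`, `end_s`, `t0_s`.
#' @export
default_fit_windows <- function(variant = c("pre_fess", "post_fess")) {
  variant <- match.arg(variant)
  if (variant == "pre_fess") {
    dplyr::bind_rows(
      tibble::tibble(roi = c("maxillary_L", "maxillary_R", "sphenoid_R",
                             "frontal_L", "frontal_R"),
                     direction = "wash_in",
                     start_s = 34.5, end_s = 52.5, t0_s = 34.5),
      tibble::tibble(roi = "sphenoid_L", direction = "wash_in",
                     start_s = 10.5, end_s = 52.5, t0_s = 10.5),
      tibble::tibble(roi = sinus_regions(), direction = "wash_out",
                     start_s = 63, end_s = 69, t0_s = 63)
    )
  } else {
    tibble::tibble(roi = sinus_regions(), direction = "wash_in",
                   start_s = 10.5, end_s = 49.5, t0_s = 10.5)
  }
}
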