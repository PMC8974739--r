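#' Build named ROI masks from a label volume
#'
#' One boolean mask per requested region, equal to the exact label
#' support, optionally eroded by a number of voxels (6-neighbourhood) to
#' keep the ROI away from partial-volume boundaries.
#'
#' @param label_map 3-D integer label array with a `labels` attribute
#'   (from [build_label_map()]), or a plain array plus `labels`.
#' @param names Regions to extract; default all gas regions present.
#' @param erode_voxels Non-negative integer erosion depth (default 0).
#' @param labels Named integer label vocabulary; defaults to the attribute
#'   on `label_map` or [region_labels()].
#' @return `xe_roi_set`: named list of logical 3-D masks.
#' @export
rois_from_labels <- function(label_map, names = NULL, erode_voxels = 0,
                             labels = NULL) {
  labels <- labels %||% attr(label_map, "labels") %||% region_labels()
  if (is.null(names)) {
    names <- intersect(gas_regions(), names(labels))
  }
  absent <- setdiff(names, names(labels))
  if (length(absent) > 0) {
    stop("unknown region name(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  masks <- lapply(names, function(nm) {
    m <- array(label_map == labels[[nm]], dim = dim(label_map))
    if (!any(m)) {
      stop("label '", nm, "' has no voxels in this volume", call. = FALSE)
    }
    if (erode_voxels > 0) {
      for (i in seq_len(erode_voxels)) m <- erode3d(m)
      if (!any(m)) {
        stop("erosion by ", erode_voxels, " voxel(s) empties ROI '", nm, "'",
             call. = FALSE)
      }
    }
    m
  })
  names(masks) <- names
  structure(masks, class = "xe_roi_set")
}

# 6-neighbour binary erosion by one voxel (faces treated as background)
erode3d <- function(m) {
  d <- dim(m)
  shift <- function(m, axis, by) {
    out <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[axis]
    if (by == 1) { idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1) }
    else { idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  m & shift(m, 1, 1) & shift(m, 1, -1) &
    shift(m, 2, 1) & shift(m, 2, -1) &
    shift(m, 3, 1) & shift(m, 3, -1)
}

#' @export
print.xe_roi_set <- function(x, ...) {
  cat("<xe_roi_set> ", length(x), " ROI(s): ",
      paste(sprintf("%s (%d vx)", names(x), vapply(x, sum, 0L)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract a region-of-interest time-density curve
#'
#' Mean HU over the mask voxels at every frame, the standard ROI statistic
#' behind sinus time-density curves.
#'
#' @param series An `xe_series`.
#' @param roi Logical 3-D mask (or an `xe_roi_set` element).
#' @param channel Channel to read (default `"mixed"`).
#' @param roi_name Name recorded in the output.
#' @return Tibble of class `xe_tdc` with columns `roi`, `time_s`, `hu` and
#'   attributes `n_voxels`, `channel`.
#' @export
extract_tdc <- function(series, roi, channel = "mixed", roi_name = "roi") {
  stopifnot(inherits(series, "xe_series"))
  if (!channel %in% names(series$volumes)) {
    stop("channel '", channel, "' not present in series", call. = FALSE)
  }
  vol <- series$volumes[[channel]]
  if (!identical(dim(roi), dim(vol)[1:3])) {
    stop("ROI shape does not match the series grid", call. = FALSE)
  }
  idx <- which(roi)
  if (length(idx) == 0) stop("ROI mask is empty", call. = FALSE)
  nvox <- prod(dim(vol)[1:3])
  mat <- matrix(vol, nrow = nvox)
  hu <- colMeans(mat[idx, , drop = FALSE])
  out <- tibble::tibble(roi = roi_name, time_s = series$frame_times, hu = hu)
  attr(out, "n_voxels") <- length(idx)
  attr(out, "channel") <- channel
  class(out) <- c("xe_tdc", class(out))
  out
}

#' Extract time-density curves for every ROI in a set
#'
#' @param series An `xe_series`.
#' @param roi_set An `xe_roi_set`.
#' @param channel Channel to read.
#' @return Long tibble (`roi`, `time_s`, `hu`, `n_voxels`), one block per
#'   ROI.
#' @export
extract_tdcs <- function(series, roi_set, channel = "mixed") {
  stopifnot(inherits(roi_set, "xe_roi_set"))
  purrr::map_dfr(names(roi_set), function(nm) {
    tdc <- extract_tdc(series, roi_set[[nm]], channel, roi_name = nm)
    tdc$n_voxels <- attr(tdc, "n_voxels")
    tibble::as_tibble(tdc)
  })
}

#' Write / read an ROI set as a label volume plus name table
#'
#' Masks must be disjoint (they are, when derived from a label map). The
#' label volume is stored as NIfTI, the name-to-code table as JSON.
#'
#' @param roi_set An `xe_roi_set`.
#' @param dir Output directory.
#' @return `write_rois` returns `dir` invisibly; `read_rois` an
#'   `xe_roi_set`.
#' @export
write_rois <- function(roi_set, dir) {
  stopifnot(inherits(roi_set, "xe_roi_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(roi_set[[1]])
  lab <- array(0L, dim = d)
  codes <- seq_along(roi_set)
  for (i in codes) {
    if (any(lab[roi_set[[i]]] != 0L)) {
      stop("ROI masks overlap; cannot encode as a label volume", call. = FALSE)
    }
    lab[roi_set[[i]]] <- i
  }
  RNifti::writeNifti(lab, file.path(dir, "rois.nii.gz"), datatype = "int16")
  jsonlite::write_json(as.list(stats::setNames(codes, names(roi_set))),
                       file.path(dir, "rois.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_rois
#' @export
read_rois <- function(dir) {
  tab_path <- file.path(dir, "rois.json")
  vol_path <- file.path(dir, "rois.nii.gz")
  if (!file.exists(tab_path) || !file.exists(vol_path)) {
    stop("ROI directory must contain rois.nii.gz and rois.json", call. = FALSE)
  }
  codes <- jsonlite::read_json(tab_path, simplifyVector = TRUE)
  lab <- as.array(RNifti::readNifti(vol_path))
  masks <- lapply(codes, function(code) array(lab == code, dim = dim(lab)))
  structure(masks, class = "xe_roi_set")
}
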