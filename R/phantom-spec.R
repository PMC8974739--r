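#' Region label vocabulary of the head phantom
#'
#' Integer codes for the eleven phantom regions: background air, soft
#' tissue, bone, the two nasal cavities, and the six paranasal sinuses
#' (left/right maxillary, sphenoid, frontal).
#'
#' @return Named integer vector mapping region name to label code.
#' @export
region_labels <- function() {
  c(background_air = 0L, soft_tissue = 1L, bone = 2L,
    nasal_left = 3L, nasal_right = 4L,
    maxillary_L = 5L, maxillary_R = 6L,
    sphenoid_L = 7L, sphenoid_R = 8L,
    frontal_L = 9L, frontal_R = 10L)
}

#' @rdname region_labels
#' @export
sinus_regions <- function() {
  c("maxillary_L", "maxillary_R", "sphenoid_L", "sphenoid_R",
    "frontal_L", "frontal_R")
}

#' @rdname region_labels
#' @export
gas_regions <- function() {
  c("nasal_left", "nasal_right", sinus_regions())
}

#' Default per-sinus exchange-rate tables
#'
#' First-order ostium exchange rates (1/s) for each sinus under each flow
#' regime and transport direction, per surgical condition. `tau = 1/k` is
#' the characteristic ventilation time constant. Before surgery, laminar
#' flow drives essentially no exchange in most sinuses (the left sphenoid,
#' with an unusually patent ostium, is the exception) while pulsation opens
#' exchange; after functional endoscopic sinus surgery (FESS) the widened
#' ostia make the sinuses directly ventilated spaces and pulsation adds
#' nothing, so laminar and pulsating rates coincide. `c_eq` is the
#' accessible equilibrium fraction: the concentration a sinus approaches
#' relative to its feeding nasal cavity.
#'
#' @param variant `"pre_fess"` or `"post_fess"`.
#' @return Tibble with columns `region`, `k_laminar_in`, `k_pulsating_in`,
#'   `k_laminar_out`, `k_pulsating_out` (1/s), and `c_eq`.
#' @export
default_kinetics <- function(variant = c("pre_fess", "post_fess")) {
  variant <- match.arg(variant)
  if (variant == "pre_fess") {
    tibble::tribble(
      ~region,        ~k_laminar_in, ~k_pulsating_in, ~k_laminar_out, ~k_pulsating_out, ~c_eq,
      "maxillary_L",  0,             1 / 7,           1 / 60,         1 / 6,            1,
      "maxillary_R",  0,             1 / 18,          1 / 60,         1 / 6,            1,
      "sphenoid_L",   1 / 10,        1 / 8,           1 / 60,         1 / 8,            1,
      "sphenoid_R",   0,             1 / 8,           1 / 60,         1 / 8,            1,
      "frontal_L",    0,             1 / 170,         0,              1 / 170,          1,
      "frontal_R",    0,             1 / 170,         0,              1 / 170,          1
    )
  } else {
    tibble::tribble(
      ~region,        ~k_laminar_in, ~k_pulsating_in, ~k_laminar_out, ~k_pulsating_out, ~c_eq,
      "maxillary_L",  1 / 4,         1 / 4,           1 / 4,          1 / 4,            0.9,
      "maxillary_R",  1 / 4,         1 / 4,           1 / 4,          1 / 4,            0.9,
      "sphenoid_L",   1 / 12,        1 / 12,          1 / 12,         1 / 12,           0.6,
      "sphenoid_R",   1 / 4,         1 / 4,           1 / 4,          1 / 4,            0.9,
      "frontal_L",    1 / 12,        1 / 12,          1 / 12,         1 / 12,           0.6,
      "frontal_R",    1 / 12,        1 / 12,          1 / 12,         1 / 12,           0.6
    )
  }
}

#' Specify a synthetic dual-energy head phantom
#'
#' Bundles the geometry, compartment kinetics, Hounsfield-unit rendering
#' model and noise/seed settings of one simulated experiment. Air-filled
#' spaces render at -1000 HU when xenon-free; full xenon adds the
#' channel-specific enhancement `e100_hu` (mixed image: 250 HU, so 100%
#' xenon reads -750 HU). Enhancement is linear in xenon concentration.
#'
#' @param variant Surgical condition, selects the default kinetics table.
#' @param grid_shape Integer vector of 3 voxel counts (default 64x64x48).
#' @param voxel_mm Voxel edge lengths in mm (metadata only).
#' @param nasal_tau_s Time constant (s) of the directly ventilated nasal
#'   cavities (default 2.5 s, giving the observed plateau at ~20 s).
#' @param kinetics Sinus exchange-rate table; see [default_kinetics()].
#' @param baseline_hu Named numeric: baseline HU per tissue class.
#' @param e100_hu Named numeric: full-xenon enhancement per channel
#'   (`low_kv`, `high_kv`, `mixed`). All must be > 0 and `mixed` defaults
#'   to exactly 250 HU.
#' @param noise_sigma_hu Additive Gaussian HU noise SD (default 5).
#' @param seed Integer seed controlling the noise stream.
#' @return Object of class `xe_phantom_spec`.
#' @export
phantom_spec <- function(variant = c("pre_fess", "post_fess"),
                         grid_shape = c(64L, 64L, 48L),
                         voxel_mm = c(3, 3, 3),
                         nasal_tau_s = 2.5,
                         kinetics = default_kinetics(variant),
                         baseline_hu = c(background_air = -1000, soft_tissue = 40,
                                         bone = 700, gas_space = -1000),
                         e100_hu = c(low_kv = 330, high_kv = 175, mixed = 250),
                         noise_sigma_hu = 5,
                         seed = 42L) {
  variant <- match.arg(variant)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0),
            length(voxel_mm) == 3, all(voxel_mm > 0),
            is.numeric(nasal_tau_s), nasal_tau_s > 0,
            is.numeric(noise_sigma_hu), noise_sigma_hu >= 0)
  kinetics <- tibble::as_tibble(kinetics)
  rate_cols <- c("k_laminar_in", "k_pulsating_in", "k_laminar_out",
                 "k_pulsating_out")
  stopifnot(all(c("region", rate_cols, "c_eq") %in% names(kinetics)))
  if (any(as.matrix(kinetics[rate_cols]) < 0)) {
    stop("exchange rates must be >= 0", call. = FALSE)
  }
  if (any(kinetics$c_eq < 0 | kinetics$c_eq > 1)) {
    stop("c_eq must lie in [0, 1]", call. = FALSE)
  }
  if (!all(c("low_kv", "high_kv", "mixed") %in% names(e100_hu)) ||
      any(e100_hu <= 0)) {
    stop("e100_hu must be positive for channels low_kv, high_kv, mixed",
         call. = FALSE)
  }
  structure(
    list(variant = variant, grid_shape = grid_shape, voxel_mm = voxel_mm,
         nasal_tau_s = nasal_tau_s, kinetics = kinetics,
         baseline_hu = baseline_hu, e100_hu = e100_hu,
         noise_sigma_hu = noise_sigma_hu, seed = as.integer(seed)),
    class = "xe_phantom_spec"
  )
}

#' @export
print.xe_phantom_spec <- function(x, ...) {
  cat("<xe_phantom_spec> ", x$variant, ", grid ",
      paste(x$grid_shape, collapse = "x"),
      ", noise ", x$noise_sigma_hu, " HU, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Stylized mirror-symmetric geometry in normalized head coordinates.
# u: right(0) -> left(1), v: anterior -> posterior, w: inferior -> superior.
phantom_geometry <- function() {
  list(
    head_radius = 0.45,          # soft-tissue ellipsoid, normalized
    bone_inner = 0.85,           # soft tissue inside this fraction; shell = bone
    nasal = list(u = c(0.02, 0.12), v = c(0.25, 0.65), w = c(0.25, 0.55)),
    sinus = list(
      maxillary = list(du = 0.22, v = 0.45, w = 0.38, r = c(0.10, 0.12, 0.10)),
      sphenoid  = list(du = 0.08, v = 0.75, w = 0.45, r = c(0.06, 0.08, 0.07)),
      frontal   = list(du = 0.07, v = 0.25, w = 0.66, r = c(0.05, 0.06, 0.07))
    )
  )
}

#' Build the phantom label volume
#'
#' Deterministic stylized head: a soft-tissue ellipsoid with a bone shell,
#' two nasal-cavity boxes flanking a midline septum, and six mirror-
#' symmetric sinus ellipsoids. Mirror symmetry makes left/right signal
#' differences purely kinetic. Geometry is specified in normalized
#' coordinates, so it scales with `grid_shape`.
#'
#' @param spec An `xe_phantom_spec`.
#' @return 3-D integer array of label codes (see [region_labels()]), with
#'   attribute `labels`. Errors if the grid is too small to place every
#'   region.
#' @export
build_label_map <- function(spec) {
  stopifnot(inherits(spec, "xe_phantom_spec"))
  g <- phantom_geometry()
  dims <- spec$grid_shape
  labs <- region_labels()

  # voxel-center normalized coordinates
  u <- (seq_len(dims[1]) - 0.5) / dims[1]
  v <- (seq_len(dims[2]) - 0.5) / dims[2]
  w <- (seq_len(dims[3]) - 0.5) / dims[3]
  U <- array(rep(u, times = dims[2] * dims[3]), dim = dims)
  V <- array(rep(rep(v, each = dims[1]), times = dims[3]), dim = dims)
  W <- array(rep(w, each = dims[1] * dims[2]), dim = dims)

  r2 <- ((U - 0.5) / g$head_radius)^2 + ((V - 0.5) / g$head_radius)^2 +
    ((W - 0.5) / g$head_radius)^2
  lab <- array(labs[["background_air"]], dim = dims)
  lab[r2 <= 1] <- labs[["bone"]]
  lab[r2 <= g$bone_inner^2] <- labs[["soft_tissue"]]

  box <- function(ul, vl, wl) {
    U >= ul[1] & U < ul[2] & V >= vl[1] & V < vl[2] & W >= wl[1] & W < wl[2]
  }
  ellipsoid <- function(cu, cv, cw, r) {
    ((U - cu) / r[1])^2 + ((V - cv) / r[2])^2 + ((W - cw) / r[3])^2 <= 1
  }

  nb <- g$nasal
  lab[box(0.5 + nb$u, nb$v, nb$w)] <- labs[["nasal_left"]]
  lab[box(0.5 - rev(nb$u), nb$v, nb$w)] <- labs[["nasal_right"]]
  for (s in names(g$sinus)) {
    p <- g$sinus[[s]]
    lab[ellipsoid(0.5 + p$du, p$v, p$w, p$r)] <- labs[[paste0(s, "_L")]]
    lab[ellipsoid(0.5 - p$du, p$v, p$w, p$r)] <- labs[[paste0(s, "_R")]]
  }

  present <- labs %in% unique(as.vector(lab))
  if (!all(present)) {
    stop("grid ", paste(dims, collapse = "x"),
         " is too small to place region(s): ",
         paste(names(labs)[!present], collapse = ", "), call. = FALSE)
  }
  attr(lab, "labels") <- labs
  lab
}
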