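# Synthetic voxelized head phantom: concentric conductive shells plus small
# bilateral vestibular regions of interest (ROIs) buried medial to the
# mastoid electrode sites.

# Fixed label ids. Layer labels are 1..n_layers in legend order; ROI and pad
# labels live in reserved ranges so user-supplied volumes can coexist.
.roi_labels <- c(
  vestibule_left = 10L, scc_left = 11L,
  vestibule_right = 12L, scc_right = 13L,
  cochlea_left = 14L, cochlea_right = 15L
)
.gel_label_base <- 100L
.metal_label_base <- 200L

#' Phantom configuration
#'
#' Parameters of the synthetic layered-sphere head phantom. The default is a
#' four-shell head model (scalp / skull / CSF / gray matter with outer radii
#' 92 / 86 / 80 / 78 mm) around a 55 mm white-matter core, with one
#' vestibular ROI per side: a 3 mm-radius "vestibule" sphere centred 62 mm
#' from the origin along the left-mastoid direction, plus three mutually
#' orthogonal half-tori (major radius 4 mm, minor radius 1 mm) standing in
#' for the anterior / posterior / lateral semicircular canals. The right ROI
#' is the exact mirror image of the left about the mid-sagittal plane, unless
#' an asymmetry factor is applied.
#'
#' @param layer_radii_mm Outer radius of each concentric layer, strictly
#'   decreasing, ordered outermost to innermost.
#' @param layer_tissues Tissue name per layer (keys into
#'   [conductivity_table()]), same length as `layer_radii_mm`.
#' @param voxel_mm Isotropic voxel edge length (mm).
#' @param roi_spec Either `NULL` (no ROIs; used for plain benchmark spheres)
#'   or a list with `vestibule_center` (left-side centre, mm, head frame),
#'   `vestibule_radius` (mm), `canal_major_radius` and `canal_minor_radius`
#'   (mm) of the semicircular-canal tori.
#' @param asymmetry_factor Unitless scale applied to the right-side ROI
#'   linear dimensions about its own centre; 1 gives an exactly mirror-
#'   symmetric phantom.
#' @param include_cochlea If `TRUE`, add a small cochlea sphere per side
#'   (excluded from vestibular-network metrics).
#' @param roi_jitter_mm Optional uniform jitter (mm) added to the left ROI
#'   centre (mirrored on the right); 0 keeps the phantom fully deterministic.
#' @param grid_margin_mm Air margin beyond the outer radius so that stamped
#'   electrode pads (default thickness 5 mm) fit inside the grid.
#' @param seed Seed for the jitter option.
#' @return A list of class `"phantom_config"`.
#' @export
phantom_config <- function(layer_radii_mm = c(92, 86, 80, 78, 55),
                           layer_tissues = c("skin", "skull", "CSF",
                                             "gray matter", "white matter"),
                           voxel_mm = 2,
                           roi_spec = default_roi_spec(),
                           asymmetry_factor = 1,
                           include_cochlea = FALSE,
                           roi_jitter_mm = 0,
                           grid_margin_mm = 9,
                           seed = 42L) {
  if (length(layer_radii_mm) != length(layer_tissues))
    stop("layer_radii_mm and layer_tissues must have the same length")
  if (any(layer_radii_mm <= 0) || any(diff(layer_radii_mm) >= 0))
    stop("layer_radii_mm must be positive and strictly decreasing")
  if (!is.numeric(voxel_mm) || voxel_mm <= 0) stop("voxel_mm must be > 0")
  if (!is.numeric(asymmetry_factor) || asymmetry_factor <= 0)
    stop("asymmetry_factor must be > 0")
  if (grid_margin_mm < 5)
    stop("grid_margin_mm must leave room for electrode pads (>= 5 mm)")
  structure(list(
    layer_radii_mm = as.numeric(layer_radii_mm),
    layer_tissues = layer_tissues,
    voxel_mm = voxel_mm,
    roi_spec = roi_spec,
    asymmetry_factor = asymmetry_factor,
    include_cochlea = isTRUE(include_cochlea),
    roi_jitter_mm = roi_jitter_mm,
    grid_margin_mm = grid_margin_mm,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Default vestibular ROI specification
#'
#' The left vestibule centre sits 62 mm from the head-frame origin along the
#' left-mastoid electrode direction, i.e. directly medial to the mastoid pad,
#' inside the gray-matter compartment of the default phantom.
#' @return List with `vestibule_center`, `vestibule_radius`,
#'   `canal_major_radius`, `canal_minor_radius` (all mm).
#' @export
default_roi_spec <- function() {
  d <- site_direction(1L)
  list(
    vestibule_center = 62 * d,
    vestibule_radius = 3,
    canal_major_radius = 4,
    canal_minor_radius = 1
  )
}

# Torus mask helper: u* are displacement arrays from the ROI centre (already
# scaled by any asymmetry factor), `axis` is the torus normal.
.torus_mask <- function(ux, uy, uz, axis, R, rm) {
  if (axis == 1L) { rho <- sqrt(uy^2 + uz^2); ha <- ux }
  else if (axis == 2L) { rho <- sqrt(ux^2 + uz^2); ha <- uy }
  else { rho <- sqrt(ux^2 + uy^2); ha <- uz }
  (rho - R)^2 + ha^2 <= rm^2
}

# Masks for one side's ROI. side = -1 (left) or +1 (right); factor scales the
# right-side geometry about its centre.
.side_roi_masks <- function(co, center_left, spec, side, factor) {
  # center_left has negative x by convention; mirror for the right side.
  ctr <- center_left
  if (side > 0) ctr[1] <- -ctr[1]
  ux <- (co$X - ctr[1]) / factor
  uy <- (co$Y - ctr[2]) / factor
  uz <- (co$Z - ctr[3]) / factor
  vest <- ux^2 + uy^2 + uz^2 <= spec$vestibule_radius^2
  R <- spec$canal_major_radius; rm <- spec$canal_minor_radius
  # Three mutually orthogonal half-tori; the half-selection uses only y/z so
  # that the left and right canal sets are exact mirror images.
  scc <- (.torus_mask(ux, uy, uz, 2L, R, rm) & uz >= 0) |   # "anterior"
         (.torus_mask(ux, uy, uz, 1L, R, rm) & uz >= 0) |   # "posterior"
         (.torus_mask(ux, uy, uz, 3L, R, rm) & uy <= 0)     # "lateral"
  scc <- scc & !vest
  list(vestibule = vest, scc = scc, center = ctr)
}

#' Build a synthetic voxelized head phantom
#'
#' Voxelizes the concentric layers of a [phantom_config()] onto a cubic grid
#' centred on the head-frame origin (x right, y anterior, z superior), then
#' carves the bilateral vestibular ROIs into the brain compartment. Layer
#' labels are assigned outermost to innermost; ROI labels overwrite gray /
#' white matter only. The grid always has an odd number of voxels per axis so
#' the mid-sagittal plane passes through voxel centers and, for
#' `asymmetry_factor = 1`, the label volume is exactly mirror-symmetric.
#'
#' @param config A [phantom_config()].
#' @param conductivities A [conductivity_table()]; stored with the volume.
#' @return A `tissue_label_volume`: list with `labels` (3-D integer array,
#'   0 = exterior air), `spacing_mm`, `origin` (head-frame mm coordinates of
#'   voxel `[1,1,1]`'s centre), `legend` (data frame `label`, `name`,
#'   `tissue`), `config` and `conductivities`.
#' @examples
#' vol <- build_phantom(phantom_config(voxel_mm = 4))
#' table(vol$labels)[1:3]
#' @export
build_phantom <- function(config = phantom_config(),
                          conductivities = conductivity_table()) {
  stopifnot(inherits(config, "phantom_config"))
  h <- config$voxel_mm
  r_out <- config$layer_radii_mm[1]
  half <- r_out + config$grid_margin_mm
  n <- 2L * as.integer(ceiling(half / h)) + 1L
  dims <- c(n, n, n)
  co <- coord_arrays(dims, h)
  r2 <- co$X^2 + co$Y^2 + co$Z^2

  labels <- array(0L, dims)
  n_layers <- length(config$layer_radii_mm)
  for (k in seq_len(n_layers))
    labels[r2 <= config$layer_radii_mm[k]^2] <- k

  legend <- data.frame(
    label = seq_len(n_layers),
    name = config$layer_tissues,
    tissue = config$layer_tissues,
    stringsAsFactors = FALSE
  )

  if (!is.null(config$roi_spec)) {
    spec <- config$roi_spec
    ctr_l <- spec$vestibule_center
    if (ctr_l[1] >= 0)
      stop("left vestibule centre must have negative lateral (x) coordinate")
    if (config$roi_jitter_mm > 0) {
      jit <- with_local_seed(config$seed,
                             runif(3, -config$roi_jitter_mm, config$roi_jitter_mm))
      ctr_l <- ctr_l + jit
    }
    brain_labels <- which(config$layer_tissues %in% c("gray matter", "white matter"))
    if (!length(brain_labels))
      stop("phantom has no brain compartment (gray/white matter layer) for ROIs")
    for (side in c(-1, 1)) {
      factor <- if (side > 0) config$asymmetry_factor else 1
      m <- .side_roi_masks(co, ctr_l, spec, side, factor)
      for (comp in c("vestibule", "scc")) {
        mask <- m[[comp]]
        nm <- paste0(if (comp == "scc") "scc" else "vestibule",
                     if (side > 0) "_right" else "_left")
        lab <- .roi_labels[[nm]]
        host <- labels[mask]
        if (any(!host %in% brain_labels))
          stop("ROI '", nm, "' extends outside the brain compartment")
        if (sum(mask) < 8)
          stop("ROI under-resolved: '", nm, "' occupies ", sum(mask),
               " voxels (< 8) at voxel_mm = ", h)
        labels[mask] <- lab
        legend <- rbind(legend, data.frame(
          label = lab, name = nm,
          tissue = if (comp == "scc") "SCC" else "vestibule",
          stringsAsFactors = FALSE
        ))
      }
      if (config$include_cochlea) {
        cctr <- m$center + c(-side * 4, 3, -3)
        cmask <- (co$X - cctr[1])^2 + (co$Y - cctr[2])^2 + (co$Z - cctr[3])^2 <= 2.5^2
        cmask <- cmask & array(labels %in% brain_labels, dims)
        nm <- if (side > 0) "cochlea_right" else "cochlea_left"
        lab <- .roi_labels[[nm]]
        labels[cmask] <- lab
        legend <- rbind(legend, data.frame(
          label = lab, name = nm, tissue = "SCC", stringsAsFactors = FALSE
        ))
      }
    }
  }

  structure(list(
    labels = labels,
    spacing_mm = h,
    origin = rep(-(n - 1) / 2 * h, 3),
    legend = legend,
    config = config,
    conductivities = conductivities
  ), class = "tissue_label_volume")
}

#' @export
print.tissue_label_volume <- function(x, ...) {
  cat("<tissue_label_volume> ", paste(dim(x$labels), collapse = " x "),
      " voxels @ ", x$spacing_mm, " mm\n", sep = "")
  cat("tissues:", paste(x$legend$name, collapse = ", "), "\n")
  invisible(x)
}

#' Rescale the right-side vestibular ROI (anatomical asymmetry)
#'
#' Rebuilds the phantom with the right ROI's linear dimensions scaled by
#' `factor` about its centre, leaving the left side untouched. `factor = 1`
#' returns a voxel-wise identical volume. Must be applied before electrodes
#' are stamped.
#'
#' @param vol A `tissue_label_volume` built by [build_phantom()].
#' @param factor Positive scale factor (absolute, replacing any previous
#'   asymmetry factor).
#' @return A new `tissue_label_volume`.
#' @export
apply_asymmetry <- function(vol, factor) {
  stopifnot(inherits(vol, "tissue_label_volume"))
  if (!is.null(vol$pads))
    stop("apply_asymmetry() must be called before stamp_electrodes()")
  if (!is.numeric(factor) || factor <= 0) stop("factor must be > 0")
  cfg <- vol$config
  cfg$asymmetry_factor <- factor
  build_phantom(cfg, vol$conductivities)
}

# Label ids of a side's vestibular network (vestibule + SCC; cochlea excluded).
#' ROI label lookup
#'
#' @param vol A `tissue_label_volume`.
#' @param side `"left"` or `"right"`.
#' @param component `"network"` (vestibule + SCC), `"vestibule"` or `"scc"`.
#' @return Integer vector of label ids.
#' @export
roi_labels <- function(vol, side = c("left", "right"),
                       component = c("network", "vestibule", "scc")) {
  side <- match.arg(side)
  component <- match.arg(component)
  want <- switch(component,
    network = paste0(c("vestibule_", "scc_"), side),
    vestibule = paste0("vestibule_", side),
    scc = paste0("scc_", side)
  )
  labs <- vol$legend$label[vol$legend$name %in% want]
  if (!length(labs)) stop("phantom has no ROI labels for ", side, " ", component)
  labs
}

# Logical mask of voxels carrying any of the given labels.
#' @rdname roi_labels
#' @param labels Integer label ids.
#' @export
roi_mask <- function(vol, labels) {
  array(vol$labels %in% labels, dim(vol$labels))
}
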