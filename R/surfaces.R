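# Voxel-face interface surfaces and surface current integrals.

.surface_df <- function(a, axis, dir) {
  data.frame(a = a, axis = axis, dir = dir)
}

# Faces of the boundary of an arbitrary voxel set (TRUE side). The normal
# points from the set outward. Always closed in the discrete sense: the
# signed per-axis face counts sum to zero.
#' Boundary faces of a voxel set
#'
#' @param vol A `tissue_label_volume` (supplies dims and spacing).
#' @param mask Logical array marking the enclosed voxel set.
#' @return A `surface_face_set`: data frame with columns `a` (linear voxel
#'   index on the inside), `axis` (1 = x, 2 = y, 3 = z) and `dir` (+1/-1,
#'   normal pointing outward), with attributes `dims`, `spacing_mm`,
#'   `face_area_mm2`.
#' @export
mask_surface <- function(vol, mask) {
  dims <- dim(vol$labels)
  stopifnot(identical(dim(mask), dims))
  out <- vector("list", 6)
  n <- 0L
  for (axis in 1:3) {
    m1 <- switch(axis, mask[-dims[1], , ], mask[, -dims[2], ], mask[, , -dims[3]])
    m2 <- switch(axis, mask[-1, , ], mask[, -1, ], mask[, , -1])
    f <- array(FALSE, dims)
    if (axis == 1) f[-dims[1], , ] <- m1 & !m2
    else if (axis == 2) f[, -dims[2], ] <- m1 & !m2
    else f[, , -dims[3]] <- m1 & !m2
    idx <- which(f)
    out[[n <- n + 1L]] <- .surface_df(idx, rep(axis, length(idx)), rep(1L, length(idx)))
    f <- array(FALSE, dims)
    if (axis == 1) f[-1, , ] <- m2 & !m1
    else if (axis == 2) f[, -1, ] <- m2 & !m1
    else f[, , -1] <- m2 & !m1
    idx <- which(f)
    out[[n <- n + 1L]] <- .surface_df(idx, rep(axis, length(idx)), rep(-1L, length(idx)))
  }
  s <- do.call(rbind, out)
  structure(s, dims = dims, spacing_mm = vol$spacing_mm,
            face_area_mm2 = vol$spacing_mm^2,
            class = c("surface_face_set", "data.frame"))
}

#' Interface between two tissue label sets
#'
#' Returns exactly the voxel faces with one side labelled in `set_a` and the
#' other in `set_b`, normals oriented from `set_a` toward `set_b`. An empty
#' interface returns an empty face set (not an error).
#'
#' @param vol A `tissue_label_volume`.
#' @param set_a,set_b Disjoint integer label sets.
#' @return A `surface_face_set` (see [mask_surface()]); `a` indexes the
#'   `set_a`-side voxel.
#' @export
extract_interface_surface <- function(vol, set_a, set_b) {
  if (length(intersect(set_a, set_b)))
    stop("set_a and set_b must be disjoint")
  dims <- dim(vol$labels)
  in_a <- array(vol$labels %in% set_a, dims)
  in_b <- array(vol$labels %in% set_b, dims)
  out <- vector("list", 6)
  n <- 0L
  for (axis in 1:3) {
    a1 <- switch(axis, in_a[-dims[1], , ], in_a[, -dims[2], ], in_a[, , -dims[3]])
    a2 <- switch(axis, in_a[-1, , ], in_a[, -1, ], in_a[, , -1])
    b1 <- switch(axis, in_b[-dims[1], , ], in_b[, -dims[2], ], in_b[, , -dims[3]])
    b2 <- switch(axis, in_b[-1, , ], in_b[, -1, ], in_b[, , -1])
    f <- array(FALSE, dims)
    if (axis == 1) f[-dims[1], , ] <- a1 & b2
    else if (axis == 2) f[, -dims[2], ] <- a1 & b2
    else f[, , -dims[3]] <- a1 & b2
    idx <- which(f)
    out[[n <- n + 1L]] <- .surface_df(idx, rep(axis, length(idx)), rep(1L, length(idx)))
    f <- array(FALSE, dims)
    if (axis == 1) f[-1, , ] <- a2 & b1
    else if (axis == 2) f[, -1, ] <- a2 & b1
    else f[, , -1] <- a2 & b1
    idx <- which(f)
    out[[n <- n + 1L]] <- .surface_df(idx, rep(axis, length(idx)), rep(-1L, length(idx)))
  }
  s <- do.call(rbind, out)
  structure(s, dims = dims, spacing_mm = vol$spacing_mm,
            face_area_mm2 = vol$spacing_mm^2,
            set_a = set_a, set_b = set_b,
            class = c("surface_face_set", "data.frame"))
}

#' Closed surface around a set of ROI labels
#'
#' Boundary of the voxel set carrying the given labels (interface with
#' everything else, exterior included); closed by construction.
#' @param vol A `tissue_label_volume`.
#' @param labels Integer label ids.
#' @return A `surface_face_set`.
#' @export
roi_surface <- function(vol, labels) {
  s <- mask_surface(vol, roi_mask(vol, labels))
  attr(s, "roi_labels") <- labels
  s
}

# TRUE if the signed per-axis face sums vanish (discrete closedness).
surface_is_closed <- function(surface) {
  all(vapply(1:3, function(ax)
    sum(surface$dir[surface$axis == ax]) == 0L, logical(1)))
}

# Signed normal current (A) through each face, J.n evaluated *at the face*
# from the discrete face conductance: I_f = g (V_a - V_b) with the
# harmonic-mean conductance the solver itself uses. This is the discretely
# conservative flux (a voxel-averaged central-difference J is badly wrong
# across high-contrast interfaces such as skull/CSF). Faces whose far side
# is non-conductive carry zero flux (insulating boundary).
.face_currents <- function(efield, surface) {
  dims <- attr(surface, "dims")
  stopifnot(identical(dims, dim(efield$Emag)))
  if (is.null(efield$V) || is.null(efield$sigma))
    stop("efield must carry V and sigma (recompute with compute_efield())")
  h_m <- attr(surface, "spacing_mm") / 1000
  V <- efield$V
  sg <- efield$sigma
  flux <- numeric(nrow(surface))
  for (ax in 1:3) {
    sel <- surface$axis == ax
    if (!any(sel)) next
    stride <- axis_stride(dims, ax)
    a <- surface$a[sel]
    dirs <- surface$dir[sel]
    q <- a + dirs * stride
    sa <- sg[a]; sq <- sg[q]
    ok <- !is.na(V[a]) & !is.na(V[q]) & sa > 0 & sq > 0
    g <- ifelse(ok, h_m * 2 * sa * sq / (sa + sq), 0)
    dv <- ifelse(ok, V[a] - V[q], 0)
    flux[sel] <- g * dv
  }
  flux
}

#' Current entering a region of interest
#'
#' Total current crossing a closed ROI surface, computed as half the
#' unsigned surface flux \eqn{0.5 \sum_f |J\cdot n| A_f}: for a source-free
#' region the inflow equals the outflow, so half the unsigned flux is the
#' current passing through the region. Reported in microamperes. Note that
#' how the "ROI current" of the GVS literature is defined is not published;
#' this convention is this package's, and values may differ systematically
#' from tabulated ones.
#'
#' @param efield An `efield_volume` from [compute_efield()].
#' @param surface A closed `surface_face_set` around the ROI.
#' @return Current in uA.
#' @export
roi_inflow_current <- function(efield, surface) {
  if (!surface_is_closed(surface))
    stop("ROI surface is not closed")
  flux <- .face_currents(efield, surface)
  0.5 * sum(abs(flux)) * 1e6
}

#' Audit current conservation across a separating surface
#'
#' For a closed surface that separates the anode terminal from the cathode
#' terminal, the net signed flux must equal the injected current; for a
#' surface enclosing neither electrode it must vanish (divergence-free
#' interior).
#'
#' @param efield An `efield_volume`.
#' @param surface A closed `surface_face_set` (normals outward).
#' @param I_total_mA The configured injected current (mA).
#' @return List with `net_current_mA` (signed net outflow) and `rel_error`
#'   = `||net| - I| / I`.
#' @export
check_current_conservation <- function(efield, surface, I_total_mA) {
  flux <- .face_currents(efield, surface)
  net_mA <- sum(flux) * 1000
  list(net_current_mA = net_mA,
       rel_error = abs(abs(net_mA) - I_total_mA) / I_total_mA)
}

#' Fraction of injected current entering the cranial cavity
#'
#' Percentage of the injected current crossing the inner-skull boundary
#' (skull/CSF interface of the phantom): `100 * (0.5 * sum |J.n| A) /
#' I_total`. Current that enters the cavity must leave it again, so half the
#' unsigned flux is the current entering.
#'
#' @param efield An `efield_volume`.
#' @param surface The inner-skull `surface_face_set`, e.g.
#'   `extract_interface_surface(vol, skull_label, cranial_labels)`.
#' @param I_total_mA Injected current (mA).
#' @param vol Optional volume; when given, errors if an electrode label lies
#'   on the enclosed (`set_b`) side of the surface.
#' @return Percentage in `[0, 100]` (up to discretization error).
#' @export
cranial_current_fraction <- function(efield, surface, I_total_mA, vol = NULL) {
  if (!is.null(vol)) {
    pad_labels <- vol$legend$label[vol$legend$tissue %in% c("gel", "electrode")]
    inside <- attr(surface, "set_b") %||% attr(surface, "roi_labels")
    if (length(intersect(pad_labels, inside)))
      stop("surface encloses an electrode; the cranial fraction is undefined")
  }
  flux <- .face_currents(efield, surface)
  100 * (0.5 * sum(abs(flux))) / (I_total_mA / 1000)
}

#' Inner-skull (cranial cavity) surface of a phantom
#'
#' @param vol A `tissue_label_volume` whose legend contains a skull layer.
#' @return The skull-to-cranial-contents `surface_face_set`.
#' @export
inner_skull_surface <- function(vol) {
  skull <- vol$legend$label[vol$legend$tissue == "skull"]
  if (!length(skull)) stop("phantom has no skull layer")
  cranial_tissues <- c("CSF", "gray matter", "white matter", "SCC",
                       "vestibule", "blood", "cranial nerves", "air")
  cranial <- vol$legend$label[vol$legend$tissue %in% cranial_tissues]
  extract_interface_surface(vol, skull, cranial)
}
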