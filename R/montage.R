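# Electrode sites, the seven GVS montage presets, pad stamping and
# inter-electrode separations.

# Site direction calibration (head frame: x right, y anterior, z superior).
# Azimuths are measured in the horizontal plane from the posterior (-y) or
# anterior (+y) axis toward the site's side; elevation from the horizontal.
# The mastoid azimuth (57.327 deg from posterior, 15 deg below the horizon)
# is calibrated so that the mastoid-mastoid chord on the default 92 mm scalp
# is 149.62 mm, the classic bilateral-bipolar separation; the other angles
# are plausible scalp positions, not fits.
.site_defs <- list(
  list(id = 1L, name = "left mastoid",   base = "posterior", az = 57.327, el = -15, sx = -1),
  list(id = 2L, name = "right forehead", base = "anterior",  az = 25,     el = 35,  sx = 1),
  list(id = 3L, name = "right mastoid",  base = "posterior", az = 57.327, el = -15, sx = 1),
  list(id = 4L, name = "nape",           base = "posterior", az = 0,      el = -30, sx = 1),
  list(id = 5L, name = "left temple",    base = "lateral",   az = 90,     el = 0,   sx = -1),
  list(id = 6L, name = "right temple",   base = "lateral",   az = 90,     el = 0,   sx = 1),
  list(id = 7L, name = "left forehead",  base = "anterior",  az = 25,     el = 35,  sx = -1)
)

#' Electrode site directions
#'
#' Unit direction vectors (head frame, from the origin toward the scalp
#' point) for the seven electrode sites used by the GVS montage presets:
#' 1 left mastoid, 2 right forehead, 3 right mastoid, 4 nape, 5 left temple,
#' 6 right temple, 7 left forehead. Sites 1/3 and 5/6 and 2/7 are mirror
#' pairs about the mid-sagittal plane.
#'
#' @return Data frame with columns `site_id`, `name`, `dx`, `dy`, `dz`.
#' @export
electrode_sites <- function() {
  rows <- lapply(.site_defs, function(s) {
    a <- s$az * pi / 180
    e <- s$el * pi / 180
    d <- switch(s$base,
      posterior = c(s$sx * sin(a) * cos(e), -cos(a) * cos(e), sin(e)),
      anterior  = c(s$sx * sin(a) * cos(e),  cos(a) * cos(e), sin(e)),
      lateral   = c(s$sx * cos(e), 0, sin(e))
    )
    data.frame(site_id = s$id, name = s$name,
               dx = d[1], dy = d[2], dz = d[3], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Unit direction of one site.
site_direction <- function(site_id) {
  s <- electrode_sites()
  r <- s[s$site_id == site_id, ]
  if (!nrow(r)) stop("unknown electrode site ", site_id)
  d <- c(r$dx, r$dy, r$dz)
  d / sqrt(sum(d^2))
}

#' Construct an electrode pad
#'
#' @param site_id Integer site 1-7, or `NA` when `direction` is given.
#' @param polarity `"anode"` or `"cathode"`.
#' @param direction Optional explicit unit direction (overrides `site_id`).
#' @param diameter_mm Pad diameter (default 30 mm).
#' @param thickness_mm Total pad thickness, split equally between the gel
#'   layer (touching the scalp) and the metal layer capping it (default 5 mm).
#' @return A list of class `"electrode_pad"`.
#' @export
electrode_pad <- function(site_id = NA_integer_,
                          polarity = c("anode", "cathode"),
                          direction = NULL,
                          diameter_mm = 30, thickness_mm = 5) {
  polarity <- match.arg(polarity)
  if (is.null(direction)) direction <- site_direction(site_id)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-9) direction <- direction / nrm
  structure(list(site_id = site_id, polarity = polarity,
                 direction = direction, diameter_mm = diameter_mm,
                 thickness_mm = thickness_mm,
                 terminal = polarity), class = "electrode_pad")
}

.montage_defs <- list(
  montage1 = list(alias = "bilateral_bipolar",
                  anodes = 1L, cathodes = 3L,
                  annotation = "virtual roll to cathodal side; sway rolls to the anodal side"),
  montage2 = list(alias = "bilateral_monopolar",
                  anodes = c(1L, 3L), cathodes = 2L,
                  annotation = "virtual forward pitch; backward sway toward anodes"),
  montage3 = list(alias = "unilateral_monopolar",
                  anodes = 1L, cathodes = 2L,
                  annotation = "predominantly roll to cathodal side; oblique sway toward anode"),
  montage4 = list(alias = "sdas",
                  anodes = c(1L, 3L), cathodes = c(5L, 6L),
                  annotation = "virtual forward pitch; backward sway toward anodes"),
  montage5 = list(alias = "odas",
                  anodes = c(1L, 6L), cathodes = c(3L, 5L),
                  annotation = "virtual yaw toward right; sway yaws toward left"),
  montage6 = list(alias = "mastoid_nape",
                  anodes = 1L, cathodes = 4L,
                  annotation = "virtual roll away from anodal side; sway rolls to the anodal side"),
  montage7 = list(alias = "mastoid_forehead",
                  anodes = 1L, cathodes = 7L,
                  annotation = "virtual forward pitch toward cathode; backward sway toward anode")
)

#' GVS montage presets
#'
#' The seven electrode placements compared in the GVS current-flow
#' literature, by number (`"montage1"` .. `"montage7"`) or alias:
#' \describe{
#'   \item{montage1 / bilateral_bipolar}{anode left mastoid (1), cathode right mastoid (3)}
#'   \item{montage2 / bilateral_monopolar}{anodes both mastoids (1, 3), cathode right forehead (2)}
#'   \item{montage3 / unilateral_monopolar}{anode left mastoid (1), cathode right forehead (2)}
#'   \item{montage4 / sdas}{anodes both mastoids (1, 3), cathodes both temples (5, 6)}
#'   \item{montage5 / odas}{anodes left mastoid + right temple (1, 6), cathodes right mastoid + left temple (3, 5)}
#'   \item{montage6 / mastoid_nape}{anode left mastoid (1), cathode nape (4)}
#'   \item{montage7 / mastoid_forehead}{anode left mastoid (1), cathode left forehead (7)}
#' }
#' All anodes of a montage share one equipotential terminal carrying the full
#' injected current; all cathodes share the grounded terminal.
#'
#' @param name Preset name or alias.
#' @param diameter_mm,thickness_mm Pad geometry passed to [electrode_pad()].
#' @return A list of class `"montage"` with `name`, `pads`, `annotation`.
#' @examples
#' get_montage("bilateral_bipolar")
#' @export
get_montage <- function(name, diameter_mm = 30, thickness_mm = 5) {
  key <- names(.montage_defs)[match(name, names(.montage_defs))]
  if (is.na(key)) {
    aliases <- vapply(.montage_defs, `[[`, "", "alias")
    key <- names(.montage_defs)[match(name, aliases)]
  }
  if (is.na(key))
    stop("unknown montage '", name, "'; valid names: ",
         paste(c(names(.montage_defs),
                 vapply(.montage_defs, `[[`, "", "alias")), collapse = ", "))
  def <- .montage_defs[[key]]
  pads <- c(
    lapply(def$anodes, electrode_pad, polarity = "anode",
           diameter_mm = diameter_mm, thickness_mm = thickness_mm),
    lapply(def$cathodes, electrode_pad, polarity = "cathode",
           diameter_mm = diameter_mm, thickness_mm = thickness_mm)
  )
  montage(pads, name = key, annotation = def$annotation)
}

#' Construct a custom montage
#'
#' @param pads List of [electrode_pad()]s; at least one anode and one cathode.
#' @param name Montage name.
#' @param annotation Optional free-text motion annotation.
#' @return A list of class `"montage"`.
#' @export
montage <- function(pads, name = "custom", annotation = NULL) {
  pol <- vapply(pads, `[[`, "", "polarity")
  if (!any(pol == "anode") || !any(pol == "cathode"))
    stop("a montage needs at least one anode and one cathode pad")
  structure(list(name = name, pads = pads, annotation = annotation),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  pol <- vapply(x$pads, `[[`, "", "polarity")
  sites <- vapply(x$pads, function(p) as.integer(p$site_id), integer(1))
  cat("<montage> ", x$name, ": anodes {",
      paste(sites[pol == "anode"], collapse = ","), "}, cathodes {",
      paste(sites[pol == "cathode"], collapse = ","), "}\n", sep = "")
  if (!is.null(x$annotation)) cat("  ", x$annotation, "\n", sep = "")
  invisible(x)
}

#' Stamp electrode pads onto a phantom
#'
#' Adds a conductive-gel layer and a metal cap per pad. Each pad is a
#' spherical-cap disc normal to the scalp: gel occupies the shell between the
#' scalp radius and scalp + thickness/2, metal the shell above it, both
#' restricted to the pad radius around the pad axis. Per-pad gel and metal
#' labels are appended to the legend.
#'
#' @param vol A `tissue_label_volume` (no pads stamped yet for these voxels).
#' @param montage A `"montage"` or preset name.
#' @return The volume with pads stamped, `vol$pads` describing them and
#'   `vol$montage` recording the montage.
#' @export
stamp_electrodes <- function(vol, montage) {
  stopifnot(inherits(vol, "tissue_label_volume"))
  if (is.character(montage)) montage <- get_montage(montage)
  stopifnot(inherits(montage, "montage"))
  r_scalp <- vol$config$layer_radii_mm[1]
  h <- vol$spacing_mm
  dims <- dim(vol$labels)
  co <- coord_arrays(dims, h)
  r <- sqrt(co$X^2 + co$Y^2 + co$Z^2)
  skin_label <- vol$legend$label[1]
  pads <- data.frame()
  n_prev <- if (is.null(vol$pads)) 0L else nrow(vol$pads)
  for (i in seq_along(montage$pads)) {
    p <- montage$pads[[i]]
    d <- p$direction
    if (abs(sqrt(sum(d^2)) - 1) > 1e-9) stop("pad direction is not a unit vector")
    t_half <- p$thickness_mm / 2
    along <- co$X * d[1] + co$Y * d[2] + co$Z * d[3]
    rho2 <- pmax(0, r^2 - along^2)
    in_disc <- rho2 <= (p$diameter_mm / 2)^2 & along > 0
    gel_mask <- in_disc & r > r_scalp & r <= r_scalp + t_half
    metal_mask <- in_disc & r > r_scalp + t_half & r <= r_scalp + 2 * t_half
    if (!any(gel_mask) || !any(metal_mask))
      stop("pad ", i, " does not intersect the scalp surface region")
    if (any(vol$labels[gel_mask] != 0L) || any(vol$labels[metal_mask] != 0L))
      stop("electrode pads overlap an existing pad (or tissue); ",
           "each scalp site can be stamped once")
    k <- n_prev + i
    gel_lab <- .gel_label_base + k
    met_lab <- .metal_label_base + k
    vol$labels[gel_mask] <- gel_lab
    vol$labels[metal_mask] <- met_lab
    vol$legend <- rbind(vol$legend,
      data.frame(label = c(gel_lab, met_lab),
                 name = paste0(c("gel_", "electrode_"), k),
                 tissue = c("gel", "electrode"), stringsAsFactors = FALSE))
    # gel must touch the scalp somewhere along the pad axis
    touch <- .faces_between(vol$labels, gel_lab, skin_label)
    if (!touch)
      stop("pad ", i, " gel layer does not contact the scalp")
    pads <- rbind(pads, data.frame(
      pad = k, site_id = p$site_id, polarity = p$polarity,
      gel_label = gel_lab, metal_label = met_lab,
      dx = d[1], dy = d[2], dz = d[3],
      diameter_mm = p$diameter_mm, thickness_mm = p$thickness_mm,
      stringsAsFactors = FALSE))
  }
  vol$pads <- if (n_prev) rbind(vol$pads, pads) else pads
  vol$montage <- montage
  vol
}

# TRUE if any voxel face separates label a from label b.
.faces_between <- function(labels, a, b) {
  dims <- dim(labels)
  for (axis in 1:3) {
    i1 <- switch(axis, labels[-dims[1], , ], labels[, -dims[2], ], labels[, , -dims[3]])
    i2 <- switch(axis, labels[-1, , ], labels[, -1, ], labels[, , -1])
    if (any((i1 == a & i2 == b) | (i1 == b & i2 == a))) return(TRUE)
  }
  FALSE
}

#' Inter-electrode separations
#'
#' Straight-line (chord) distance in mm between pad-centre scalp points for
#' every pad pair of a montage, evaluated on the phantom's scalp sphere.
#'
#' @param montage A `"montage"` or preset name.
#' @param vol Optional `tissue_label_volume` supplying the scalp radius.
#' @param scalp_radius_mm Scalp radius used when `vol` is missing.
#' @return Data frame with one row per unordered pad pair: sites, polarities
#'   and `separation_mm`.
#' @examples
#' electrode_separation("bilateral_bipolar")
#' @export
electrode_separation <- function(montage, vol = NULL, scalp_radius_mm = 92) {
  if (is.character(montage)) montage <- get_montage(montage)
  R <- if (!is.null(vol)) vol$config$layer_radii_mm[1] else scalp_radius_mm
  pts <- t(vapply(montage$pads, function(p) R * p$direction, numeric(3)))
  pol <- vapply(montage$pads, `[[`, "", "polarity")
  site <- vapply(montage$pads, function(p) as.integer(p$site_id), integer(1))
  out <- data.frame()
  np <- nrow(pts)
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (j <= i) next
    out <- rbind(out, data.frame(
      site_a = site[i], polarity_a = pol[i],
      site_b = site[j], polarity_b = pol[j],
      separation_mm = sqrt(sum((pts[i, ] - pts[j, ])^2)),
      stringsAsFactors = FALSE))
  }
  out
}
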