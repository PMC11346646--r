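# NIfTI / YAML / JSON interchange for phantoms, configurations and fields.

# Head-frame affine: voxel indices (0-based) to mm coordinates.
.vol_affine <- function(vol) {
  a <- diag(c(rep(vol$spacing_mm, 3), 1))
  a[1:3, 4] <- vol$origin
  structure(a, dimnames = NULL)
}

#' Write / read a tissue label volume as NIfTI
#'
#' The label array is stored as integer NIfTI with the head frame in the
#' affine; the legend and phantom configuration go to a JSON sidecar
#' (`<path>.json`), so any external segmentation using the same legend can
#' be read back and solved.
#'
#' @param vol A `tissue_label_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$labels + 0L)
  RNifti::qform(img) <- structure(.vol_affine(vol), code = 2L)
  RNifti::writeNifti(img, path)
  sidecar <- paste0(path, ".json")
  cfg <- vol$config
  cfg$roi_spec <- lapply(cfg$roi_spec, I)
  jsonlite::write_json(list(
    legend = vol$legend,
    spacing_mm = vol$spacing_mm,
    origin = vol$origin,
    config = list(
      layer_radii_mm = cfg$layer_radii_mm,
      layer_tissues = cfg$layer_tissues,
      voxel_mm = cfg$voxel_mm,
      asymmetry_factor = cfg$asymmetry_factor,
      include_cochlea = cfg$include_cochlea,
      grid_margin_mm = cfg$grid_margin_mm,
      seed = cfg$seed
    )
  ), sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_label_volume
#' @param conductivities A [conductivity_table()] attached to the volume.
#' @export
read_label_volume <- function(path, conductivities = conductivity_table()) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  labels <- array(as.integer(img), dim(img))
  cfg <- side$config
  config <- phantom_config(
    layer_radii_mm = cfg$layer_radii_mm,
    layer_tissues = cfg$layer_tissues,
    voxel_mm = cfg$voxel_mm,
    roi_spec = NULL,
    asymmetry_factor = cfg$asymmetry_factor %||% 1,
    include_cochlea = isTRUE(cfg$include_cochlea),
    grid_margin_mm = cfg$grid_margin_mm %||% 9,
    seed = cfg$seed %||% 42L
  )
  structure(list(
    labels = labels,
    spacing_mm = side$spacing_mm,
    origin = side$origin,
    legend = as.data.frame(side$legend, stringsAsFactors = FALSE),
    config = config,
    conductivities = conductivities
  ), class = "tissue_label_volume")
}

#' Write a scalar field volume as NIfTI
#'
#' @param field 3-D numeric array on the phantom grid (e.g. `potential$V`
#'   or `efield$Emag`).
#' @param vol The `tissue_label_volume` supplying grid geometry.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_volume <- function(field, vol, path) {
  stopifnot(identical(dim(field), dim(vol$labels)))
  img <- RNifti::asNifti(field)
  RNifti::qform(img) <- structure(.vol_affine(vol), code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a phantom configuration from YAML
#'
#' Fields mirror [phantom_config()]; absent fields use the defaults.
#' @param path YAML file path.
#' @return A `phantom_config`.
#' @export
read_phantom_config <- function(path) {
  y <- yaml::read_yaml(path)
  roi <- if (is.null(y$roi_spec)) default_roi_spec() else {
    r <- y$roi_spec
    list(vestibule_center = as.numeric(r$vestibule_center),
         vestibule_radius = r$vestibule_radius %||% 3,
         canal_major_radius = r$canal_major_radius %||% 4,
         canal_minor_radius = r$canal_minor_radius %||% 1)
  }
  if (isTRUE(y$no_roi)) roi <- NULL
  phantom_config(
    layer_radii_mm = y$layer_radii_mm %||% c(92, 86, 80, 78, 55),
    layer_tissues = y$layer_tissues %||% c("skin", "skull", "CSF",
                                           "gray matter", "white matter"),
    voxel_mm = y$voxel_mm %||% 2,
    roi_spec = roi,
    asymmetry_factor = y$asymmetry_factor %||% 1,
    include_cochlea = isTRUE(y$include_cochlea),
    roi_jitter_mm = y$roi_jitter_mm %||% 0,
    grid_margin_mm = y$grid_margin_mm %||% 9,
    seed = y$seed %||% 42L
  )
}

#' Read a montage from YAML
#'
#' A preset reference (`preset: montage3`) or an explicit pad list, each pad
#' with `site` (1-7) or `direction`, `polarity`, and optional `diameter_mm`
#' / `thickness_mm`.
#' @param path YAML file path.
#' @return A `"montage"`.
#' @export
read_montage <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$preset)) return(get_montage(y$preset))
  pads <- lapply(y$pads, function(p)
    electrode_pad(site_id = p$site %||% NA_integer_,
                  polarity = p$polarity,
                  direction = if (!is.null(p$direction)) as.numeric(p$direction),
                  diameter_mm = p$diameter_mm %||% 30,
                  thickness_mm = p$thickness_mm %||% 5))
  montage(pads, name = y$name %||% "custom", annotation = y$annotation)
}
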