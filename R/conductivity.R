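#' Tissue conductivity tables
#'
#' Isotropic, homogeneous electrical conductivities (S/m) assigned to each
#' tissue compartment. The `"primary"` set holds the values used throughout
#' the GVS current-flow literature for this kind of model: skin 0.465,
#' skull 0.01, CSF 1.65, gray matter 0.276, white matter 0.126, air 1e-7,
#' cranial nerves 0.017126, ear cartilage 0.16113, semicircular canals (SCC)
#' 2, blood 0.7, electrode gel 1.4 and metal electrode 5.8e7. The
#' `"weighted_mean"` set overrides the five major tissues with weighted
#' average mean values from a conductivity meta-analysis: skin 0.413,
#' skull 0.016, CSF 1.71, gray matter 0.466, white matter 0.216.
#'
#' The vestibule compartment is assigned the same conductivity as the SCC
#' (2 S/m): both are fluid-filled inner-ear spaces dominated by endolymph /
#' perilymph, and no separate literature value is carried for the vestibule.
#'
#' @param set_id `"primary"` (default) or `"weighted_mean"`.
#' @return A named numeric vector of conductivities in S/m with class
#'   `"conductivity_table"` and attribute `set_id`.
#' @examples
#' ct <- conductivity_table()
#' ct[["skull"]]
#' @export
conductivity_table <- function(set_id = c("primary", "weighted_mean")) {
  set_id <- match.arg(set_id)
  sigma <- c(
    "skin"           = 0.465,
    "skull"          = 0.01,
    "CSF"            = 1.65,
    "gray matter"    = 0.276,
    "white matter"   = 0.126,
    "air"            = 1e-7,
    "cranial nerves" = 0.017126,
    "ear cartilage"  = 0.16113,
    "SCC"            = 2,
    "vestibule"      = 2,
    "blood"          = 0.7,
    "gel"            = 1.4,
    "electrode"      = 5.8e7
  )
  if (set_id == "weighted_mean") {
    sigma[c("skin", "skull", "CSF", "gray matter", "white matter")] <-
      c(0.413, 0.016, 1.71, 0.466, 0.216)
  }
  structure(sigma, set_id = set_id, class = "conductivity_table")
}

#' @export
print.conductivity_table <- function(x, ...) {
  cat("<conductivity_table> set:", attr(x, "set_id"), "\n")
  print(unclass(x))
  invisible(x)
}

# Per-voxel conductivity array (S/m) for a label volume; exterior (label 0)
# gets 0 and is excluded from the solve.
sigma_array <- function(vol, conductivities = vol$conductivities) {
  stopifnot(inherits(vol, "tissue_label_volume"))
  legend <- vol$legend
  key <- legend$tissue[match(vol$labels, legend$label)]
  miss <- setdiff(unique(key[!is.na(key)]), names(conductivities))
  if (length(miss))
    stop("no conductivity value for tissue(s): ", paste(miss, collapse = ", "))
  sig <- unname(conductivities[key])
  sig[is.na(sig)] <- 0
  array(sig, dim(vol$labels))
}
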