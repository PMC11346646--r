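# Shared fixtures built in code.

# Minimal hand-built label volume (no phantom geometry), for solver-level
# tests. `labels` is a 3-D integer array; legend maps labels to conductivity
# keys of `ct`.
make_test_volume <- function(labels, spacing_mm, legend, ct) {
  structure(list(
    labels = labels,
    spacing_mm = spacing_mm,
    origin = rep(0, 3),
    legend = legend,
    config = NULL,
    conductivities = ct
  ), class = "tissue_label_volume")
}

# 1 x 1 x n conductive rod with metal terminal voxels at both ends.
# Cross-section = spacing^2; tissue conductivity `sigma`.
make_rod <- function(n_tissue = 10, spacing_mm = 10, sigma = 0.5) {
  n <- n_tissue + 2L
  labels <- array(0L, c(1L, 1L, n))
  labels[1, 1, 1] <- 201L
  labels[1, 1, n] <- 202L
  labels[1, 1, 2:(n - 1)] <- 1L
  ct <- structure(c(tissue = sigma, electrode = 5.8e7),
                  set_id = "test", class = "conductivity_table")
  legend <- data.frame(label = c(1L, 201L, 202L),
                       name = c("tissue", "anode_metal", "cathode_metal"),
                       tissue = c("tissue", "electrode", "electrode"),
                       stringsAsFactors = FALSE)
  vol <- make_test_volume(labels, spacing_mm, legend, ct)
  terms <- list(list(labels = 201L, type = "current", share = 1, name = "anode"),
                list(labels = 202L, type = "ground", name = "cathode"))
  list(vol = vol, terminals = terms)
}

# Small three-layer sphere phantom with three pads (two sharing the anode
# terminal), for superposition/terminal tests at low cost.
make_mini_sphere <- function(voxel_mm = 3) {
  tissues <- c("skin", "skull", "gray matter")
  ct <- conductivity_table()
  cfg <- phantom_config(layer_radii_mm = c(46, 43, 40), layer_tissues = tissues,
                        voxel_mm = voxel_mm, roi_spec = NULL)
  build_phantom(cfg, ct)
}

# A fake efield_volume with prescribed uniform current density along +x,
# on a uniform-conductivity grid (V linear in x).
make_uniform_J_field <- function(dims, spacing_mm, J = 1, sigma = 1) {
  co <- vestibflow:::coord_arrays(dims, spacing_mm)
  E <- J / sigma
  V <- -E * co$X / 1000  # volts, E = -dV/dx
  z <- array(0, dims)
  structure(list(
    Ex = array(E, dims), Ey = z, Ez = z,
    Emag = array(E, dims),
    Jx = array(J, dims), Jy = z, Jz = z,
    V = V, sigma = array(sigma, dims),
    spacing_mm = spacing_mm
  ), class = "efield_volume")
}

# Mirror a label volume about the mid-sagittal plane, swapping left/right
# ROI labels.
mirror_labels <- function(labels) {
  m <- labels[rev(seq_len(dim(labels)[1])), , ]
  out <- m
  out[m == 10L] <- 12L; out[m == 12L] <- 10L
  out[m == 11L] <- 13L; out[m == 13L] <- 11L
  out
}
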