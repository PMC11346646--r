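# Electric field and current density derived from the solved potential.

# Gradient of V along one axis (V/m): central differences where both
# neighbours are defined, one-sided at conductor boundaries, 0 where no
# neighbour exists.
.grad_axis <- function(V, axis, h_m) {
  dims <- dim(V)
  n <- dims[axis]
  shift <- function(k) {
    # V shifted so that element [i] holds V[i + k] along `axis` (NA padded)
    out <- array(NA_real_, dims)
    src <- seq_len(n - abs(k))
    if (k > 0) {
      if (axis == 1) out[src, , ] <- V[src + k, , ]
      else if (axis == 2) out[, src, ] <- V[, src + k, ]
      else out[, , src] <- V[, , src + k]
    } else {
      dst <- src + abs(k)
      if (axis == 1) out[dst, , ] <- V[src, , ]
      else if (axis == 2) out[, dst, ] <- V[, src, ]
      else out[, , dst] <- V[, , src]
    }
    out
  }
  Vp <- shift(1L)
  Vm <- shift(-1L)
  has_p <- !is.na(Vp)
  has_m <- !is.na(Vm)
  g <- array(0, dims)
  both <- has_p & has_m
  g[both] <- (Vp[both] - Vm[both]) / (2 * h_m)
  fwd <- has_p & !has_m
  g[fwd] <- (Vp[fwd] - V[fwd]) / h_m
  bwd <- has_m & !has_p
  g[bwd] <- (V[bwd] - Vm[bwd]) / h_m
  g[is.na(V)] <- NA_real_
  g
}

#' Electric field and current density from a potential field
#'
#' Computes \eqn{E = -\nabla V} (V/m) by voxel-centred finite differences
#' (central where both neighbours are conductive, one-sided at conductor
#' boundaries), the field magnitude, and the current density
#' \eqn{J = \sigma E} (A/m^2) using the per-voxel conductivity.
#'
#' @param potential A `"potential_field"` (or bare 3-D array of volts).
#' @param vol The `tissue_label_volume` the potential was solved on.
#' @param conductivities A [conductivity_table()].
#' @return An `efield_volume`: list of 3-D arrays `Ex`, `Ey`, `Ez`, `Emag`
#'   (V/m), `Jx`, `Jy`, `Jz` (A/m^2), `NA` outside the conductor, plus
#'   `spacing_mm`.
#' @export
compute_efield <- function(potential, vol, conductivities = vol$conductivities) {
  V <- if (inherits(potential, "potential_field")) potential$V else potential
  stopifnot(is.array(V), length(dim(V)) == 3)
  if (!identical(dim(V), dim(vol$labels)))
    stop("potential and volume grids do not match")
  if (inherits(potential, "potential_field") &&
      !isTRUE(all.equal(potential$spacing_mm, vol$spacing_mm)))
    stop("potential and volume voxel spacings do not match")
  h_m <- vol$spacing_mm / 1000
  Ex <- -.grad_axis(V, 1L, h_m)
  Ey <- -.grad_axis(V, 2L, h_m)
  Ez <- -.grad_axis(V, 3L, h_m)
  Emag <- sqrt(Ex^2 + Ey^2 + Ez^2)
  sigma <- sigma_array(vol, conductivities)
  structure(list(
    Ex = Ex, Ey = Ey, Ez = Ez, Emag = Emag,
    Jx = sigma * Ex, Jy = sigma * Ey, Jz = sigma * Ez,
    V = V, sigma = sigma,
    spacing_mm = vol$spacing_mm
  ), class = "efield_volume")
}

#' @export
print.efield_volume <- function(x, ...) {
  cat("<efield_volume> ", paste(dim(x$Emag), collapse = " x "),
      " voxels; |E| range ",
      paste(signif(range(x$Emag, na.rm = TRUE), 3), collapse = " .. "),
      " V/m\n", sep = "")
  invisible(x)
}
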