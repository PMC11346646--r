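# Assembly and solution of the discrete volume-conduction problem
# div(sigma grad V) = 0 with current-controlled terminals.

# Face conductances (S) along one axis. Both endpoints must be conductive
# (sigma > 0); exterior faces get 0, which is the Neumann (insulated)
# condition by omission. Harmonic mean: g = (A/h) * 2 s1 s2 / (s1 + s2),
# and A/h = h for a cubic voxel (h in meters).
.face_conductance <- function(sigma, axis, h_m) {
  dims <- dim(sigma)
  g <- array(0, dims)
  s1 <- switch(axis, sigma[-dims[1], , ], sigma[, -dims[2], ], sigma[, , -dims[3]])
  s2 <- switch(axis, sigma[-1, , ], sigma[, -1, ], sigma[, , -1])
  gv <- ifelse(s1 > 0 & s2 > 0, h_m * 2 * s1 * s2 / (s1 + s2), 0)
  if (axis == 1) g[-dims[1], , ] <- gv
  else if (axis == 2) g[, -dims[2], ] <- gv
  else g[, , -dims[3]] <- gv
  g
}

#' Assemble the discrete volume-conduction system
#'
#' Builds the finite-volume operator for \eqn{\nabla\cdot(\sigma\nabla V)=0}
#' on a stamped phantom: one unknown per conductive voxel, harmonic-mean face
#' conductances, zero-flux (Neumann) exterior faces by omission. All metal
#' voxels of the anode terminal are collapsed into a single equipotential
#' unknown that carries the total-current constraint; cathode metal voxels
#' are fixed at 0 V (the ground reference). The operator is symmetric
#' positive definite after grounding; its rows sum to zero over interior
#' voxels (discrete current conservation).
#'
#' @param vol A `tissue_label_volume` with electrodes stamped
#'   ([stamp_electrodes()]), unless explicit `terminals` are given.
#' @param conductivities A [conductivity_table()].
#' @param terminals Optional explicit terminal list overriding the stamped
#'   montage; each element is `list(labels =, type = "current"|"ground",
#'   share =)` where `share` is the fraction of the injected current carried
#'   by that terminal (anode 1, floating conductor 0).
#' @return A list of class `"discrete_system"`.
#' @export
assemble_system <- function(vol, conductivities = vol$conductivities,
                            terminals = NULL) {
  stopifnot(inherits(vol, "tissue_label_volume"))
  if (is.null(terminals)) {
    if (is.null(vol$pads))
      stop("no electrodes stamped and no explicit terminals given")
    an <- vol$pads$metal_label[vol$pads$polarity == "anode"]
    ca <- vol$pads$metal_label[vol$pads$polarity == "cathode"]
    terminals <- list(
      list(labels = an, type = "current", share = 1, name = "anode"),
      list(labels = ca, type = "ground", name = "cathode")
    )
  }
  sigma <- sigma_array(vol, conductivities)
  dims <- dim(sigma)
  h_m <- vol$spacing_mm / 1000
  gx <- .face_conductance(sigma, 1L, h_m)
  gy <- .face_conductance(sigma, 2L, h_m)
  gz <- .face_conductance(sigma, 3L, h_m)

  ground_labels <- unlist(lapply(Filter(function(t) t$type == "ground",
                                        terminals), `[[`, "labels"))
  if (!length(ground_labels)) stop("at least one ground (cathode) terminal is required")
  cur_terms <- Filter(function(t) t$type == "current", terminals)
  if (!length(cur_terms)) stop("at least one current (anode) terminal is required")

  active <- vol$labels > 0L
  ground <- array(vol$labels %in% ground_labels, dims)
  if (!any(ground)) stop("no cathode voxels found in the volume")
  term_masks <- lapply(cur_terms, function(t)
    array(vol$labels %in% t$labels, dims))
  in_term <- Reduce(`|`, term_masks)
  ordinary <- active & !ground & !in_term

  uidx <- array(0L, dims)
  n0 <- sum(ordinary)
  uidx[ordinary] <- seq_len(n0)
  for (ti in seq_along(term_masks)) {
    if (!any(term_masks[[ti]]))
      stop("current terminal ", ti, " has no voxels in the volume")
    uidx[term_masks[[ti]]] <- n0 + ti
  }
  uidx[ground] <- -1L
  n <- n0 + length(term_masks)

  reach <- fv_reachable_from_fixed(as.integer(dims), uidx, gx, gy, gz, n)
  for (ti in seq_along(cur_terms)) {
    if (!reach[n0 + ti])
      stop("singular system: current terminal '",
           cur_terms[[ti]]$name %||% ti,
           "' is not connected to the cathode through conductive tissue")
  }

  structure(list(
    dims = as.integer(dims),
    spacing_mm = vol$spacing_mm,
    uidx = uidx, gx = gx, gy = gy, gz = gz,
    n_unknowns = n, n_ordinary = n0,
    terminals = lapply(seq_along(cur_terms), function(ti) {
      t <- cur_terms[[ti]]
      list(name = t$name %||% paste0("terminal", ti), id = n0 + ti,
           share = t$share %||% 0, labels = t$labels)
    }),
    ground_labels = ground_labels
  ), class = "discrete_system")
}

#' @export
print.discrete_system <- function(x, ...) {
  cat("<discrete_system> ", x$n_unknowns, " unknowns (",
      length(x$terminals), " current terminal(s)) on ",
      paste(x$dims, collapse = " x "), " grid\n", sep = "")
  invisible(x)
}

# Materialize the operator as a dense matrix (small systems / tests only).
as_dense_operator <- function(system) {
  n <- system$n_unknowns
  if (n > 5000) stop("refusing to densify a system with > 5000 unknowns")
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    A[, j] <- fv_matvec(system$dims, system$uidx,
                        system$gx, system$gy, system$gz, e)
  }
  A
}

#' Solve for the electric potential
#'
#' Solves the assembled system by Jacobi-preconditioned conjugate gradient
#' with a relative-residual stopping rule, injecting `I_total_mA` at the
#' anode terminal and holding the cathode terminal at 0 V.
#'
#' @param system A `"discrete_system"` from [assemble_system()].
#' @param I_total_mA Total injected current in mA (default 1).
#' @param tol Relative residual tolerance (default 1e-6).
#' @param max_iter Iteration cap; non-convergence raises an error carrying
#'   the residual history (`condition$resid_history`).
#' @param x0 Optional initial guess (length `n_unknowns`); the converged
#'   solution is independent of it to within the tolerance.
#' @return A list of class `"potential_field"`: `V` (3-D array, volts, `NA`
#'   outside the conductor), `terminal_potentials`, `I_total_mA` and a
#'   `report` with iterations, final relative residual and the delivered
#'   current per terminal.
#' @export
solve_potential <- function(system, I_total_mA = 1, tol = 1e-6,
                            max_iter = 20000L, x0 = NULL) {
  stopifnot(inherits(system, "discrete_system"))
  if (!is.numeric(I_total_mA) || I_total_mA <= 0) stop("I_total_mA must be > 0")
  n <- system$n_unknowns
  b <- numeric(n)
  for (t in system$terminals) b[t$id] <- t$share * I_total_mA / 1000
  res <- fv_pcg(system$dims, system$uidx, system$gx, system$gy, system$gz,
                b, tol, as.integer(max_iter), x0)
  if (!isTRUE(res$converged)) {
    cond <- errorCondition(
      paste0("conjugate gradient did not reach tol = ", tol, " in ",
             res$iterations, " iterations (relative residual ",
             signif(res$rel_residual, 3), ")"),
      class = c("vestibflow_no_convergence", "error"),
      resid_history = res$resid_history)
    stop(cond)
  }
  x <- res$x
  # Delivered current per terminal: net conductive outflow from the
  # collapsed terminal unknown (equals (A x)[terminal] since ground is 0 V).
  y <- fv_matvec(system$dims, system$uidx, system$gx, system$gy, system$gz, x)
  delivered <- vapply(system$terminals, function(t) y[t$id] * 1000, numeric(1))
  names(delivered) <- vapply(system$terminals, `[[`, "", "name")

  V <- array(NA_real_, system$dims)
  pos <- system$uidx > 0L
  V[pos] <- x[system$uidx[pos]]
  V[system$uidx == -1L] <- 0

  tp <- vapply(system$terminals, function(t) x[t$id], numeric(1))
  names(tp) <- names(delivered)
  structure(list(
    V = V,
    spacing_mm = system$spacing_mm,
    terminal_potentials = tp,
    I_total_mA = I_total_mA,
    report = list(iterations = res$iterations,
                  rel_residual = res$rel_residual,
                  tol = tol,
                  delivered_current_mA = delivered),
    x = x
  ), class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat("<potential_field> ", x$I_total_mA, " mA, ",
      x$report$iterations, " CG iterations, relative residual ",
      signif(x$report$rel_residual, 3), "\n", sep = "")
  cat("terminal potentials (V):",
      paste(signif(x$terminal_potentials, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Per-pad delivered currents
#'
#' Net conductive current leaving each electrode pad's metal layer (mA),
#' from the discrete face fluxes. For multi-anode montages this reports how
#' the equipotential terminal's total current splits between pads (the
#' split emerges from the solution; it is not imposed).
#'
#' @param efield An `efield_volume` from [compute_efield()].
#' @param vol The stamped `tissue_label_volume`.
#' @return Data frame with `pad`, `site_id`, `polarity`, `current_mA`
#'   (positive = net outflow from the pad).
#' @export
pad_currents <- function(efield, vol) {
  if (is.null(vol$pads)) stop("no electrodes stamped")
  rows <- lapply(seq_len(nrow(vol$pads)), function(i) {
    surf <- roi_surface(vol, vol$pads$metal_label[i])
    flux <- .face_currents(efield, surf)
    data.frame(pad = vol$pads$pad[i], site_id = vol$pads$site_id[i],
               polarity = vol$pads$polarity[i],
               current_mA = sum(flux) * 1000, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stamp, assemble and solve one montage
#'
#' Convenience wrapper running the full forward pipeline for one montage on
#' an (unstamped) phantom.
#'
#' @param vol A `tissue_label_volume` without electrodes.
#' @param montage A `"montage"` or preset name.
#' @inheritParams solve_potential
#' @param conductivities A [conductivity_table()].
#' @return List with `vol` (stamped), `potential` and `efield`.
#' @export
solve_montage <- function(vol, montage, I_total_mA = 1, tol = 1e-6,
                          max_iter = 20000L,
                          conductivities = vol$conductivities) {
  vol <- stamp_electrodes(vol, montage)
  sys <- assemble_system(vol, conductivities)
  pot <- solve_potential(sys, I_total_mA = I_total_mA, tol = tol,
                         max_iter = max_iter)
  ef <- compute_efield(pot, vol, conductivities)
  list(vol = vol, potential = pot, efield = ef)
}
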