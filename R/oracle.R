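# Closed-form validation standards for the finite-volume solver: the
# Legendre-series potential of a layered conductive sphere with surface
# point-current electrodes, and a manufactured-solution harness.

#' Layered-sphere specification
#'
#' @param radii_mm Outer radius of each concentric layer, strictly
#'   decreasing (mm).
#' @param sigmas Conductivity per layer (S/m), same length.
#' @param n_terms Series truncation order (harmonic degrees 1..n_terms).
#' @return A list of class `"sphere_spec"`.
#' @export
sphere_spec <- function(radii_mm, sigmas, n_terms = 200L) {
  stopifnot(length(radii_mm) == length(sigmas))
  if (any(radii_mm <= 0) || any(diff(radii_mm) >= 0))
    stop("radii_mm must be positive and strictly decreasing")
  if (any(sigmas <= 0)) stop("sigmas must be > 0")
  if (n_terms < 1) stop("n_terms must be >= 1")
  structure(list(radii_mm = as.numeric(radii_mm), sigmas = as.numeric(sigmas),
                 n_terms = as.integer(n_terms)), class = "sphere_spec")
}

# Radial coefficients (a_k, b_k per layer) for a unit point current source
# on the outer surface at angle 0, per harmonic degree n. Layer k basis:
#   V_k(r) = a_k (r / r_k)^n + b_k (r_k / r)^(n+1),
# with r_k the layer's outer radius; the per-layer scaling keeps the small
# interface systems well conditioned up to high degree. Coefficients are
# fixed by continuity of V and of sigma dV/dr at each interface and by the
# injected-current (Neumann) condition at the surface; b = 0 in the core.
.sphere_coefficients <- function(spec, I_A) {
  K <- length(spec$radii_mm)
  r <- spec$radii_mm / 1000  # meters
  sg <- spec$sigmas
  R1 <- r[1]
  nmax <- spec$n_terms
  # unknown order: a_1, b_1, a_2, b_2, ..., a_K (b_K omitted)
  nunk <- 2 * K - 1
  a_of <- function(k) 2 * k - 1
  b_of <- function(k) 2 * k
  coefs <- vector("list", nmax)
  for (n in seq_len(nmax)) {
    f_n <- I_A * (2 * n + 1) / (4 * pi * R1)
    if (K == 1) {
      # single layer: V = a_1 (r/R1)^n only
      coefs[[n]] <- list(a = f_n / (sg[1] * n), b = 0)
      next
    }
    M <- matrix(0, nunk, nunk)
    rhs <- numeric(nunk)
    # surface Neumann: sigma_1 (n a_1 - (n+1) b_1) / R1 = I (2n+1) / (4 pi R1^2)
    M[1, a_of(1)] <- sg[1] * n
    M[1, b_of(1)] <- -sg[1] * (n + 1)
    rhs[1] <- f_n
    row <- 1L
    for (i in seq_len(K - 1)) {
      rho <- r[i + 1]
      u_i <- (rho / r[i])^n
      w_i <- (r[i] / rho)^(n + 1)
      # continuity of V
      row <- row + 1L
      M[row, a_of(i)] <- u_i
      M[row, b_of(i)] <- w_i
      M[row, a_of(i + 1)] <- -1
      if (i + 1 < K) M[row, b_of(i + 1)] <- -1
      # continuity of sigma dV/dr (times rho)
      row <- row + 1L
      M[row, a_of(i)] <- sg[i] * n * u_i
      M[row, b_of(i)] <- -sg[i] * (n + 1) * w_i
      M[row, a_of(i + 1)] <- -sg[i + 1] * n
      if (i + 1 < K) M[row, b_of(i + 1)] <- sg[i + 1] * (n + 1)
    }
    sol <- solve(M, rhs)
    a <- sol[a_of(seq_len(K))]
    b <- c(sol[b_of(seq_len(K - 1))], 0)
    coefs[[n]] <- list(a = a, b = b)
  }
  coefs
}

# Potential (V) at interior points due to a unit point source at surface
# direction `edir`, from precomputed coefficients.
.sphere_eval <- function(spec, coefs, edir, points_mm, tol_series = 1e-8) {
  r_mm <- sqrt(rowSums(points_mm^2))
  if (any(r_mm > spec$radii_mm[1] + 1e-9))
    stop("field point outside the outer radius")
  r <- r_mm / 1000
  radii <- spec$radii_mm / 1000
  # layer index: layer k occupies (r_{k+1}, r_k]
  layer <- vapply(r_mm, function(rr) {
    k <- 1L
    while (k < length(radii) && rr <= spec$radii_mm[k + 1]) k <- k + 1L
    k
  }, integer(1))
  ct <- (points_mm %*% edir) / pmax(r_mm, .Machine$double.eps)
  ct <- pmin(1, pmax(-1, as.numeric(ct)))
  # Legendre recurrence
  Pnm1 <- rep(1, length(ct))   # P_0
  Pn <- ct                     # P_1
  V <- numeric(length(ct))
  last_term <- rep(Inf, length(ct))
  for (n in seq_len(spec$n_terms)) {
    cf <- coefs[[n]]
    rad <- numeric(length(ct))
    for (k in unique(layer)) {
      sel <- layer == k
      rk <- radii[k]
      rs <- r[sel]
      u <- (rs / rk)^n
      w <- if (cf$b[k] != 0) (rk / pmax(rs, 1e-300))^(n + 1) else 0
      rad[sel] <- cf$a[k] * u + cf$b[k] * w
    }
    term <- rad * Pn
    V <- V + term
    last_term <- abs(term)
    if (n >= 10 && max(last_term) < tol_series * max(abs(V), 1e-300)) {
      return(list(V = V, converged = TRUE, n_used = n,
                  tail = max(last_term) / max(abs(V))))
    }
    # advance recurrence: P_{n+1}
    Pnp1 <- ((2 * n + 1) * ct * Pn - n * Pnm1) / (n + 1)
    Pnm1 <- Pn
    Pn <- Pnp1
  }
  list(V = V, converged = FALSE, n_used = spec$n_terms,
       tail = max(last_term) / max(abs(V)))
}

#' Analytic potential of a layered sphere with surface point electrodes
#'
#' Legendre-series solution for a current `I` injected at `source_point` and
#' withdrawn at `sink_point`, both on the outer surface, evaluated at
#' interior field points. Per harmonic degree the radial coefficients in
#' each layer are fixed by continuity of the potential and the radial
#' current density at the interfaces and by the injected-current boundary
#' condition at the surface; source and sink are superposed.
#'
#' @param spec A [sphere_spec()].
#' @param source_point,sink_point Points on the outer surface (mm).
#' @param field_points Matrix (n x 3) of interior points (mm).
#' @param I_mA Injected current (mA).
#' @param tol_series Relative tail tolerance; an unconverged series at the
#'   requested points raises an error reporting the achieved tolerance.
#' @return Numeric vector of potentials (V).
#' @export
layered_sphere_potential <- function(spec, source_point, sink_point,
                                     field_points, I_mA = 1,
                                     tol_series = 1e-8) {
  stopifnot(inherits(spec, "sphere_spec"))
  if (is.null(dim(field_points))) field_points <- matrix(field_points, ncol = 3)
  R1 <- spec$radii_mm[1]
  for (p in list(source_point, sink_point)) {
    if (abs(sqrt(sum(p^2)) - R1) > 1e-6 * R1)
      stop("source/sink must lie on the outer surface")
  }
  I_A <- I_mA / 1000
  coefs <- .sphere_coefficients(spec, I_A)
  src <- .sphere_eval(spec, coefs, source_point / sqrt(sum(source_point^2)),
                      field_points, tol_series)
  snk <- .sphere_eval(spec, coefs, sink_point / sqrt(sum(sink_point^2)),
                      field_points, tol_series)
  if (!src$converged || !snk$converged)
    stop("series not converged at the requested points (achieved tail ",
         signif(max(src$tail, snk$tail), 3), ", requested ", tol_series, ")")
  src$V - snk$V
}

#' Closed-form potential of a homogeneous sphere (surface point electrode)
#'
#' Independent classical closed form used to cross-check the series
#' machinery in the single-layer case: for a unit point current source on
#' the surface of a homogeneous sphere of radius R and conductivity sigma,
#' \deqn{V = \frac{I}{4\pi\sigma R}\left[\frac{2}{d} - 2 +
#'   \log\frac{2}{1 - t\cos\gamma + d}\right]}
#' with t = r/R and d the normalized source-to-point distance.
#'
#' @param R_mm Sphere radius (mm); `sigma` conductivity (S/m).
#' @param sigma Conductivity (S/m).
#' @param source_point Point on the surface (mm).
#' @param field_points Interior points (mm), matrix n x 3.
#' @param I_mA Injected current (mA).
#' @return Potentials (V).
#' @export
homogeneous_sphere_potential <- function(R_mm, sigma, source_point,
                                         field_points, I_mA = 1) {
  if (is.null(dim(field_points))) field_points <- matrix(field_points, ncol = 3)
  R <- R_mm / 1000
  I_A <- I_mA / 1000
  r <- sqrt(rowSums(field_points^2)) / 1000
  t <- r / R
  ct <- (field_points %*% (source_point / sqrt(sum(source_point^2)))) /
    pmax(r * 1000, .Machine$double.eps)
  ct <- pmin(1, pmax(-1, as.numeric(ct)))
  d <- sqrt(1 - 2 * t * ct + t^2)
  I_A / (4 * pi * sigma * R) * (2 / d - 2 + log(2 / (1 - t * ct + d)))
}

#' Manufactured-solution error of the finite-volume discretization
#'
#' Solves the Laplace problem on a cube with uniform conductivity and
#' Dirichlet data from the harmonic test function \eqn{V = x^2 - z^2}
#' imposed on the boundary faces (face-centred values through half-cell
#' conductances), then returns the relative L2 error of the interior
#' solution against the closed form. Used with a sequence of resolutions to
#' estimate the observed convergence order.
#'
#' @param resolution_mm Voxel edge length (mm).
#' @param half_width_mm Half edge length of the cube domain (mm).
#' @param fun Test function of (x, y, z) in mm; must be harmonic.
#' @param tol,max_iter Passed to the conjugate-gradient solve.
#' @return Relative L2 error (unitless).
#' @export
manufactured_solution_error <- function(resolution_mm, half_width_mm = 20,
                                        fun = function(x, y, z) x^2 - z^2,
                                        tol = 1e-10, max_iter = 50000L) {
  h <- resolution_mm
  n <- as.integer(round(2 * half_width_mm / h))
  h_m <- h / 1000
  sigma <- 1
  g_int <- h_m * sigma           # interior face conductance
  g_bnd <- 2 * h_m * sigma       # half-cell conductance to a boundary face
  cc <- (seq_len(n) - (n + 1) / 2) * h  # cell-centre coordinates (mm)
  L <- half_width_mm
  # Enlarged grid with a shell of fixed "ghost" voxels standing in for the
  # boundary faces: ghost value = test function at the face centre, ghost
  # conductance = half-cell value. Corner/edge ghosts carry g = 0.
  dims2 <- rep(n + 2L, 3)
  uidx2 <- array(-1L, dims2)
  inner <- 2:(n + 1)
  uidx2[inner, inner, inner] <- seq_len(n^3)
  gx2 <- array(0, dims2); gy2 <- array(0, dims2); gz2 <- array(0, dims2)
  gx2[2:n, inner, inner] <- g_int
  gy2[inner, 2:n, inner] <- g_int
  gz2[inner, inner, 2:n] <- g_int
  gx2[1, inner, inner] <- g_bnd; gx2[n + 1, inner, inner] <- g_bnd
  gy2[inner, 1, inner] <- g_bnd; gy2[inner, n + 1, inner] <- g_bnd
  gz2[inner, inner, 1] <- g_bnd; gz2[inner, inner, n + 1] <- g_bnd
  vfix <- array(0, dims2)
  xx <- matrix(rep(cc, times = n), n, n)   # first index varies
  yy <- matrix(rep(cc, each = n), n, n)    # second index varies
  vfix[1, inner, inner] <- fun(-L, xx, yy)      # (y, z) plane
  vfix[n + 2, inner, inner] <- fun(L, xx, yy)
  vfix[inner, 1, inner] <- fun(xx, -L, yy)      # (x, z) plane
  vfix[inner, n + 2, inner] <- fun(xx, L, yy)
  vfix[inner, inner, 1] <- fun(xx, yy, -L)      # (x, y) plane
  vfix[inner, inner, n + 2] <- fun(xx, yy, L)
  nunk <- n^3
  bb <- fv_rhs_fixed(as.integer(dims2), uidx2, gx2, gy2, gz2, vfix, nunk)
  res <- fv_pcg(as.integer(dims2), uidx2, gx2, gy2, gz2, bb, tol,
                as.integer(max_iter), NULL)
  if (!isTRUE(res$converged)) stop("manufactured-solution solve did not converge")
  co <- coord_arrays(rep(n, 3), h)
  exact <- fun(co$X, co$Y, co$Z)
  num <- array(res$x, rep(n, 3))
  sqrt(sum((num - exact)^2) / sum(exact^2))
}

#' Observed convergence order of the manufactured solution
#'
#' @param resolutions_mm Decreasing voxel sizes (default 4, 2, 1 mm).
#' @param ... Passed to [manufactured_solution_error()].
#' @return List with per-resolution `errors` and the least-squares
#'   `order` of convergence.
#' @export
manufactured_convergence <- function(resolutions_mm = c(4, 2, 1), ...) {
  errs <- vapply(resolutions_mm, manufactured_solution_error, numeric(1), ...)
  fit <- stats::lm(log(errs) ~ log(resolutions_mm))
  list(resolutions_mm = resolutions_mm, errors = errs,
       order = unname(coef(fit)[2]))
}

#' Finite-volume solver vs layered-sphere benchmark
#'
#' Builds a voxelized concentric-sphere phantom, stamps small antipodal
#' electrode pads at the poles, solves numerically, and compares the
#' potential on an interior sampling shell against the analytic series
#' solution with point electrodes at the pad centres. Both potentials are
#' mean-centred over the sampling shell before comparison (the potential is
#' defined up to a gauge constant; the numerical gauge is the grounded
#' cathode). Pads are kept small (default 10 mm) and the shell far from the
#' electrodes so the disc/point discrepancy stays below the grid error.
#'
#' @param voxel_mm Grid resolution (mm).
#' @param radii_mm,sigmas Layer structure (default three-layer
#'   scalp/skull/brain, 92/86/80 mm, 0.465/0.01/0.276 S/m).
#' @param shell_radius_mm Radius of the interior sampling shell.
#' @param n_points Number of shell sampling points (Fibonacci lattice).
#' @param pad_diameter_mm Electrode pad diameter.
#' @param tol,max_iter,x0 Passed to [solve_potential()].
#' @return List with `rel_l2_error`, the sampled numeric and analytic
#'   potentials, and the solver report.
#' @export
sphere_benchmark <- function(voxel_mm = 2,
                             radii_mm = c(92, 86, 80),
                             sigmas = c(0.465, 0.01, 0.276),
                             shell_radius_mm = 40,
                             n_points = 400,
                             pad_diameter_mm = 10,
                             tol = 1e-6, max_iter = 40000L, x0 = NULL) {
  tissues <- paste0("layer", seq_along(radii_mm))
  ct <- structure(c(stats::setNames(sigmas, tissues),
                    gel = sigmas[1], electrode = 5.8e7),
                  set_id = "benchmark", class = "conductivity_table")
  cfg <- phantom_config(layer_radii_mm = radii_mm, layer_tissues = tissues,
                        voxel_mm = voxel_mm, roi_spec = NULL)
  vol <- build_phantom(cfg, ct)
  mont <- montage(list(
    electrode_pad(polarity = "anode", direction = c(0, 0, 1),
                  diameter_mm = pad_diameter_mm),
    electrode_pad(polarity = "cathode", direction = c(0, 0, -1),
                  diameter_mm = pad_diameter_mm)
  ), name = "polar_pair")
  vol <- stamp_electrodes(vol, mont)
  sys <- assemble_system(vol, ct)
  pot <- solve_potential(sys, I_total_mA = 1, tol = tol, max_iter = max_iter,
                         x0 = x0)
  pts <- shell_radius_mm * fibonacci_sphere(n_points)
  v_num <- trilinear(pot$V, pts, voxel_mm)
  spec <- sphere_spec(radii_mm, sigmas)
  v_ana <- layered_sphere_potential(spec, c(0, 0, radii_mm[1]),
                                    c(0, 0, -radii_mm[1]), pts, I_mA = 1)
  v_num_c <- v_num - mean(v_num)
  v_ana_c <- v_ana - mean(v_ana)
  list(
    rel_l2_error = sqrt(sum((v_num_c - v_ana_c)^2) / sum(v_ana_c^2)),
    v_numeric = v_num_c, v_analytic = v_ana_c,
    points = pts, report = pot$report, potential = pot, vol = vol
  )
}

#' Run the solver validation suite
#'
#' Layered-sphere benchmark at the requested resolutions plus the
#' manufactured-solution convergence study.
#'
#' @param sphere_resolutions_mm Voxel sizes for the sphere benchmark.
#' @param manufactured_resolutions_mm Voxel sizes for the manufactured study.
#' @param thresholds Named list of pass thresholds.
#' @return List with per-resolution sphere errors, manufactured errors and
#'   order, and pass flags.
#' @export
validate_solver <- function(sphere_resolutions_mm = c(2, 1),
                            manufactured_resolutions_mm = c(4, 2, 1),
                            thresholds = list(sphere_2mm = 0.05,
                                              sphere_1mm = 0.02,
                                              min_order = 1.5)) {
  sph <- numeric(0)
  x0 <- NULL
  for (h in sort(sphere_resolutions_mm, decreasing = TRUE)) {
    bench <- sphere_benchmark(voxel_mm = h)
    sph[as.character(h)] <- bench$rel_l2_error
  }
  man <- manufactured_convergence(manufactured_resolutions_mm)
  pass <- list(
    sphere_2mm = is.na(sph["2"]) || sph[["2"]] < thresholds$sphere_2mm,
    sphere_1mm = is.na(sph["1"]) || sph[["1"]] < thresholds$sphere_1mm,
    order = man$order >= thresholds$min_order
  )
  list(sphere_errors = sph, manufactured = man, pass = pass,
       ok = all(unlist(pass)))
}
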