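test_that("uniform rod reproduces Ohm's law (20 V/m interior field)", {
  rod <- make_rod(n_tissue = 10, spacing_mm = 10, sigma = 0.5)
  sys <- assemble_system(rod$vol, terminals = rod$terminals)
  pot <- solve_potential(sys, I_total_mA = 1, tol = 1e-10)
  ef <- compute_efield(pot, rod$vol)
  # E = (I/A)/sigma = (1e-3 / 1e-4) / 0.5 = 20 V/m in the rod interior
  # (voxels adjacent to the metal terminals see the half-cell contact drop)
  interior <- ef$Emag[1, 1, 4:9]
  expect_equal(unname(interior), rep(20, 6), tolerance = 1e-6)
  # delivered current matches the configured current to 0.1%
  expect_lt(abs(pot$report$delivered_current_mA[["anode"]] - 1) / 1, 1e-3)
  # mid-plane conservation: net flux through a separating cross-section
  mask <- array(FALSE, dim(rod$vol$labels)); mask[, , 1:6] <- TRUE
  cc <- check_current_conservation(ef, mask_surface(rod$vol, mask), 1)
  expect_lt(cc$rel_error, 1e-3)
})

test_that("assembled operator equals a brute-force dense stencil assembly", {
  # 3x3x3 uniform cube with single-voxel terminals at opposite corners
  labels <- array(1L, c(3L, 3L, 3L))
  labels[1, 1, 1] <- 201L
  labels[3, 3, 3] <- 202L
  ct <- structure(c(tissue = 2, electrode = 5.8e7),
                  set_id = "test", class = "conductivity_table")
  legend <- data.frame(label = c(1L, 201L, 202L),
                       name = c("tissue", "a", "c"),
                       tissue = c("tissue", "electrode", "electrode"),
                       stringsAsFactors = FALSE)
  vol <- make_test_volume(labels, 5, legend, ct)
  sys <- assemble_system(vol, terminals = list(
    list(labels = 201L, type = "current", share = 1, name = "anode"),
    list(labels = 202L, type = "ground", name = "cathode")))
  A <- vestibflow:::as_dense_operator(sys)
  # independent dense construction from the stencil formula
  h_m <- 5 / 1000
  sig <- c(tissue = 2, electrode = 5.8e7)
  sg <- array(sig[legend$tissue[match(labels, legend$label)]], dim(labels))
  n <- sys$n_unknowns
  B <- matrix(0, n, n)
  idx <- sys$uidx
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    for (d in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      i2 <- i + d[1]; j2 <- j + d[2]; k2 <- k + d[3]
      if (i2 > 3 || j2 > 3 || k2 > 3) next
      g <- h_m * 2 * sg[i, j, k] * sg[i2, j2, k2] / (sg[i, j, k] + sg[i2, j2, k2])
      u <- idx[i, j, k]; v <- idx[i2, j2, k2]
      if (u > 0 && v > 0 && u != v) {
        B[u, u] <- B[u, u] + g; B[v, v] <- B[v, v] + g
        B[u, v] <- B[u, v] - g; B[v, u] <- B[v, u] - g
      } else if (u > 0 && v == -1) B[u, u] <- B[u, u] + g
      else if (v > 0 && u == -1) B[v, v] <- B[v, v] + g
    }
  }
  expect_equal(A, B, tolerance = 1e-12)
  expect_equal(A, t(A))
  # interior (non-terminal, non-ground-adjacent) rows conserve current
  ground_adjacent <- which(abs(rowSums(B)) > 1e-9)
  interior <- setdiff(seq_len(n - 1), ground_adjacent)
  expect_true(all(abs(rowSums(A)[interior]) < 1e-9))
})

test_that("solution is linear in the injected current", {
  rod <- make_rod()
  sys <- assemble_system(rod$vol, terminals = rod$terminals)
  base <- solve_potential(sys, I_total_mA = 1, tol = 1e-8)
  for (alpha in c(0.5, 2, 10)) {
    scaled <- solve_potential(sys, I_total_mA = alpha, tol = 1e-8)
    dev <- abs(scaled$V - alpha * base$V) / max(abs(alpha * base$V))
    expect_lt(max(dev, na.rm = TRUE), 10 * 1e-8)
  }
})

test_that("anode/cathode swap negates the mean-centred potential", {
  vol <- make_mini_sphere(voxel_mm = 3)
  m <- montage(list(
    electrode_pad(polarity = "anode", direction = c(0, 0, 1), diameter_mm = 12),
    electrode_pad(polarity = "cathode", direction = c(1, 0, 0), diameter_mm = 12)))
  m_swapped <- montage(list(
    electrode_pad(polarity = "cathode", direction = c(0, 0, 1), diameter_mm = 12),
    electrode_pad(polarity = "anode", direction = c(1, 0, 0), diameter_mm = 12)))
  s1 <- solve_montage(vol, m, tol = 1e-8)
  s2 <- solve_montage(vol, m_swapped, tol = 1e-8)
  v1 <- s1$potential$V; v2 <- s2$potential$V
  v1 <- v1 - mean(v1, na.rm = TRUE)
  v2 <- v2 - mean(v2, na.rm = TRUE)
  dev <- max(abs(v1 + v2), na.rm = TRUE) / max(abs(v1), na.rm = TRUE)
  expect_lt(dev, 1e-5)
})

test_that("a montage with two anodes equals superposed single-anode solves", {
  vol <- make_mini_sphere(voxel_mm = 3)
  pads <- list(
    electrode_pad(polarity = "anode", direction = c(0, 0, 1), diameter_mm = 12),
    electrode_pad(polarity = "anode", direction = c(1, 0, 0), diameter_mm = 12),
    electrode_pad(polarity = "cathode", direction = c(0, -1, 0), diameter_mm = 12))
  stv <- stamp_electrodes(vol, montage(pads))
  sys <- assemble_system(stv)
  pot <- solve_potential(sys, tol = 1e-9)
  ef <- compute_efield(pot, stv)
  pc <- pad_currents(ef, stv)
  I1 <- pc$current_mA[1]; I2 <- pc$current_mA[2]
  expect_equal(I1 + I2, 1, tolerance = 1e-3)
  # single-anode solves on the same geometry, the other anode floating
  met <- stv$pads$metal_label
  ca <- stv$pads$metal_label[stv$pads$polarity == "cathode"]
  solo <- function(active, floating, share) {
    s <- assemble_system(stv, terminals = list(
      list(labels = met[active], type = "current", share = 1, name = "anode"),
      list(labels = met[floating], type = "current", share = 0, name = "float"),
      list(labels = ca, type = "ground", name = "cathode")))
    solve_potential(s, I_total_mA = share, tol = 1e-9)$V
  }
  v_sum <- solo(1, 2, I1) + solo(2, 1, I2)
  dev <- max(abs(v_sum - pot$V), na.rm = TRUE) / max(abs(pot$V), na.rm = TRUE)
  expect_lt(dev, 1e-5)
})

test_that("extrema of the potential sit on the electrode terminals", {
  vol <- make_mini_sphere(voxel_mm = 3)
  s <- solve_montage(vol, montage(list(
    electrode_pad(polarity = "anode", direction = c(0, 0, 1), diameter_mm = 12),
    electrode_pad(polarity = "cathode", direction = c(0, 0, -1), diameter_mm = 12))))
  V <- s$potential$V
  vt <- s$potential$terminal_potentials[["anode"]]
  expect_lt(max(V, na.rm = TRUE), vt + 1e-9)
  expect_gt(min(V, na.rm = TRUE), 0 - 1e-9)
})

test_that("degenerate systems are rejected with informative errors", {
  # two disconnected rods: anode in one, cathode in the other
  labels <- array(0L, c(1L, 1L, 9L))
  labels[1, 1, 1] <- 201L; labels[1, 1, 2:3] <- 1L
  labels[1, 1, 7:8] <- 1L; labels[1, 1, 9] <- 202L
  ct <- structure(c(tissue = 1, electrode = 5.8e7),
                  set_id = "test", class = "conductivity_table")
  legend <- data.frame(label = c(1L, 201L, 202L),
                       name = c("t", "a", "c"),
                       tissue = c("tissue", "electrode", "electrode"),
                       stringsAsFactors = FALSE)
  vol <- make_test_volume(labels, 10, legend, ct)
  terms <- list(list(labels = 201L, type = "current", share = 1, name = "anode"),
                list(labels = 202L, type = "ground", name = "cathode"))
  expect_error(assemble_system(vol, terminals = terms), "singular")
  # non-convergence carries the residual history
  rod <- make_rod(n_tissue = 30)
  sys <- assemble_system(rod$vol, terminals = rod$terminals)
  err <- tryCatch(solve_potential(sys, tol = 1e-14, max_iter = 2L),
                  error = function(e) e)
  expect_s3_class(err, "vestibflow_no_convergence")
  expect_true(length(err$resid_history) >= 2)
  # solutions are independent of the initial guess
  p1 <- solve_potential(sys, tol = 1e-10)
  x0 <- rep(0.123, sys$n_unknowns)
  p2 <- solve_potential(sys, tol = 1e-10, x0 = x0)
  expect_lt(max(abs(p1$V - p2$V), na.rm = TRUE) / max(abs(p1$V), na.rm = TRUE),
            1e-6)
})
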