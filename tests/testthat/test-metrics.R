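test_that("electric field derivation is exact for linear and constant potentials", {
  dims <- c(7L, 7L, 7L)
  ct <- structure(c(tissue = 1), set_id = "test", class = "conductivity_table")
  legend <- data.frame(label = 1L, name = "tissue", tissue = "tissue",
                       stringsAsFactors = FALSE)
  vol <- make_test_volume(array(1L, dims), 2, legend, ct)
  co <- vestibflow:::coord_arrays(dims, 2)
  # constant potential: zero field
  ef0 <- compute_efield(array(1.5, dims), vol)
  expect_true(all(ef0$Emag == 0))
  # V = x^2 - z^2 (mm^2 -> scale to volts): central differences are exact
  # for quadratics at interior voxels, one-sided at the boundary is O(h)
  V <- (co$X^2 - co$Z^2) * 1e-6
  ef <- compute_efield(V, vol)
  interior <- 2:6
  h_m <- 2e-3
  Ex_exact <- -2 * co$X * 1e-3   # d/dx (x_m^2) = 2 x_m, x_m = x_mm * 1e-3
  expect_equal(ef$Ex[interior, interior, interior],
               Ex_exact[interior, interior, interior], tolerance = 1e-12)
  expect_equal(ef$Ey[interior, interior, interior],
               array(0, c(5, 5, 5)), tolerance = 1e-12)
  # spacing mismatch is caught
  vol_bad <- vol; vol_bad$spacing_mm <- 3
  pf <- structure(list(V = V, spacing_mm = 2), class = "potential_field")
  expect_error(compute_efield(pf, vol_bad), "spacing")
})

test_that("ROI statistics use population SD and interpolated percentiles", {
  dims <- c(10L, 10L, 10L)
  fake <- function(vals) {
    em <- array(NA_real_, dims)
    em[seq_along(vals)] <- vals
    structure(list(Emag = em), class = "efield_volume")
  }
  mask_of <- function(n) {
    m <- array(FALSE, dims); m[seq_len(n)] <- TRUE; m
  }
  # constant ROI: mean = p99 = value, sd = 0
  st <- roi_statistics(fake(rep(0.05, 100)), mask_of(100))
  expect_equal(st$mean_V_per_m, 0.05)
  expect_equal(st$sd_V_per_m, 0)
  expect_equal(st$p99_V_per_m, 0.05)
  # 1..100: interpolated 99th percentile is 99.01 (direct sort oracle)
  st2 <- roi_statistics(fake(1:100), mask_of(100))
  expect_equal(st2$p99_V_per_m, 99.01)
  v <- c(2, 4, 4, 4, 5, 5, 7, 9)
  st3 <- roi_statistics(fake(v), mask_of(8))
  expect_equal(st3$sd_V_per_m, 2)           # population SD, not sample SD
  expect_equal(st3$mean_V_per_m, 5)
  # two-voxel ROI mean
  st4 <- roi_statistics(fake(c(0.02, 0.04)), mask_of(2))
  expect_equal(st4$mean_V_per_m, 0.03)
  expect_error(roi_statistics(fake(1), array(FALSE, dims)), "empty ROI")
})

test_that("ROI inflow current integrates the surface flux", {
  dims <- c(10L, 10L, 10L)
  ct <- structure(c(tissue = 1), set_id = "test", class = "conductivity_table")
  legend <- data.frame(label = 1L, name = "tissue", tissue = "tissue",
                       stringsAsFactors = FALSE)
  vol <- make_test_volume(array(1L, dims), 2, legend, ct)
  ef <- make_uniform_J_field(dims, 2, J = 1, sigma = 1)
  # cubic ROI of 5 voxels a side = 1 cm side; uniform 1 A/m^2 along x:
  # only the two x faces carry flux, each 1e-4 m^2 -> 100 uA through
  mask <- array(FALSE, dims); mask[3:7, 3:7, 3:7] <- TRUE
  surf <- mask_surface(vol, mask)
  expect_equal(roi_inflow_current(ef, surf), 100, tolerance = 1e-9)
  # zero field: zero current
  ef0 <- make_uniform_J_field(dims, 2, J = 0)
  expect_equal(roi_inflow_current(ef0, surf), 0)
  # net flux through a closed surface in a divergence-free field vanishes
  cc <- check_current_conservation(ef, surf, 1)
  expect_lt(abs(cc$net_current_mA), 1e-12)
  # an open surface is rejected
  open_surf <- surf[surf$axis == 1 & surf$dir == 1, ]
  for (a in c("dims", "spacing_mm", "face_area_mm2"))
    attr(open_surf, a) <- attr(surf, a)
  class(open_surf) <- class(surf)
  expect_error(roi_inflow_current(ef, open_surf), "not closed")
})

test_that("interface extraction finds exactly the shared faces", {
  dims <- c(3L, 3L, 3L)
  labels <- array(2L, dims); labels[2, 2, 2] <- 1L
  ct <- structure(c(a = 1, b = 1), set_id = "test", class = "conductivity_table")
  legend <- data.frame(label = c(1L, 2L), name = c("a", "b"),
                       tissue = c("a", "b"), stringsAsFactors = FALSE)
  vol <- make_test_volume(labels, 1, legend, ct)
  surf <- extract_interface_surface(vol, 1L, 2L)
  expect_identical(nrow(surf), 6L)            # the six faces of the centre voxel
  expect_true(all(surf$a == which(labels == 1L)))
  # disjoint labels that are never adjacent give an empty set
  labels2 <- array(0L, dims); labels2[1, 1, 1] <- 1L; labels2[3, 3, 3] <- 2L
  vol2 <- make_test_volume(labels2, 1, legend, ct)
  expect_identical(nrow(extract_interface_surface(vol2, 1L, 2L)), 0L)
  expect_error(extract_interface_surface(vol, 1L, 1L), "disjoint")
})

test_that("symmetricity and intensity rescaling follow their definitions", {
  mk <- function(mean, p99) list(mean_V_per_m = mean, p99_V_per_m = p99)
  s <- symmetricity(mk(0.028, 0.147), mk(0.030, 0.172))
  expect_equal(round(s$mean_ratio, 3), 0.933)
  s2 <- symmetricity(mk(0.020, 0.091), mk(0.019, 0.115))
  expect_equal(round(s2$mean_ratio, 2), 1.05)
  ident <- symmetricity(mk(0.5, 1), mk(0.5, 1))
  expect_equal(ident$mean_ratio, 1)
  expect_equal(ident$max_ratio, 1)
  expect_error(symmetricity(mk(1, 1), mk(0, 1)), "degenerate")
  expect_equal(scale_to_match(0.028, 0.013), 2.1538, tolerance = 1e-4)
  expect_equal(scale_to_match(0.026, 0.013), 2)
  expect_equal(scale_to_match(0.4, 0.4), 1)
  expect_error(scale_to_match(1, 0), "rescale")
})

test_that("bootstrap confidence interval is deterministic and calibrated", {
  # constant sample: zero-width interval
  ci0 <- bootstrap_ci(rep(2.5, 20))
  expect_equal(as.numeric(ci0), c(2.5, 2.5))
  # same seed, same interval; different seed, different interval
  x <- vestibflow:::with_local_seed(3, rexp(200))
  expect_identical(bootstrap_ci(x, seed = 7), bootstrap_ci(x, seed = 7))
  expect_false(identical(bootstrap_ci(x, seed = 7), bootstrap_ci(x, seed = 8)))
  # the caller's RNG stream is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(bootstrap_ci(x)); after <- runif(1)
  expect_identical(before, after)
  # width matches the closed-form normal CI within 10%
  z <- vestibflow:::with_local_seed(1, rnorm(1000))
  ci <- bootstrap_ci(z, n_boot = 4000)
  expect_true(ci[["lower"]] < 0 && ci[["upper"]] > 0)
  width <- ci[["upper"]] - ci[["lower"]]
  expect_lt(abs(width - 2 * 1.96 / sqrt(1000)) / (2 * 1.96 / sqrt(1000)), 0.1)
  expect_error(bootstrap_ci(1), "at least 2")
  expect_error(bootstrap_ci(1:5, level = 1.2), "level")
})

test_that("star-plot normalization scales every category to a unit maximum", {
  col <- c(0.028, 0.024, 0.039, 0.020, 0.013, 0.021, 0.041)
  tab <- data.frame(montage = paste0("m", 1:7), left_mean = col)
  norm <- starplot_normalize(tab)
  expect_equal(max(norm$left_mean), 1)
  expect_equal(norm$left_mean[1], 0.028 / 0.041, tolerance = 1e-12)
  expect_equal(starplot_normalize(data.frame(x = c(2, 2, 2)))$x, rep(1, 3))
  m <- cbind(a = c(1, 2), b = c(4, 2))
  expect_equal(unname(starplot_normalize(m)[, "a"]), c(0.5, 1))
  expect_error(starplot_normalize(data.frame(x = c(-1, 0))), "positive")
})
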