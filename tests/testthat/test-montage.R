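expected_polarity <- list(
  montage1 = list(anodes = 1L, cathodes = 3L),
  montage2 = list(anodes = c(1L, 3L), cathodes = 2L),
  montage3 = list(anodes = 1L, cathodes = 2L),
  montage4 = list(anodes = c(1L, 3L), cathodes = c(5L, 6L)),
  montage5 = list(anodes = c(1L, 6L), cathodes = c(3L, 5L)),
  montage6 = list(anodes = 1L, cathodes = 4L),
  montage7 = list(anodes = 1L, cathodes = 7L)
)

test_that("the seven montage presets carry the canonical polarities", {
  aliases <- c("bilateral_bipolar", "bilateral_monopolar",
               "unilateral_monopolar", "sdas", "odas", "mastoid_nape",
               "mastoid_forehead")
  for (i in seq_along(expected_polarity)) {
    name <- names(expected_polarity)[i]
    m <- get_montage(name)
    pol <- vapply(m$pads, `[[`, "", "polarity")
    sites <- vapply(m$pads, function(p) p$site_id, integer(1))
    expect_setequal(sites[pol == "anode"], expected_polarity[[name]]$anodes)
    expect_setequal(sites[pol == "cathode"], expected_polarity[[name]]$cathodes)
    # aliases resolve to the same preset
    m2 <- get_montage(aliases[i])
    expect_identical(m2$name, name)
  }
  # SDAS and ODAS share the placement but not the polarity assignment
  s4 <- vapply(get_montage("sdas")$pads, function(p) p$site_id, integer(1))
  s5 <- vapply(get_montage("odas")$pads, function(p) p$site_id, integer(1))
  expect_setequal(s4, s5)
  a4 <- vapply(get_montage("sdas")$pads, `[[`, "", "polarity")
  expect_false(identical(sort(paste(s4, a4)),
                         sort(paste(s5, vapply(get_montage("odas")$pads,
                                               `[[`, "", "polarity")))))
  expect_error(get_montage("montage99"), "valid names")
})

test_that("electrode sites are unit vectors with exact mirror pairs", {
  s <- electrode_sites()
  d <- as.matrix(s[, c("dx", "dy", "dz")])
  expect_true(all(abs(sqrt(rowSums(d^2)) - 1) < 1e-9))
  mirror <- function(v) c(-v[1], v[2], v[3])
  for (pair in list(c(1, 3), c(5, 6), c(7, 2))) {
    da <- d[s$site_id == pair[1], ]
    db <- d[s$site_id == pair[2], ]
    expect_equal(unname(mirror(da)), unname(db), tolerance = 1e-12)
  }
})

test_that("chord separations follow sphere geometry and the mastoid calibration", {
  # antipodal pads on a 92 mm sphere are one diameter apart
  m <- montage(list(electrode_pad(polarity = "anode", direction = c(0, 0, 1)),
                    electrode_pad(polarity = "cathode", direction = c(0, 0, -1))))
  expect_equal(electrode_separation(m)$separation_mm, 184, tolerance = 1e-9)
  # coincident pads are 0 mm apart
  m0 <- montage(list(electrode_pad(polarity = "anode", direction = c(1, 0, 0)),
                     electrode_pad(polarity = "cathode", direction = c(1, 0, 0))))
  expect_equal(electrode_separation(m0)$separation_mm, 0)
  # the mastoid-mastoid chord reproduces the classic bilateral-bipolar
  # separation of 149.619 mm within 1 mm
  sep <- electrode_separation("bilateral_bipolar")
  expect_lt(abs(sep$separation_mm - 149.619), 1)
  # order of pads does not change the pair distance
  mrev <- montage(rev(get_montage("bilateral_bipolar")$pads))
  expect_equal(electrode_separation(mrev)$separation_mm, sep$separation_mm)
})

test_that("stamping creates per-pad gel and metal layers of the right size", {
  vol <- build_phantom(phantom_config(voxel_mm = 2))
  st <- stamp_electrodes(vol, "montage1")
  expect_identical(nrow(st$pads), 2L)
  # per-pad labels exist and are disjoint
  expect_setequal(unique(st$labels[st$labels >= 100L & st$labels < 200L]),
                  st$pads$gel_label)
  expect_setequal(unique(st$labels[st$labels >= 200L]), st$pads$metal_label)
  # metal voxel count matches the analytic spherical-cap shell volume
  alpha <- asin(15 / 92)
  omega <- 2 * pi * (1 - cos(alpha))
  v_ana <- omega / 3 * (97^3 - 94.5^3)   # mm^3
  for (lab in st$pads$metal_label) {
    v_vox <- sum(st$labels == lab) * 8
    expect_lt(abs(v_vox / v_ana - 1), 0.25)
  }
  # stamping the same montage again overlaps
  expect_error(stamp_electrodes(st, "montage1"), "overlap")
})

test_that("scalp boundary area approximates the analytic sphere area", {
  vol <- build_phantom(phantom_config(voxel_mm = 2, roi_spec = NULL))
  surf <- extract_interface_surface(vol, 1L, 0L)
  # the staircase (Manhattan) boundary of a voxelized sphere carries ~1.5x
  # the analytic area
  area <- nrow(surf) * attr(surf, "face_area_mm2")
  expect_gt(area / (4 * pi * 92^2), 1.2)
  expect_lt(area / (4 * pi * 92^2), 1.6)
})
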