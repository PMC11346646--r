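test_that("default phantom labels the layered geometry correctly", {
  vol <- build_phantom(phantom_config(voxel_mm = 2))
  dims <- dim(vol$labels)
  ctr <- (dims + 1) / 2
  # origin voxel sits in the innermost (white matter) layer
  expect_equal(vol$labels[ctr[1], ctr[2], ctr[3]], 5L)
  # brute-force scalp-shell count: independent distance scan over all grid
  # points with 86 < r <= 92
  co <- vestibflow:::coord_arrays(dims, vol$spacing_mm)
  r <- sqrt(co$X^2 + co$Y^2 + co$Z^2)
  expect_identical(sum(vol$labels == 1L), sum(r > 86 & r <= 92))
  # layer shell volumes approach analytic (4/3) pi (r1^3 - r2^3)
  shell <- function(lab) sum(vol$labels == lab) * vol$spacing_mm^3
  ana <- function(r1, r2) 4 / 3 * pi * (r1^3 - r2^3)
  expect_lt(abs(shell(2L) / ana(86, 80) - 1), 0.05)   # skull at 2 mm
  expect_lt(abs(shell(4L) / (ana(78, 55) -
    sum(vol$labels %in% 10:13) * vol$spacing_mm^3) - 1), 0.05)
})

test_that("layer volumes converge to analytic shells at 1 mm", {
  vol <- build_phantom(phantom_config(voxel_mm = 1))
  ana <- function(r1, r2) 4 / 3 * pi * (r1^3 - r2^3)
  for (spec in list(list(1L, 92, 86), list(2L, 86, 80), list(3L, 80, 78))) {
    v <- sum(vol$labels == spec[[1]]) * vol$spacing_mm^3
    expect_lt(abs(v / ana(spec[[2]], spec[[3]]) - 1), 0.02)
  }
})

test_that("symmetric phantom is voxel-wise mirror symmetric with equal ROI counts", {
  vol <- build_phantom(phantom_config(voxel_mm = 2))
  expect_identical(mirror_labels(vol$labels), vol$labels)
  expect_identical(sum(vol$labels == 10L), sum(vol$labels == 12L))
  expect_identical(sum(vol$labels == 11L), sum(vol$labels == 13L))
  # ROIs are resolved and carved from brain tissue only: no skull/scalp
  # voxels were overwritten (their counts match a ROI-free build)
  expect_gte(sum(vol$labels == 10L), 8)
  expect_gte(sum(vol$labels == 11L), 8)
  cfg_no_roi <- phantom_config(voxel_mm = 2, roi_spec = NULL)
  plain <- build_phantom(cfg_no_roi)
  expect_identical(sum(vol$labels == 1L), sum(plain$labels == 1L))
  expect_identical(sum(vol$labels == 2L), sum(plain$labels == 2L))
  roi <- vol$labels %in% 10:13
  expect_true(all(plain$labels[roi] %in% c(4L, 5L)))
})

test_that("phantom configuration is validated", {
  expect_error(phantom_config(layer_radii_mm = c(55, 78, 80, 86, 92)),
               "decreasing")
  expect_error(phantom_config(layer_radii_mm = c(92, 86),
                              layer_tissues = "skin"), "length")
  expect_error(phantom_config(voxel_mm = 0), "voxel_mm")
  expect_error(phantom_config(asymmetry_factor = -1), "asymmetry_factor")
  # coarse voxels under-resolve the ROIs
  expect_error(build_phantom(phantom_config(voxel_mm = 4)), "under-resolved")
  # ROI outside the brain compartment
  bad_roi <- default_roi_spec()
  bad_roi$vestibule_center <- c(-89, 0, 0)
  expect_error(build_phantom(phantom_config(roi_spec = bad_roi)),
               "outside the brain")
})

test_that("asymmetry rescales the right ROI only", {
  vol <- build_phantom(phantom_config(voxel_mm = 2))
  # factor 1 is the identity
  expect_identical(apply_asymmetry(vol, 1)$labels, vol$labels)
  # factor 1.26 doubles the right vestibule volume (1.26^3 ~ 2) up to
  # voxel quantization; the left side is untouched
  av <- apply_asymmetry(vol, 1.26)
  expect_identical(sum(av$labels == 10L), sum(vol$labels == 10L))
  ratio <- sum(av$labels == 12L) / sum(vol$labels == 12L)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.6)
  # shrinking under the resolution limit errors
  expect_error(apply_asymmetry(vol, 0.5), "under-resolved")
  # must be applied before stamping
  stamped <- stamp_electrodes(vol, "montage1")
  expect_error(apply_asymmetry(stamped, 1.1), "before")
})

test_that("roi label lookup distinguishes sides and components", {
  vol <- build_phantom(phantom_config(voxel_mm = 2))
  expect_identical(sort(roi_labels(vol, "left", "network")), c(10L, 11L))
  expect_identical(roi_labels(vol, "right", "vestibule"), 12L)
  expect_identical(roi_labels(vol, "right", "scc"), 13L)
  m <- roi_mask(vol, c(10L, 11L))
  expect_identical(sum(m), sum(vol$labels %in% c(10L, 11L)))
})
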