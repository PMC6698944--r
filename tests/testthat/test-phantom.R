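# Digital head phantom: determinism, noiseless exactness, label coverage,
# degradation model, and the mapping error bound against the ground truth.

test_that("the same seed reproduces the phantom bit for bit", {
  ph1 <- phantom_noisy()
  ph2 <- generate_phantom(seed = 0L)
  expect_identical(ph1$mr$data, ph2$mr$data)
  expect_identical(ph1$ct$data, ph2$ct$data)
  expect_identical(ph1$truth$labels, ph2$truth$labels)
  expect_identical(ph1$contours$contours, ph2$contours$contours)
})

test_that("without degradation every tissue sits exactly at its set point", {
  ph <- phantom_clean()
  mr <- ph$mr$data
  expect_true(all(mr[ph$tissue == "wm"] == 1000))
  expect_true(all(mr[ph$tissue == "gm"] == 650))
  expect_true(all(mr[ph$tissue == "csf"] == 200))
  expect_true(all(mr[ph$tissue == "air"] == 0))
  expect_true(all(mr[ph$tissue == "cortical"] == 0))
  ct <- ph$ct$data
  expect_true(all(ct[ph$tissue == "cortical"] == 1000))
  expect_true(all(ct[ph$tissue == "air"] == -1000))
})

test_that("the truth labels partition the grid and contours trace real air", {
  ph <- phantom_noisy()
  expect_true(all(ph$truth$labels %in% SCT_LABELS))
  ks <- vapply(ph$contours$contours, `[[`, 1L, "slice")
  expect_lte(length(unique(ks)), 12L)
  for (ct in ph$contours$contours) {
    m <- rasterize_polygon(ct$vertices, dim(ph$mr$data)[2], dim(ph$mr$data)[3])
    truth_slice <- ph$truth$labels[ct$slice, , ] == SCT_LABELS[["AIR"]]
    # the rasterized polygon reproduces the slice's air region closely
    expect_gte(sum(m & truth_slice) / sum(m | truth_slice), 0.9)
  }
})

test_that("degradation is seeded, Rician and parameter-faithful", {
  v <- const_volume(c(25, 25, 25), 1000)
  # identity when both knobs are off
  expect_identical(degrade(v, 0, 0, 1)$data, v$data)

  # sigma 5 on a bright constant region: the sample sd lands near 5
  d1 <- degrade(v, 0, 5, 7)
  expect_gte(sd(d1$data), 4); expect_lte(sd(d1$data), 6)

  # different seeds differ voxel-wise but share summary statistics
  d2 <- degrade(v, 0, 5, 8)
  expect_false(identical(d1$data, d2$data))
  expect_lt(abs(mean(d1$data) - mean(d2$data)), 1)

  # the bias field stays within its amplitude
  db <- degrade(v, 0.05, 0, 1)
  expect_gte(min(db$data), 950); expect_lte(max(db$data), 1050)

  # low-signal voxels get a Rayleigh floor, not zero-mean noise
  vz <- const_volume(c(25, 25, 25), 0)
  dz <- degrade(vz, 0, 20, 3)
  expect_gt(mean(dz$data), 20)      # Rayleigh mean = sigma * sqrt(pi/2)
  expect_lt(mean(dz$data), 30)
})

test_that("an sCT built from the truth labels stays within half of each HU band", {
  ph <- phantom_noisy()
  arr3 <- function(x) { dim(x) <- dim(ph$truth$labels); x }
  stats <- list(
    cortical = compute_region_stats(ph$mr, arr3(ph$truth$labels == SCT_LABELS[["CORTICAL_BONE"]])),
    trabecular = compute_region_stats(ph$mr, arr3(ph$truth$labels == SCT_LABELS[["TRABECULAR_BONE"]])),
    brain = compute_region_stats(ph$mr, arr3(ph$truth$labels == SCT_LABELS[["BRAIN"]])),
    soft = compute_region_stats(ph$mr, arr3(ph$truth$labels %in%
                                              SCT_LABELS[c("MUSCLE", "FAT")])))
  sct <- assemble_sct(ph$mr, ph$truth, spec = default_mapping_spec(stats))
  half_band <- c(CORTICAL_BONE = 200, TRABECULAR_BONE = 100, BRAIN = 17.5,
                 CSF = 0, EYE = 0, AIR = 0, MUSCLE = 30, FAT = 25)
  for (nm in names(half_band)) {
    reg <- arr3(ph$truth$labels == SCT_LABELS[[nm]])
    e <- ed_errors(sct, ph$ct, reg)
    expect_lte(e[["MAE"]], half_band[[nm]] + 1e-9)
  }
})

test_that("impossible geometry is rejected", {
  expect_error(generate_phantom(size = 64), "geometry")
})

test_that("lesion and skull defect options change only their own tissue", {
  ph <- memo("phantom_lesion",
             generate_phantom(seed = 1L, lesion = TRUE, noise_sigma = 0,
                              bias_amplitude = 0))
  expect_gt(sum(ph$tissue == "contrast"), 0)
  expect_true(all(ph$mr$data[ph$tissue == "contrast"] == 1600))
  expect_true(all(ph$ct$data[ph$tissue == "contrast"] == 0))
})
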