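# Electron-density mapping: the tissue-to-HU transform table and sCT
# assembly.

example_stats <- function() {
  list(cortical = tissue_stats(100, 25, 40, 50),
       trabecular = tissue_stats(800, 30, 700, 50),
       brain = tissue_stats(900, 100, 500, 50),
       soft = tissue_stats(600, 100, 300, 50))
}

test_that("window endpoints and midpoints map exactly for every tissue", {
  spec <- default_mapping_spec(example_stats())
  row_of <- function(t) spec[spec$tissue == t, ]

  cb <- row_of("CORTICAL_BONE")        # window [50, 150] -> [700, 1100] inv
  expect_equal(map_voxel(50, cb), 1100)
  expect_equal(map_voxel(150, cb), 700)
  expect_equal(map_voxel(100, cb), 900)

  tb <- row_of("TRABECULAR_BONE")      # [740, 860] -> [500, 700] inv
  expect_equal(map_voxel(740, tb), 700)
  expect_equal(map_voxel(860, tb), 500)
  expect_equal(map_voxel(800, tb), 600)

  br <- row_of("BRAIN")                # [700, 1100] -> [40, 75] linear
  expect_equal(map_voxel(700, br), 40)
  expect_equal(map_voxel(1100, br), 75)
  expect_equal(map_voxel(900, br), 57.5)

  mu <- row_of("MUSCLE")               # [min_soft, mu+sd] -> [20, 80] inv
  expect_equal(map_voxel(300, mu), 80)
  expect_equal(map_voxel(700, mu), 20)
  expect_equal(map_voxel(500, mu), 50)

  ft <- row_of("FAT")                  # [mu+sd, mu+2sd] -> [-70, -20] inv
  expect_equal(map_voxel(700, ft), -20)
  expect_equal(map_voxel(800, ft), -70)
  expect_equal(map_voxel(750, ft), -45)

  # bulk tissues return their constant for any intensity
  for (tn in c("AIR", "BACKGROUND")) {
    expect_equal(map_voxel(c(0, 123, 9e5), row_of(tn)), rep(-1000, 3))
  }
  expect_equal(map_voxel(c(1, 1000), row_of("CSF")), c(45, 45))
  expect_equal(map_voxel(7, row_of("EYE")), 45)
  expect_equal(map_voxel(1e6, row_of("CONTRAST")), 0)
})

test_that("intensities outside the window clip and degenerate windows midpoint", {
  spec <- default_mapping_spec(example_stats())
  cb <- spec[spec$tissue == "CORTICAL_BONE", ]
  expect_equal(map_voxel(-50, cb), 1100)   # below window -> clipped to lo
  expect_equal(map_voxel(500, cb), 700)
  deg <- data.frame(tissue = "BRAIN", transform = "linear",
                    mr_lo = 100, mr_hi = 100, hu_lo = 40, hu_hi = 75)
  expect_equal(map_voxel(100, deg), 57.5)
  bad <- data.frame(tissue = "BRAIN", transform = "linear",
                    mr_lo = NA_real_, mr_hi = NA_real_, hu_lo = 40, hu_hi = 75)
  expect_error(map_voxel(1, bad), "all-intensity")
})

test_that("mapping-table invariants are validated", {
  expect_error(mapping_spec(data.frame(tissue = "AIR", transform = "bulk",
                                       mr_lo = NA, mr_hi = NA,
                                       hu_lo = -1000, hu_hi = 0)),
               "bulk")
  expect_error(mapping_spec(data.frame(tissue = "BRAIN", transform = "sqrt",
                                       mr_lo = 0, mr_hi = 1,
                                       hu_lo = 0, hu_hi = 1)),
               "transform")
})

test_that("an all-air grid maps to uniform -1000", {
  v <- const_volume(c(3, 4, 5), 20)
  lab <- label_volume(array(SCT_LABELS[["AIR"]], c(3, 4, 5)))
  sct <- assemble_sct(v, lab, spec = default_mapping_spec(example_stats()))
  expect_true(all(sct$data == -1000))
  expect_identical(sct$modality, "CT")
})

test_that("assembled sCT values stay inside each tissue's HU interval", {
  run <- run_noisy()
  hu <- run$sct$data
  lab <- run$labels$labels
  intervals <- list(CORTICAL_BONE = c(700, 1100), TRABECULAR_BONE = c(500, 700),
                    BRAIN = c(40, 75), MUSCLE = c(20, 80), FAT = c(-70, -20))
  for (nm in names(intervals)) {
    sel <- lab == SCT_LABELS[[nm]]
    if (!any(sel)) next
    expect_gte(min(hu[sel]), intervals[[nm]][1])
    expect_lte(max(hu[sel]), intervals[[nm]][2])
  }
  expect_true(all(hu[lab == SCT_LABELS[["CSF"]]] == 45))
  expect_true(all(hu[lab == SCT_LABELS[["AIR"]]] == -1000))
  expect_true(all(hu[lab == SCT_LABELS[["BACKGROUND"]]] == -1000))
})

test_that("inverse-linear transforms are anti-monotone in MR intensity", {
  spec <- default_mapping_spec(example_stats())
  cb <- spec[spec$tissue == "CORTICAL_BONE", ]
  xs <- seq(0, 300, by = 7)
  hus <- map_voxel(xs, cb)
  expect_true(all(diff(hus) <= 0))
  br <- spec[spec$tissue == "BRAIN", ]
  expect_true(all(diff(map_voxel(seq(600, 1200, 13), br)) >= 0))
})

test_that("unmapped label codes are rejected", {
  v <- const_volume(c(2, 2, 2), 10)
  lab <- label_volume(array(SCT_LABELS[["TRABECULAR_BONE"]], c(2, 2, 2)))
  st <- example_stats(); st$trabecular <- NULL
  expect_error(assemble_sct(v, lab, spec = default_mapping_spec(st)),
               "no mapping entry")
})
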