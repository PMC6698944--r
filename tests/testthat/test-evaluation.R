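# Evaluation metrics: Dice, HU errors, region construction, external bone
# contour distances.

test_that("dice follows its set definition and is symmetric", {
  d <- c(2, 4, 4)
  a <- array(FALSE, d); a[1, 1:2, 1:2] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- array(FALSE, d); b[2, 3:4, 3:4] <- TRUE
  expect_equal(dice(a, b), 0)
  # |A| = |B| = 4 with overlap 2 -> 2*2 / 8 = 0.5
  c1 <- array(FALSE, d); c1[1, 1, 1:4] <- TRUE
  c2 <- array(FALSE, d); c2[1, 1, 3:4] <- TRUE; c2[1, 2, 1:2] <- TRUE
  expect_equal(dice(c1, c2), 0.5)
  expect_equal(dice(c1, c2), dice(c2, c1))
  expect_equal(dice(array(FALSE, d), array(FALSE, d)), 1)
  expect_error(dice(a, array(FALSE, c(1, 4, 4))), "shape")
})

test_that("ME/MAE match direct summation", {
  d <- c(1, 1, 2)
  sct <- intensity_volume(array(c(5, 5), d), modality = "CT")
  ct <- intensity_volume(array(c(0, 10), d), modality = "CT")
  e <- ed_errors(sct, ct, array(TRUE, d))
  expect_equal(e[["ME"]], 0)
  expect_equal(e[["MAE"]], 5)

  expect_equal(ed_errors(sct, sct, array(TRUE, d)), c(ME = 0, MAE = 0))
  expect_error(ed_errors(sct, ct, array(FALSE, d)), "empty region")

  # 1000-voxel random instance against the brute-force sums
  set.seed(99)
  dd <- c(10, 10, 10)
  s <- array(runif(1000, -1000, 1000), dd)
  c2 <- array(runif(1000, -1000, 1000), dd)
  reg <- array(runif(1000) < 0.5, dd)
  e2 <- ed_errors(intensity_volume(s, modality = "CT"),
                  intensity_volume(c2, modality = "CT"), reg)
  expect_identical(e2[["ME"]], sum(c2[reg] - s[reg]) / sum(reg))
  expect_identical(e2[["MAE"]], sum(abs(c2[reg] - s[reg])) / sum(reg))
  expect_gte(e2[["MAE"]], abs(e2[["ME"]]))
})

test_that("evaluation regions apply the documented HU boundaries", {
  d <- c(4, 20, 20)
  base_s <- array(-1000, d); base_c <- array(-1000, d)
  base_s[, 5:15, 5:15] <- 40
  base_c[, 5:15, 5:15] <- 40
  base_c[2, 8, 8] <- 150     # soft tissue
  base_c[2, 9, 9] <- 200     # exactly 200 -> bone, not soft tissue
  base_s[3, 10, 10] <- -1000 # sCT air where CT reads -500
  base_c[3, 10, 10] <- -500
  sct <- intensity_volume(base_s, modality = "CT")
  ct <- intensity_volume(base_c, modality = "CT")
  r <- build_eval_regions(sct, ct)
  expect_true(r$soft_tissue[2, 8, 8])
  expect_false(r$soft_tissue[2, 9, 9])
  expect_true(r$bone[2, 9, 9])
  expect_false(r$air[3, 10, 10])        # air only where BOTH read < -800
  expect_true(r$air[1, 1, 1])
  expect_true(all(r$whole_body[, 5:15, 5:15]))
})

test_that("contour distance is zero for identical volumes and exact for shifts", {
  # a full-height bone slab: external contours are two straight lines, so a
  # 1-voxel x-shift moves every contour voxel by exactly 1 mm
  d <- c(8, 30, 30)
  a <- array(-1000, d)
  a[, , 12:18] <- 1000
  slab <- intensity_volume(a, c(1, 1, 1), "CT")
  idresult <- external_bone_contour_distance(slab, slab)
  expect_equal(unname(idresult$per_view[!is.na(idresult$per_view)]),
               rep(0, sum(!is.na(idresult$per_view))))
  expect_equal(idresult$mean, 0)

  b <- array(-1000, d)
  b[, , 13:19] <- 1000
  shifted <- intensity_volume(b, c(1, 1, 1), "CT")
  r <- external_bone_contour_distance(slab, shifted)
  expect_equal(unname(r$per_view[["axial"]]), 1.0)

  # directed measure: sCT -> CT is not symmetric in general
  e <- array(-1000, d); e[4:5, 14:16, 14:16] <- 1000        # small block
  f <- array(-1000, d); f[4:5, 10:20, 10:20] <- 1000        # large block
  de <- external_bone_contour_distance(intensity_volume(e, modality = "CT"),
                                       intensity_volume(f, modality = "CT"))
  df <- external_bone_contour_distance(intensity_volume(f, modality = "CT"),
                                       intensity_volume(e, modality = "CT"))
  expect_false(isTRUE(all.equal(de$mean, df$mean)))

  expect_error(external_bone_contour_distance(
    intensity_volume(array(-1000, d), modality = "CT"), slab), "no bone")
})

test_that("phantom sCT matches the ground-truth CT geometry closely", {
  ph <- phantom_noisy()
  run <- run_noisy()
  r <- external_bone_contour_distance(run$sct, ph$ct)
  expect_lte(r$mean, sqrt(3))       # within one voxel diagonal
  ev <- evaluate_sct(run$sct, ph$ct, run$labels)
  expect_true(all(ev$errors$MAE >= abs(ev$errors$ME)))
  expect_gte(ev$dice[["bone"]], 0.8)
})
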