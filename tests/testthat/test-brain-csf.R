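# Brain/CSF chain: white-matter reference search, edge detection with gap
# closing, brain growing, CSF reference and growing, skull mask.

test_that("the white-matter reference lands in the most uniform bright region", {
  set.seed(31)
  d <- c(40, 40, 40)
  a <- array(0, d)
  a[8:32, 8:32, 4:18] <- rnorm(length(a[8:32, 8:32, 4:18]), 700, 30)   # GM-like
  a[8:32, 8:32, 22:36] <- rnorm(length(a[8:32, 8:32, 22:36]), 1000, 5) # WM-like
  a <- pmax(a, 0)
  v <- intensity_volume(a)
  body <- a > 0
  ref <- find_wm_reference(v, body)
  expect_gte(ref$wmIntensity, 985)
  expect_lte(ref$wmIntensity, 1015)
  expect_equal(ref$window_stat$lo, 0.53 * ref$wmIntensity)
  expect_equal(ref$window_stat$hi, 1.35 * ref$wmIntensity)
  expect_equal(ref$window_grow$lo, 0.7 * ref$wmIntensity)
  expect_equal(ref$window_grow$hi, 1.2 * ref$wmIntensity)
})

test_that("ties between equally uniform regions go to the brighter one", {
  d <- c(40, 40, 40)
  a <- array(100, d)                  # dark filler keeps the median low
  a[4:18, 15:25, 4:18] <- 900
  a[22:36, 15:25, 22:36] <- 1000
  v <- intensity_volume(a)
  ref <- find_wm_reference(v, array(TRUE, d))
  expect_equal(ref$wmIntensity, 1000)
})

test_that("edges of a clean rim form a closed barrier without bridging", {
  d <- c(3, 48, 48)
  a <- array(0, d)
  ix <- as.matrix(expand.grid(1:48, 1:48))
  rr <- sqrt((ix[, 1] - 24)^2 + (ix[, 2] - 24)^2)
  rim <- ix[rr >= 14 & rr <= 17, , drop = FALSE]
  for (k in 1:3) a[cbind(k, rim)] <- 1000
  v <- intensity_volume(a)
  ref <- make_ref(1000)
  edges <- detect_and_close_edges(v, ref)
  expect_true(any(edges[2, , ]))
  # all edge pixels hug the rim
  w <- which(edges[2, , ], arr.ind = TRUE)
  er <- sqrt((w[, 1] - 24)^2 + (w[, 2] - 24)^2)
  expect_true(all(er >= 11 & er <= 20))
})

test_that("a broken rim is closed: flood fill cannot leak inside", {
  d <- c(1, 48, 48)
  a <- array(0, d)
  ix <- as.matrix(expand.grid(1:48, 1:48))
  rr <- sqrt((ix[, 1] - 24)^2 + (ix[, 2] - 24)^2)
  th <- atan2(ix[, 1] - 24, ix[, 2] - 24)
  rim <- rr >= 14 & rr <= 17 & !(abs(th) < 0.12)   # ~3-voxel angular gap
  a[cbind(1, ix[rim, , drop = FALSE])] <- 1000
  v <- intensity_volume(a)
  edges <- detect_and_close_edges(v, make_ref(1000))
  # flood from a corner, blocked only by the closed edges: the centre must
  # stay unreached
  flood <- region_grow(v, c(1, 1, 1), c(0, 2000), barrier = edges)
  expect_false(flood[1, 24, 24])

  # an all-zero volume has no edges
  expect_false(any(detect_and_close_edges(const_volume(c(2, 10, 10), 0),
                                          make_ref(1000))))
})

test_that("initial brain growing honours the closed window and edge barriers", {
  d <- c(10, 20, 20)
  a <- array(0, d)
  a[3:8, 3:10, 3:18] <- 1000
  a[5, 5, 5] <- 700                  # exactly 0.7 * wm: included (closed)
  a[5, 5, 6] <- 699.9                # just below: excluded
  v <- intensity_volume(a)
  ref <- make_ref(1000, voxel = c(4, 4, 4))
  g <- segment_brain_initial(v, ref, edges = NULL)
  expect_true(g[5, 5, 5])
  expect_false(g[5, 5, 6])

  # an in-window bridge covered by edges is not crossed
  a2 <- array(0, d)
  a2[5, 5, 1:20] <- 1000
  edges <- array(FALSE, d); edges[5, 5, 10] <- TRUE
  v2 <- intensity_volume(a2)
  g2 <- segment_brain_initial(v2, make_ref(1000, voxel = c(5, 5, 2)), edges)
  expect_false(any(g2[5, 5, 11:20]))

  expect_error(segment_brain_initial(v, make_ref(1000, voxel = c(1, 1, 1))),
               "seed outside intensity window")
})

test_that("the CSF reference finds the uniform dark cavity inside the brain", {
  set.seed(41)
  d <- c(30, 30, 30)
  a <- array(rnorm(prod(d), 1000, 5), d)
  a[10:16, 10:16, 10:16] <- rnorm(343, 200, 5)     # ventricle
  a <- pmax(a, 0)
  v <- intensity_volume(a)
  brain0 <- array(TRUE, d)
  ref <- make_ref(1000)
  st <- find_csf_reference(v, brain0, ref)
  expect_gte(st$mean, 185); expect_lte(st$mean, 215)
  expect_true(all(st$center >= 10 & st$center <= 16))

  # no voxel below 0.53 wm: error
  v2 <- intensity_volume(array(1000, d))
  expect_error(find_csf_reference(v2, brain0, ref), "no CSF reference")

  # two candidate cavities: the more uniform one wins
  set.seed(42)
  a3 <- array(1000, d)
  a3[5:9, 5:9, 5:9] <- rnorm(125, 200, 20)
  a3[20:24, 20:24, 20:24] <- rnorm(125, 200, 5)
  v3 <- intensity_volume(pmax(a3, 0))
  st3 <- find_csf_reference(v3, array(TRUE, d), ref)
  expect_true(all(st3$center >= 20))
})

test_that("CSF growing is window-bound and respects the skull barrier", {
  d <- c(12, 12, 12)
  a <- array(1000, d)
  a[4:9, 4:9, 4:9] <- 200
  v <- intensity_volume(a)
  skull <- array(FALSE, d); skull[, , 11:12] <- TRUE
  a[6, 6, 11] <- 200                  # CSF-intensity voxel inside the skull mask
  v <- intensity_volume(a)
  st <- tissue_stats(200, 10, 180, 27)
  seeds <- array(FALSE, d); seeds[6, 6, 6] <- TRUE
  g <- segment_csf(v, st, skull, seeds = seeds)
  expect_true(all(g[4:9, 4:9, 4:9]))
  expect_false(g[6, 6, 11])

  expect_error(segment_csf(v, st, skull,
                           seeds = { s <- array(FALSE, d); s[6, 6, 11] <- TRUE; s }),
               "seed in skull mask")

  # degenerate window: only exact-intensity voxels grow
  st0 <- tissue_stats(200, 0, 200, 27)
  a[5, 5, 5] <- 200.5
  g0 <- segment_csf(intensity_volume(a), st0, skull, seeds = seeds)
  expect_false(g0[5, 5, 5])
})

test_that("final brain includes connected in-window tissue outside the skull mask", {
  d <- c(10, 14, 14)
  a <- array(0, d)
  a[3:8, 3:8, 3:8] <- 1000
  a[3:8, 9:11, 3:8] <- 600           # GM at 0.6 wm, adjacent
  a[3:8, 12, 3:8] <- 600             # same intensity, but inside skull mask
  v <- intensity_volume(a)
  skull <- array(FALSE, d); skull[, 12:14, ] <- TRUE
  brain0 <- array(FALSE, d); brain0[3:8, 3:8, 3:8] <- TRUE
  csf <- array(FALSE, d)
  bf <- segment_brain_final(v, make_ref(1000), brain0, csf, skull)
  expect_true(all(bf[3:8, 9:11, 3:8]))
  expect_false(any(bf[, 12, ]))
  expect_true(all(bf[brain0]))       # always a superset of the initial brain
})

test_that("skull growing does not enter the brain through a surgical defect", {
  ph <- memo("phantom_defect",
             generate_phantom(seed = 2L, skull_defect = TRUE))
  mr <- ph$mr
  roi <- interpolate_contours(ph$contours, mr)
  ast <- estimate_air_stats(mr, roi)
  body <- external_body_contour(mr, ast)
  air <- build_air_mask(mr, roi, ast)
  ref <- find_wm_reference(mr, body)
  edges <- detect_and_close_edges(mr, ref)
  brain0 <- segment_brain_initial(mr, ref, edges)
  csf_ref <- find_csf_reference(mr, brain0, ref)
  skull <- build_skull_mask(mr, body, brain0, csf_ref, ast, edges, air_mask = air)
  tb <- truth_mask(ph, "BRAIN")
  expect_equal(sum(skull & tb), 0)
  expect_error(build_skull_mask(mr, body, brain0, csf_ref,
                                tissue_stats(0, 0, 0, 1), edges,
                                air_mask = array(TRUE, dim(mr$data))),
               "no skull seed")
})

test_that("pipeline masks are mutually exclusive on the phantom", {
  run <- run_noisy()
  brain <- label_mask(run, "BRAIN")
  csf <- label_mask(run, "CSF")
  eyes <- label_mask(run, "EYE")
  bone <- label_mask(run, "CORTICAL_BONE", "TRABECULAR_BONE")
  air <- label_mask(run, "AIR")
  expect_equal(sum(brain & csf), 0)
  expect_equal(sum(brain & bone), 0)
  expect_equal(sum(eyes & (brain | csf | bone | air)), 0)
})
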