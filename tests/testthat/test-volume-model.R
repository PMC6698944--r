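# Core grid primitives: region statistics, uniformity, region growing and
# connected components.

test_that("region statistics use the population sd and reject empty masks", {
  v <- intensity_volume(array(c(2, 4, 9, 9), c(1, 2, 2)))
  m <- array(c(TRUE, TRUE, FALSE, FALSE), c(1, 2, 2))
  st <- compute_region_stats(v, m)
  expect_equal(st$mean, 3)
  expect_equal(st$sd, 1)          # population sd of {2, 4}
  expect_equal(st$min, 2)
  expect_equal(st$n, 2L)

  cst <- compute_region_stats(intensity_volume(array(5, c(1, 1, 3))),
                              array(TRUE, c(1, 1, 3)))
  expect_equal(cst$sd, 0)
  expect_equal(cst$mean, 5)

  expect_error(compute_region_stats(v, array(FALSE, c(1, 2, 2))), "empty region")
})

test_that("uniformity is mean/sd with an infinite sentinel for flat windows", {
  v <- intensity_volume(array(c(2, 4, 2, 4), c(1, 2, 2)))
  expect_equal(compute_uniformity(v, c(1, 1, 1), c(0, 2, 0)), 3 / 1)

  v2 <- intensity_volume(array(7, c(3, 3, 3)))
  expect_identical(compute_uniformity(v2, c(2, 2, 2), 10), Inf)

  v3 <- intensity_volume(array(c(10, 10, 10, 14), c(1, 2, 2)))
  expect_equal(compute_uniformity(v3, c(1, 1, 1), c(0, 10, 10)), 11 / sqrt(3))

  expect_error(compute_uniformity(v2, c(4, 1, 1), 10), "outside grid")
})

test_that("uniformity is invariant under positive intensity rescale", {
  set.seed(11)
  a <- array(abs(rnorm(125, 100, 15)), c(5, 5, 5))
  v1 <- intensity_volume(a)
  v2 <- intensity_volume(a * 2.5)
  for (ctr in list(c(3, 3, 3), c(2, 4, 3), c(5, 1, 2))) {
    expect_equal(compute_uniformity(v1, ctr, 3),
                 compute_uniformity(v2, ctr, 3), tolerance = 1e-12)
  }
})

test_that("region growing follows intensity windows, barriers and seeds", {
  # uniform in-window block: everything reached
  v <- const_volume(c(4, 4, 4), 10)
  expect_true(all(region_grow(v, c(1, 1, 1), c(5, 15))))

  # enclosed interior: an out-of-window shell stops the growth
  a <- array(100, c(7, 7, 7))
  a[3:5, 3:5, 3:5] <- 10
  v <- intensity_volume(a)
  g <- region_grow(v, c(4, 4, 4), c(0, 50))
  expect_equal(sum(g), 27)
  expect_true(all(which(g, arr.ind = TRUE) >= 3 & which(g, arr.ind = TRUE) <= 5))

  # two blobs split by an out-of-window wall: only the seeded one grows
  a <- array(10, c(5, 5, 5))
  a[, , 3] <- 100
  v <- intensity_volume(a)
  g <- region_grow(v, c(1, 1, 1), c(0, 50), connectivity = 6L)
  oracle <- oracle_flood(a, { s <- array(FALSE, c(5, 5, 5)); s[1, 1, 1] <- TRUE; s },
                         0, 50)
  expect_identical(as.vector(g), as.vector(oracle))
  expect_false(any(g[, , 4:5]))

  expect_error(region_grow(v, c(1, 1, 3), c(0, 50)),
               "seed outside intensity window")
})

test_that("region growing matches the brute-force flood fill on random instances", {
  set.seed(42)
  for (i in 1:40) {
    d <- sample(3:12, 3, replace = TRUE)
    a <- array(sample(0:4, prod(d), replace = TRUE) * 10, d)
    conn <- sample(c(6L, 26L), 1)
    barrier <- array(runif(prod(d)) < 0.15, d)
    lo <- 0; hi <- 20
    cand <- which(a >= lo & a <= hi & !barrier)
    if (length(cand) == 0L) next
    seed_idx <- sample(cand, 1)
    seeds <- array(FALSE, d); seeds[seed_idx] <- TRUE
    g <- region_grow(intensity_volume(a), seeds, c(lo, hi), barrier, conn)
    o <- oracle_flood(a, seeds, lo, hi, barrier, conn)
    expect_identical(as.vector(g), as.vector(o))
  }
})

test_that("region growing is monotone in the window", {
  set.seed(7)
  for (i in 1:10) {
    d <- c(8, 8, 8)
    a <- array(sample(0:9, prod(d), replace = TRUE), d)
    seeds <- array(FALSE, d); seeds[1] <- TRUE
    a[1] <- 3
    g1 <- region_grow(intensity_volume(a), seeds, c(2, 5))
    g2 <- region_grow(intensity_volume(a), seeds, c(1, 7))
    expect_true(all(g2[g1]))
  }
})

test_that("connected components: connectivity rules and size accounting", {
  cube <- array(FALSE, c(4, 4, 4)); cube[2:3, 2:3, 2:3] <- TRUE
  expect_length(connected_components(cube, 6L)$sizes, 1L)

  diag2 <- array(FALSE, c(1, 2, 2)); diag2[1, 1, 1] <- TRUE; diag2[1, 2, 2] <- TRUE
  expect_length(connected_components(diag2, 6L)$sizes, 2L)
  expect_length(connected_components(diag2, 26L)$sizes, 1L)

  # 3x3 checkerboard slice, 4-connectivity in plane: 9 isolated cells split
  # 5 of one colour and 4 of the other, as enumerated by the oracle
  cb <- outer(1:3, 1:3, function(i, j) (i + j) %% 2 == 0)
  cc5 <- connected_components(cb, 6L)
  expect_length(cc5$sizes, 5L)
  cc4 <- connected_components(!cb, 6L)
  expect_length(cc4$sizes, 4L)
  olab <- oracle_components(array(cb, c(1, 3, 3)), 6L)
  expect_equal(max(olab), 5L)

  # sizes always sum to the voxel count of the mask
  set.seed(3)
  m <- array(runif(6 * 7 * 8) < 0.4, c(6, 7, 8))
  cc <- connected_components(m, 26L)
  expect_equal(sum(cc$sizes), sum(m))
  expect_equal(sum(connected_components(m, 6L)$sizes), sum(m))
})

test_that("mm_to_voxels yields odd counts and respects spacing", {
  expect_equal(mm_to_voxels(5, 1), 5L)
  expect_equal(mm_to_voxels(10, 2), 5L)
  expect_equal(mm_to_voxels(0, 1), 1L)
  expect_equal(mm_to_voxels(1.2, 1), 1L)
  expect_true(all(mm_to_voxels(c(3, 7, 10), c(1, 1.5, 3)) %% 2L == 1L))
})

test_that("volume constructors enforce their invariants", {
  expect_error(intensity_volume(array(1, c(2, 2)), modality = "MR"), "3D")
  expect_error(intensity_volume(array(-1, c(2, 2, 2)), modality = "MR"), ">= 0")
  expect_error(intensity_volume(array(1, c(2, 2, 2)), spacing_mm = c(1, 0, 1)),
               "positive")
  expect_error(label_volume(array(77L, c(2, 2, 2))), "unknown label")
  expect_error(tissue_stats(1, -1, 0, 5), "sd")
  expect_error(intensity_window(2, 1), "lo <= hi")
})
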