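# Shared fixtures and independent oracles. The full-size phantom and its
# pipeline runs are expensive, so they are computed lazily once per session
# and reused across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# default study conditions: seed 0, Rician sigma 2% of the white-matter
# level, +/- 5% bias
phantom_noisy <- function() memo("phantom_noisy", generate_phantom(seed = 0L))

phantom_clean <- function() memo("phantom_clean",
  generate_phantom(seed = 0L, noise_sigma = 0, bias_amplitude = 0))

run_noisy <- function() memo("run_noisy", {
  ph <- phantom_noisy()
  suppressMessages(mr2sct(ph$mr, ph$contours))
})

run_clean <- function() memo("run_clean", {
  ph <- phantom_clean()
  suppressMessages(mr2sct(ph$mr, ph$contours))
})

label_mask <- function(run, ...) {
  codes <- unlist(SCT_LABELS[c(...)])
  m <- run$labels$labels %in% codes
  dim(m) <- dim(run$labels$labels)
  m
}

truth_mask <- function(ph, ...) {
  codes <- unlist(SCT_LABELS[c(...)])
  m <- ph$truth$labels %in% codes
  dim(m) <- dim(ph$truth$labels)
  m
}

# --- independent oracles --------------------------------------------------

shift_arr <- function(a, dz, dy, dx) {
  d <- dim(a)
  out <- array(FALSE, d)
  zs <- seq_len(d[1]) - dz; ys <- seq_len(d[2]) - dy; xs <- seq_len(d[3]) - dx
  okz <- zs >= 1 & zs <= d[1]; oky <- ys >= 1 & ys <= d[2]; okx <- xs >= 1 & xs <= d[3]
  out[okz, oky, okx] <- a[zs[okz], ys[oky], xs[okx]]
  out
}

neighbour_offsets <- function(connectivity) {
  if (connectivity == 6L) {
    list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    out <- list()
    for (a in -1:1) for (b in -1:1) for (c in -1:1)
      if (!(a == 0 && b == 0 && c == 0)) out[[length(out) + 1L]] <- c(a, b, c)
    out
  }
}

# brute-force flood fill: iterate masked dilation from the seeds to a fixed
# point (independent of the BFS implementation under test)
oracle_flood <- function(values, seeds_mask, lo, hi, barrier = NULL,
                         connectivity = 6L) {
  ok <- values >= lo & values <= hi
  if (!is.null(barrier)) ok <- ok & !barrier
  cur <- seeds_mask & ok
  offs <- neighbour_offsets(connectivity)
  repeat {
    grown <- cur
    for (o in offs) grown <- grown | shift_arr(cur, o[1], o[2], o[3])
    grown <- grown & ok
    if (identical(grown, cur)) break
    cur <- grown
  }
  cur
}

# exhaustive connected components via repeated oracle floods
oracle_components <- function(mask, connectivity = 6L) {
  lab <- array(0L, dim(mask))
  vals <- mask * 1.0
  nid <- 0L
  while (any(mask & lab == 0L)) {
    nid <- nid + 1L
    seed <- array(FALSE, dim(mask))
    seed[which(mask & lab == 0L)[1]] <- TRUE
    comp <- oracle_flood(vals, seed, 1, 1, NULL, connectivity)
    lab[comp] <- nid
  }
  lab
}

# minimal brain reference for unit tests that drive single stages
make_ref <- function(wm = 1000, voxel = c(1, 1, 1),
                     stat = c(0.53, 1.35), grow = c(0.7, 1.2)) {
  structure(list(wm_voxel = as.integer(voxel), wmIntensity = wm,
                 window_stat = intensity_window(stat[1] * wm, stat[2] * wm),
                 window_grow = intensity_window(grow[1] * wm, grow[2] * wm)),
            class = "brain_reference")
}

# small volume with a given background value
const_volume <- function(dim, value = 0, spacing = c(1, 1, 1),
                         modality = "MR") {
  intensity_volume(array(value, dim), spacing, modality)
}

sphere_in <- function(a, center, r, value) {
  d <- dim(a)
  ix <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  sel <- (ix[, 1] - center[1])^2 + (ix[, 2] - center[2])^2 +
    (ix[, 3] - center[3])^2 <= r^2
  a[ix[sel, , drop = FALSE]] <- value
  a
}
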