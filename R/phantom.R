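# Digital head phantom: paired T1-like MR and ground-truth CT volumes with
# a complete tissue label map and auto-derived air contours, so the whole
# pipeline can be exercised end to end without any patient data.
#
# Geometry (all in mm, defined on a ~192 mm cubic domain): an ellipsoidal
# head with a 4 mm fat and 4 mm muscle scalp, a cranial vault 8 mm under
# the surface built of two 2 mm cortical tables sandwiching a 3 mm patchy
# trabecular diploe (with full-thickness cortical bridges, like sutures, so
# the cortical shell is one connected component and the diploe pockets are
# genuinely enclosed); inside: a 3 mm subarachnoid CSF film, a 6 mm gray
# matter rind and a white-matter core with an ellipsoidal ventricle
# connected to the film by a narrow CSF channel. The anterior-inferior face
# region carries two spherical eyes (each wrapped in a thin extraocular
# muscle rim), an ellipsoidal nasal cavity and a tubular airway (air).
# Optional extras: a contrast-enhancing lesion in the white matter and a
# surgical skull defect. MR intensities are per-tissue constants degraded
# by a smooth multiplicative bias field and Rician noise; the CT volume
# assigns one canonical HU per tissue.

phantom_mr_means <- function() {
  c(background = 0, air = 0, cortical = 0, trabecular = 870,
    wm = 1000, gm = 650, csf = 200, eye = 500,
    muscle = 780, fat = 1150, contrast = 1600)
}

phantom_ct_hu <- function() {
  c(background = -1000, air = -1000, cortical = 1000, trabecular = 600,
    wm = 55, gm = 55, csf = 45, eye = 45,
    muscle = 50, fat = -45, contrast = 0)
}

phantom_label_of <- function() {
  c(background = SCT_LABELS[["BACKGROUND"]], air = SCT_LABELS[["AIR"]],
    cortical = SCT_LABELS[["CORTICAL_BONE"]],
    trabecular = SCT_LABELS[["TRABECULAR_BONE"]],
    wm = SCT_LABELS[["BRAIN"]], gm = SCT_LABELS[["BRAIN"]],
    csf = SCT_LABELS[["CSF"]], eye = SCT_LABELS[["EYE"]],
    muscle = SCT_LABELS[["MUSCLE"]], fat = SCT_LABELS[["FAT"]],
    contrast = SCT_LABELS[["CONTRAST"]])
}

# evaluate an ellipsoid indicator on the coordinate vectors
ellipsoid_mask <- function(Z, Y, X, center, semi) {
  e1 <- ((Z - center[1]) / semi[1])^2
  e2 <- ((Y - center[2]) / semi[2])^2
  e3 <- ((X - center[3]) / semi[3])^2
  outer(outer(e1, e2, "+"), e3, "+") <= 1
}

sphere_mask <- function(Z, Y, X, center, r) {
  ellipsoid_mask(Z, Y, X, center, rep(r, 3))
}

#' Generate the digital head phantom
#'
#' @param size grid extent in voxels (scalar or length 3); the default
#'   192 voxels at 1 mm spacing holds the whole head.
#' @param spacing_mm voxel spacing `(dz, dy, dx)`.
#' @param seed integer seed fixing all randomness (noise and bias are the
#'   only stochastic parts).
#' @param noise_sigma Rician noise sigma in MR units (default 20, i.e. 2%
#'   of the white-matter level 1000).
#' @param bias_amplitude relative amplitude of the smooth multiplicative
#'   bias field (default 0.05, i.e. +/- 5%).
#' @param lesion add a contrast-enhancing lesion in the white matter.
#' @param skull_defect carve a surgical defect through the skull vault
#'   (the underlying CSF film stays intact).
#' @param max_contour_slices number of axial slices carrying air contours.
#' @return Object of class `head_phantom`: list with `mr`, `ct`
#'   ([intensity_volume]s), `truth` ([label_volume]), `contours`
#'   ([contour_set]) and `tissue` (character array of the fine tissue
#'   codes, distinguishing white and gray matter).
#' @export
generate_phantom <- function(size = 192L, spacing_mm = c(1, 1, 1), seed = 0L,
                             noise_sigma = 20, bias_amplitude = 0.05,
                             lesion = FALSE, skull_defect = FALSE,
                             max_contour_slices = 12L) {
  if (length(size) == 1L) size <- rep(size, 3L)
  size <- as.integer(size)
  sp <- as.numeric(spacing_mm)
  if (any(size * sp < 184))
    stop("inconsistent geometry: the head spans ~184 mm; increase size or spacing")
  d <- size
  Z <- (seq_len(d[1]) - 1) * sp[1]
  Y <- (seq_len(d[2]) - 1) * sp[2]
  X <- (seq_len(d[3]) - 1) * sp[3]

  head <- ellipsoid_mask(Z, Y, X, c(96, 94, 96), c(88, 84, 78))
  head_depth <- distance_to_mask(!head, sp)
  if (max(head_depth[head]) < 20) stop("inconsistent geometry: head too thin for the grid")

  carve <- outer(outer(Z < 120, Y > 110, "&"), rep(TRUE, d[3]), "&")
  cranium <- (head_depth > 8) & !carve
  depth <- distance_to_mask(!cranium, sp)
  if (max(depth) <= 7 + max(sp)) stop("inconsistent geometry: shell thinner than a voxel")

  # suture-like bridges: where the smooth field is high, the diploe layer is
  # replaced by full-thickness cortical bone, connecting the two tables
  gz <- sin(2 * pi * Z / 40); gy <- sin(2 * pi * Y / 40); gx <- sin(2 * pi * X / 40)
  bridge <- outer(outer(gz, gy, "*"), gx, "*") > 0.15

  tissue <- array("background", d)
  tissue[head & head_depth <= 4] <- "fat"
  tissue[head & head_depth > 4] <- "muscle"
  tissue[cranium & depth <= 2] <- "cortical"
  tl <- cranium & depth > 2 & depth <= 5
  tissue[tl & !bridge] <- "trabecular"
  tissue[tl & bridge] <- "cortical"
  tissue[cranium & depth > 5 & depth <= 7] <- "cortical"
  tissue[cranium & depth > 7 & depth <= 10] <- "csf"
  tissue[cranium & depth > 10 & depth <= 16] <- "gm"
  tissue[cranium & depth > 16] <- "wm"

  # ventricle (fully inside the white-matter core) + a narrow channel to
  # the subarachnoid film (posterior)
  vent <- ellipsoid_mask(Z, Y, X, c(100, 80, 96), c(14, 10, 10))
  tissue[vent] <- "csf"
  chan <- outer(outer((Z - 100)^2, rep(1, d[2]), "*"), (X - 96)^2, "+") <= 2.5^2
  chan <- chan & outer(outer(rep(TRUE, d[1]), Y >= 26 & Y <= 80, "&"), rep(TRUE, d[3]), "&")
  tissue[chan & cranium & depth > 7] <- "csf"

  if (lesion) {
    les <- sphere_mask(Z, Y, X, c(120, 70, 110), 8)
    tissue[les & tissue == "wm"] <- "contrast"
  }
  if (skull_defect) {
    def <- sphere_mask(Z, Y, X, c(170, 94, 96), 15)
    tissue[def & cranium & depth <= 7] <- "muscle"
  }

  # eyes wrapped in an extraocular muscle rim, then the nasal cavity and
  # airway (air regions are painted last; geometry keeps them clear of the
  # eye rims)
  for (cx in c(69, 123)) {
    tissue[sphere_mask(Z, Y, X, c(100, 143, cx), 18)] <- "muscle"
  }
  for (cx in c(69, 123)) {
    tissue[sphere_mask(Z, Y, X, c(100, 143, cx), 16)] <- "eye"
  }
  nasal <- ellipsoid_mask(Z, Y, X, c(85, 140, 96), c(25, 18, 8))
  airway <- outer(outer((Z >= 30 & Z <= 85), (Y - 140)^2, function(a, b) ifelse(a, b, Inf)),
                  (X - 96)^2, "+") <= 6^2
  tissue[nasal | airway] <- "air"

  means <- phantom_mr_means()
  hus <- phantom_ct_hu()
  labmap <- phantom_label_of()
  mr0 <- array(means[tissue], d)
  ct <- array(hus[tissue], d)
  labels <- array(labmap[tissue], d)
  storage.mode(labels) <- "integer"

  mr <- degrade(intensity_volume(mr0, sp, "MR"), bias_amplitude, noise_sigma, seed)

  air_truth <- labels == SCT_LABELS[["AIR"]]
  contours <- contours_from_mask(air_truth, max_contour_slices)

  structure(list(
    mr = mr,
    ct = intensity_volume(ct, sp, "CT"),
    truth = label_volume(labels, sp),
    contours = contours,
    tissue = tissue
  ), class = "head_phantom")
}

#' @export
print.head_phantom <- function(x, ...) {
  d <- dim(x$truth$labels)
  cat(sprintf("<head_phantom> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  print(x$truth)
  print(x$contours)
  invisible(x)
}

#' Degrade an MR volume with a bias field and Rician noise
#'
#' Multiplies the volume by a smooth low-order field taking values in
#' `[1 - a, 1 + a]` and applies Rician noise (the magnitude of the signal
#' plus complex Gaussian noise, the standard model for magnitude MR; in
#' signal-free air it leaves a Rayleigh noise floor rather than zero).
#' Deterministic per seed; the caller's RNG state is preserved.
#'
#' @param mr an MR [intensity_volume].
#' @param bias_amplitude relative bias amplitude `a >= 0`.
#' @param noise_sigma Rician sigma in MR units, `>= 0`.
#' @param seed integer seed.
#' @return the degraded [intensity_volume].
#' @export
degrade <- function(mr, bias_amplitude = 0.05, noise_sigma = 20, seed = 0L) {
  stopifnot(bias_amplitude >= 0, noise_sigma >= 0)
  v <- vol_data(mr)
  d <- dim(v)
  sp <- vol_spacing(mr)
  if (bias_amplitude > 0) {
    u1 <- (seq_len(d[1]) - 1) / max(d[1] - 1, 1) - 0.5
    u2 <- (seq_len(d[2]) - 1) / max(d[2] - 1, 1) - 0.5
    u3 <- (seq_len(d[3]) - 1) / max(d[3] - 1, 1) - 0.5
    g <- outer(outer(0.9 * sin(pi * u1), 0.7 * sin(pi * u2), "+"),
               0.5 * sin(pi * u3), "+") +
      outer(outer(u1, 0.8 * u2, "*"), rep(1, d[3]), "*")
    g <- g / max(abs(g))
    v <- v * (1 + bias_amplitude * g)
  }
  if (noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
    n <- length(v)
    v <- sqrt((v + rnorm(n, sd = noise_sigma))^2 + rnorm(n, sd = noise_sigma)^2)
    dim(v) <- d
  }
  intensity_volume(v, sp, "MR")
}
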