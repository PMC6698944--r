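#' Tissue label codes
#'
#' Integer codes used in label volumes. Every voxel of a complete label map
#' carries exactly one of these labels.
#'
#' @format Named integer vector.
#' @export
SCT_LABELS <- c(
  BACKGROUND      = 0L,
  AIR             = 1L,
  CORTICAL_BONE   = 2L,
  TRABECULAR_BONE = 3L,
  BRAIN           = 4L,
  CSF             = 5L,
  EYE             = 6L,
  MUSCLE          = 7L,
  FAT             = 8L,
  CONTRAST        = 9L
)

#' Construct an intensity volume
#'
#' A 3D scalar grid holding either MR intensities (arbitrary units, shifted
#' non-negative on load) or CT numbers (HU). Indexing is `[k, row, col]`
#' where `k` runs along the axial (inferior-to-superior) axis, `row` along
#' the posterior-to-anterior axis and `col` along the right-to-left axis.
#' Coronal slices are fixed `row`, sagittal slices fixed `col`.
#'
#' @param data 3D numeric array, extents all >= 1.
#' @param spacing_mm numeric length 3, voxel spacing `(dz, dy, dx)` in mm,
#'   strictly positive.
#' @param modality `"MR"` or `"CT"`.
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(data, spacing_mm = c(1, 1, 1), modality = c("MR", "CT")) {
  modality <- match.arg(modality)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("all three extents must be >= 1")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three strictly positive numbers")
  if (anyNA(data) || any(!is.finite(data))) stop("volume values must be finite")
  if (modality == "MR" && min(data) < 0)
    stop("MR intensities must be >= 0 (shift on load)")
  structure(list(data = data, spacing_mm = spacing_mm, modality = modality),
            class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<intensity_volume> %s  %d x %d x %d voxels  spacing %.3g x %.3g x %.3g mm\n",
              x$modality, d[1], d[2], d[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a label volume
#'
#' @param labels 3D integer array aligned to a parent [intensity_volume];
#'   values must be codes from [SCT_LABELS].
#' @param spacing_mm voxel spacing of the parent grid.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing_mm = c(1, 1, 1)) {
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  if (!all(labels %in% SCT_LABELS)) stop("unknown label code in `labels`")
  structure(list(labels = labels, spacing_mm = as.numeric(spacing_mm)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  tab <- tabulate(x$labels + 1L, nbins = length(SCT_LABELS))
  names(tab) <- names(SCT_LABELS)
  print(tab[tab > 0])
  invisible(x)
}

#' Per-tissue intensity statistics
#'
#' @param mean,sd,min scalars (sd is the population standard deviation).
#' @param n number of contributing voxels (>= 1).
#' @return Object of class `tissue_stats`.
#' @export
tissue_stats <- function(mean, sd, min, n = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (sd < 0) stop("sd must be >= 0")
  structure(list(mean = mean, sd = sd, min = min, n = as.integer(n)),
            class = "tissue_stats")
}

#' @export
print.tissue_stats <- function(x, ...) {
  cat(sprintf("<tissue_stats> mean %.4g  sd %.4g  min %.4g  n %d\n",
              x$mean, x$sd, x$min, x$n))
  invisible(x)
}

#' Closed intensity window
#'
#' @param lo,hi window endpoints, `lo <= hi`. All windows in the pipeline
#'   are closed intervals.
#' @export
intensity_window <- function(lo, hi) {
  if (lo > hi) stop("window requires lo <= hi")
  structure(list(lo = lo, hi = hi), class = "intensity_window")
}

vol_data <- function(volume) {
  if (inherits(volume, "intensity_volume")) volume$data else volume
}

vol_spacing <- function(volume) {
  if (inherits(volume, "intensity_volume")) volume$spacing_mm else c(1, 1, 1)
}

check_mask <- function(mask, volume) {
  d <- dim(vol_data(volume))
  if (!identical(dim(mask), d)) stop("mask shape does not match volume")
  mask
}

#' Intensity statistics over a masked region
#'
#' Mean, population standard deviation and minimum of the voxel intensities
#' under a logical mask.
#'
#' @param volume an [intensity_volume].
#' @param mask logical array of the same shape with at least one `TRUE` voxel.
#' @return A [tissue_stats].
#' @export
compute_region_stats <- function(volume, mask) {
  check_mask(mask, volume)
  v <- vol_data(volume)[mask]
  if (length(v) == 0L) stop("empty region")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  tissue_stats(mean = m, sd = s, min = min(v), n = length(v))
}

#' Convert a physical window extent to an odd voxel count
#'
#' `2 * floor((mm / spacing) / 2) + 1`: the odd count whose physical span is
#' closest to `mm` from below, never less than one voxel. An extent of 0
#' requests a single-voxel (in-plane) span along that axis.
#'
#' @param mm physical extent(s) in mm.
#' @param spacing_mm voxel spacing along the same axis.
#' @return integer voxel count(s), always odd and >= 1.
#' @export
mm_to_voxels <- function(mm, spacing_mm) {
  n <- 2L * as.integer(floor((mm / spacing_mm) / 2)) + 1L
  pmax(n, 1L)
}

#' Local intensity uniformity
#'
#' Uniformity of the neighbourhood of a voxel, defined as mean / sd of the
#' intensities in a window centred on the voxel (population sd). A perfectly
#' uniform window (sd = 0) returns `Inf`. The window is specified as a
#' physical extent per axis; an extent of 0 keeps the window one voxel thick
#' along that axis (an in-plane window). Windows are clipped at the grid
#' boundary.
#'
#' @param volume an [intensity_volume].
#' @param center voxel index `c(k, row, col)`, 1-based.
#' @param window_mm physical window extent in mm; length 1 (cubic) or 3
#'   (per axis `(dz, dy, dx)`).
#' @return scalar uniformity (possibly `Inf`).
#' @export
compute_uniformity <- function(volume, center, window_mm) {
  v <- vol_data(volume)
  d <- dim(v)
  center <- as.integer(center)
  if (length(center) != 3L || any(center < 1L) || any(center > d))
    stop("center outside grid")
  if (length(window_mm) == 1L) window_mm <- rep(window_mm, 3L)
  sp <- vol_spacing(volume)
  half <- (mm_to_voxels(window_mm, sp) - 1L) %/% 2L
  lo <- pmax(center - half, 1L)
  hi <- pmin(center + half, d)
  w <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  m <- mean(w)
  s <- sqrt(mean((w - m)^2))
  if (s == 0) Inf else m / s
}

normalize_seeds <- function(seeds, d) {
  if (is.null(dim(seeds))) seeds <- matrix(as.integer(seeds), ncol = 3L)
  storage.mode(seeds) <- "integer"
  if (ncol(seeds) != 3L) stop("seeds must be an n x 3 matrix of (k, row, col)")
  if (any(seeds < 1L) || any(seeds[, 1] > d[1]) || any(seeds[, 2] > d[2]) ||
      any(seeds[, 3] > d[3]))
    stop("seed outside grid")
  # 0-based linear index, axial index fastest
  (seeds[, 1] - 1L) + d[1] * ((seeds[, 2] - 1L) + d[2] * (seeds[, 3] - 1L))
}

#' Intensity-windowed region growing
#'
#' Flood fill from seed voxels through voxels whose intensity lies inside a
#' closed window and which are not barrier voxels. The result is the union
#' of connected in-window components touching a seed.
#'
#' @param volume an [intensity_volume].
#' @param seeds n x 3 integer matrix of voxel indices `(k, row, col)`,
#'   1-based (a length-3 vector is accepted for a single seed), or a logical
#'   array used as a seed mask.
#' @param window an [intensity_window] (or `c(lo, hi)`).
#' @param barrier optional logical array of blocked voxels.
#' @param connectivity 6 (face) or 26 (full) neighbourhood; the pipeline
#'   default is 6, which is conservative against leakage.
#' @return logical array of grown voxels.
#' @export
region_grow <- function(volume, seeds, window, barrier = NULL, connectivity = 6L) {
  v <- vol_data(volume)
  d <- dim(v)
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  if (is.logical(seeds) && !is.null(dim(seeds))) {
    check_mask(seeds, volume)
    idx0 <- which(seeds) - 1L
  } else {
    idx0 <- normalize_seeds(seeds, d)
  }
  if (length(idx0) == 0L) stop("no seed voxels")
  if (inherits(window, "intensity_window")) {
    lo <- window$lo; hi <- window$hi
  } else {
    lo <- window[1]; hi <- window[2]
  }
  sv <- v[idx0 + 1L]
  if (any(sv < lo | sv > hi)) stop("seed outside intensity window")
  if (!is.null(barrier)) {
    check_mask(barrier, volume)
    if (any(barrier[idx0 + 1L])) stop("seed inside barrier")
  }
  out <- .rg_flood(as.numeric(v), d, as.integer(idx0), lo, hi, barrier,
                   as.integer(connectivity))
  dim(out) <- d
  out
}

#' Connected components of a binary mask
#'
#' @param mask logical 3D array (a 2D matrix is treated as a single-slice
#'   volume).
#' @param connectivity 6 or 26.
#' @return list with `labels` (integer array, 0 = background) and `sizes`
#'   (voxel count per component id).
#' @export
connected_components <- function(mask, connectivity = 6L) {
  if (length(dim(mask)) == 2L) dim(mask) <- c(1L, dim(mask))
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  res <- .cc_label(mask, dim(mask), as.integer(connectivity))
  res
}

largest_component <- function(mask, connectivity = 6L) {
  cc <- connected_components(mask, connectivity)
  if (length(cc$sizes) == 0L) return(array(FALSE, dim(mask)))
  keep <- which.max(cc$sizes)
  out <- cc$labels == keep
  dim(out) <- dim(mask)
  out
}
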