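# Grid-level numeric helpers shared by the segmentation stages: Euclidean
# distance transforms, EDT-based morphology, hole filling, separable box
# filters and a per-slice Canny detector.

#' Euclidean distance to a mask
#'
#' Distance (mm) from every voxel centre to the nearest `TRUE` voxel of the
#' mask, honouring anisotropic spacing. `Inf` where the mask is empty.
#'
#' @param mask logical 3D array.
#' @param spacing_mm voxel spacing `(dz, dy, dx)`.
#' @return numeric array of distances in mm.
#' @export
distance_to_mask <- function(mask, spacing_mm = c(1, 1, 1)) {
  if (length(dim(mask)) == 2L) {
    dim(mask) <- c(1L, dim(mask))
    if (length(spacing_mm) == 2L) spacing_mm <- c(1, spacing_mm)
  }
  stopifnot(length(spacing_mm) == 3L)
  out <- .edt3d(mask, dim(mask), as.numeric(spacing_mm))
  dim(out) <- dim(mask)
  out
}

dilate_mm <- function(mask, r_mm, spacing_mm = c(1, 1, 1)) {
  if (r_mm <= 0 || !any(mask)) return(mask)
  distance_to_mask(mask, spacing_mm) <= r_mm
}

erode_mm <- function(mask, r_mm, spacing_mm = c(1, 1, 1)) {
  if (r_mm <= 0) return(mask)
  mask & !(distance_to_mask(!mask, spacing_mm) <= r_mm)
}

close_mm <- function(mask, r_mm, spacing_mm = c(1, 1, 1)) {
  erode_mm(dilate_mm(mask, r_mm, spacing_mm), r_mm, spacing_mm)
}

# Fill the 3D cavities of a mask: complement components not reachable from
# the volume border (6-connectivity).
fill_holes_3d <- function(mask) {
  d <- dim(mask)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  bseeds <- which(border & !mask) - 1L
  if (length(bseeds) == 0L) return(array(TRUE, d))
  outside <- .rg_flood(as.numeric(!mask), d, as.integer(bseeds), 1, 1, NULL, 6L)
  dim(outside) <- d
  mask | !outside
}

# Fill, per axial slice, the regions of !mask that do not touch the slice
# border (2D 4-connectivity).
fill_holes_slicewise <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (k in seq_len(d[1])) {
    sl <- mask[k, , ]
    if (!any(sl) || all(sl)) next
    inv <- !sl
    cc <- connected_components(inv, 6L)
    lab <- cc$labels
    dim(lab) <- dim(inv)
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border <- border[border > 0L]
    hole <- inv & !(lab %in% border)
    dim(hole) <- dim(inv)
    out[k, , ] <- sl | hole
  }
  out
}

# Running box sums of a 3D array via cumulative sums; half-width per axis in
# voxels (0 = no extension along that axis). Window clipped at the borders;
# returns list(sum, n) with the per-voxel window sums and voxel counts.
box_sums <- function(a, half) {
  d <- dim(a)
  n <- array(1, d)
  for (ax in 1:3) {
    h <- half[ax]
    if (h <= 0L) next
    a <- axis_box_sum(a, ax, h)
    n <- axis_box_sum(n, ax, h)
  }
  list(sum = a, n = n)
}

# Box sum along one axis using cumsum with border clipping.
axis_box_sum <- function(a, axis, h) {
  d <- dim(a)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  cs <- apply(m, 2, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = dp[1])
  nr <- dp[1]
  idx_hi <- pmin(seq_len(nr) + h, nr)
  idx_lo <- seq_len(nr) - h - 1L
  out <- cs[idx_hi, , drop = FALSE]
  pos <- idx_lo >= 1L
  if (any(pos)) out[pos, ] <- out[pos, , drop = FALSE] - cs[idx_lo[pos], , drop = FALSE]
  dim(out) <- dp
  aperm(out, order(perm))
}

# Local mean and population sd over a box window (half-widths in voxels).
box_mean_sd <- function(a, half) {
  s1 <- box_sums(a, half)
  s2 <- box_sums(a * a, half)
  mu <- s1$sum / s1$n
  varr <- pmax(s2$sum / s1$n - mu * mu, 0)
  list(mean = mu, sd = sqrt(varr), n = s1$n)
}

# --- per-slice Canny ------------------------------------------------------

gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Banded Toeplitz convolution matrix with replicated edges, so that
# convolution of a slice is two dense matrix products (fast via BLAS).
conv_matrix <- function(n, k) {
  r <- (length(k) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- i + seq(-r, r)
    js <- pmin(pmax(js, 1L), n)
    for (t in seq_along(js)) M[i, js[t]] <- M[i, js[t]] + k[t]
  }
  M
}

blur_slice <- function(m, sigma) {
  k <- gauss_kernel(sigma)
  Mr <- conv_matrix(nrow(m), k)
  Mc <- conv_matrix(ncol(m), k)
  Mr %*% m %*% t(Mc)
}

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

#' 2D Canny edge detection on a slice
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and hysteresis thresholding with thresholds
#' relative to the slice's maximum gradient magnitude (hence invariant to a
#' global intensity rescale).
#'
#' @param m numeric matrix (one slice).
#' @param sigma Gaussian smoothing sd in voxels.
#' @param lo_frac,hi_frac hysteresis thresholds as fractions of the maximum
#'   gradient magnitude.
#' @return logical matrix of edge pixels.
#' @export
canny_slice <- function(m, sigma = 1, lo_frac = 0.4, hi_frac = 0.8) {
  if (max(m) == min(m)) return(matrix(FALSE, nrow(m), ncol(m)))
  b <- blur_slice(m, sigma)
  # Sobel
  sx <- shift_mat(b, 0, 1) - shift_mat(b, 0, -1)
  gx <- (shift_mat(sx, -1, 0) + 2 * sx + shift_mat(sx, 1, 0))
  sy <- shift_mat(b, 1, 0) - shift_mat(b, -1, 0)
  gy <- (shift_mat(sy, 0, -1) + 2 * sy + shift_mat(sy, 0, 1))
  mag <- sqrt(gx * gx + gy * gy)
  mx <- max(mag)
  if (mx == 0) return(matrix(FALSE, nrow(m), ncol(m)))
  # non-maximum suppression: quantize direction into 4 sectors
  ang <- atan2(gy, gx)            # in (-pi, pi]
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  n1 <- mag; n2 <- mag
  for (s in 0:3) {
    d <- switch(s + 1L,
                c(0L, 1L),   # 0: horizontal gradient -> compare left/right
                c(1L, 1L),   # 45 degrees
                c(1L, 0L),   # vertical
                c(1L, -1L))  # 135 degrees
    sel <- sector == s
    n1[sel] <- shift_mat(mag, d[1], d[2])[sel]
    n2[sel] <- shift_mat(mag, -d[1], -d[2])[sel]
  }
  keep <- mag >= n1 & mag >= n2 & mag > 0
  strong <- keep & (mag >= hi_frac * mx)
  weak <- keep & (mag >= lo_frac * mx)
  if (!any(strong)) return(matrix(FALSE, nrow(m), ncol(m)))
  cc <- connected_components(weak, 26L)   # 8-connectivity in-plane
  lab <- cc$labels
  dim(lab) <- dim(weak)
  keep_ids <- unique(lab[strong])
  keep_ids <- keep_ids[keep_ids > 0L]
  out <- weak & (lab %in% keep_ids)
  dim(out) <- dim(weak)
  out
}
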