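# Air mask from sparse manual contours: rasterize and interpolate the
# contoured slices, estimate the MR statistics of air, and subtract the soft
# tissue enclosed in the contoured regions.

#' Interpolate sparse air contours across slices
#'
#' Contoured slices are rasterized exactly (even-odd rule, boundary
#' inclusive). Slices lying between two contoured slices are filled by
#' shape-based interpolation: the signed distance transforms of the two
#' bracketing rasterized masks are interpolated linearly along the slice
#' axis and thresholded at zero. Slices outside the contoured span stay
#' empty.
#'
#' @param contours a [contour_set].
#' @param frame the annotated [intensity_volume].
#' @return logical array: the interpolated air region of interest.
#' @export
interpolate_contours <- function(contours, frame) {
  d <- dim(vol_data(frame))
  sp <- vol_spacing(frame)
  roi <- array(FALSE, d)
  ks <- sort(unique(vapply(contours$contours, `[[`, 1L, "slice")))
  if (length(ks) == 0L) stop("contour set is empty")
  for (ct in contours$contours) {
    roi[ct$slice, , ] <- roi[ct$slice, , ] |
      rasterize_polygon(ct$vertices, d[2], d[3])
  }
  if (length(ks) > 1L) {
    sdist <- function(k) {
      m <- roi[k, , ]
      if (!any(m)) return(matrix(Inf, d[2], d[3]))
      din <- distance_to_mask(!m, sp[2:3])
      dout <- distance_to_mask(m, sp[2:3])
      dout - din            # negative inside
    }
    for (i in seq_len(length(ks) - 1L)) {
      k1 <- ks[i]; k2 <- ks[i + 1L]
      if (k2 - k1 < 2L) next
      s1 <- sdist(k1); s2 <- sdist(k2)
      for (k in (k1 + 1L):(k2 - 1L)) {
        w <- (k - k1) / (k2 - k1)
        roi[k, , ] <- ((1 - w) * s1 + w * s2) <= 0
      }
    }
  }
  roi
}

# Debias mean/sd measured on the darkest fraction `f` of a sample back to
# full-population values, assuming Gaussian truncation at the f-quantile:
# for X ~ N(mu, sigma) truncated to its lower f tail,
#   E = mu - sigma * phi(a)/f,  Var = sigma^2 * (1 - a*phi(a)/f - (phi(a)/f)^2)
# with a = qnorm(f).
truncated_debias <- function(m, s, f) {
  a <- qnorm(f)
  r <- dnorm(a) / f
  shrink <- 1 - a * r - r * r
  if (shrink <= 0) return(list(mean = m, sd = s))
  sigma <- s / sqrt(shrink)
  list(mean = m + sigma * r, sd = sigma)
}

#' Estimate MR statistics of air from a contoured region
#'
#' The contoured region encloses some soft tissue (mucosa, thin septa), so a
#' plain mean over the ROI overestimates the air level. Statistics are
#' computed over the darkest fraction of ROI voxels (default half) and
#' debiased to full-population mean/sd under a Gaussian truncation model, so
#' that the darkest-fraction restriction rejects bright tissue without
#' understating the air spread.
#'
#' @param volume the MR [intensity_volume].
#' @param air_roi logical array (interpolated contour region), non-empty.
#' @param fraction darkest fraction used for the statistics.
#' @return A [tissue_stats] (`n` is the number of voxels used).
#' @export
estimate_air_stats <- function(volume, air_roi, fraction = 0.5) {
  check_mask(air_roi, volume)
  v <- vol_data(volume)[air_roi]
  if (length(v) == 0L) stop("empty region")
  stopifnot(fraction > 0, fraction <= 1)
  nkeep <- max(1L, as.integer(ceiling(length(v) * fraction)))
  vs <- sort(v)[seq_len(nkeep)]
  m <- mean(vs)
  s <- sqrt(mean((vs - m)^2))
  if (fraction < 1 && s > 0) {
    db <- truncated_debias(m, s, fraction)
    m <- db$mean; s <- db$sd
  }
  tissue_stats(mean = m, sd = s, min = min(v), n = nkeep)
}

#' Build the air mask by subtracting enclosed soft tissue
#'
#' Keeps the ROI voxels whose intensity is at most
#' `mu_air + subtract_sigma * sigma_air`; brighter voxels inside the
#' contours are soft tissue and are excluded. The 3-sigma default mirrors
#' the skull-reference window used later in the pipeline.
#'
#' @param volume the MR [intensity_volume].
#' @param air_roi logical array from [interpolate_contours()].
#' @param air_stats a [tissue_stats] from [estimate_air_stats()].
#' @param subtract_sigma threshold multiplier.
#' @return logical air mask, always a subset of `air_roi`.
#' @export
build_air_mask <- function(volume, air_roi, air_stats, subtract_sigma = 3.0) {
  check_mask(air_roi, volume)
  thr <- air_stats$mean + subtract_sigma * air_stats$sd
  air_roi & (vol_data(volume) <= thr)
}
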