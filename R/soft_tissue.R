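# Residual soft-tissue classification (muscle / fat / contrast artifact)
# using per-slice statistics with adjacent-slice context, plus the external
# body contour.

#' External body contour
#'
#' MR: the largest connected component of voxels brighter than
#' `mu_air + air_sigma * sigma_air` (taking the largest component first
#' discards the isolated noise-floor speckle outside the head), then
#' morphological closing with a 3 mm ball and slice-wise hole filling.
#' CT: largest component of `HU > -400`, holes filled slice-wise.
#'
#' @param volume an [intensity_volume].
#' @param air_stats air statistics (required for MR).
#' @param air_sigma threshold multiplier for MR.
#' @param closing_mm closing radius for MR.
#' @return logical body mask.
#' @export
external_body_contour <- function(volume, air_stats = NULL, air_sigma = 3.0,
                                  closing_mm = 3.0) {
  v <- vol_data(volume)
  sp <- vol_spacing(volume)
  if (inherits(volume, "intensity_volume") && volume$modality == "CT") {
    m <- v > -400
  } else {
    if (is.null(air_stats)) stop("air_stats required for an MR body contour")
    m <- v > air_stats$mean + air_sigma * air_stats$sd
    if (!any(m)) stop("empty body")
    m <- close_mm(largest_component(m, 6L), closing_mm, sp)
  }
  if (!any(m)) stop("empty body")
  m <- largest_component(m, 6L)
  fill_holes_slicewise(m)
}

#' Per-slice soft-tissue statistics
#'
#' For each axial slice, mean and sd of the residual soft-tissue intensities
#' pooled over the slice and its adjacent slices (`context_slices` on each
#' side, clipped at the volume ends) — this absorbs the slow intensity drift
#' of the bias field along the scan axis. The global minimum over all
#' residual voxels (`min_soft`) is also returned. Slices whose context
#' contains no residual voxel copy the statistics of the nearest valid
#' slice.
#'
#' @param volume the MR [intensity_volume].
#' @param residual_soft logical mask: body minus air, bone, brain, CSF and
#'   eyes.
#' @param context_slices adjacent slices pooled on each side (default 1,
#'   i.e. a 3-slice context).
#' @return Object of class `soft_stats`: list with per-slice `mean`, `sd`,
#'   `n`, and the global `min`.
#' @export
per_slice_soft_stats <- function(volume, residual_soft, context_slices = 1L) {
  v <- vol_data(volume)
  d <- dim(v)
  check_mask(residual_soft, volume)
  if (!any(residual_soft)) stop("residual soft-tissue mask is empty")
  nz <- d[1]
  s1 <- s2 <- nn <- numeric(nz)
  for (k in seq_len(nz)) {
    sel <- residual_soft[k, , ]
    if (any(sel)) {
      x <- v[k, , ][sel]
      s1[k] <- sum(x); s2[k] <- sum(x * x); nn[k] <- length(x)
    }
  }
  mu <- sdv <- cnt <- numeric(nz)
  for (k in seq_len(nz)) {
    ks <- max(1L, k - context_slices):min(nz, k + context_slices)
    n <- sum(nn[ks])
    cnt[k] <- n
    if (n > 0) {
      m <- sum(s1[ks]) / n
      mu[k] <- m
      sdv[k] <- sqrt(max(sum(s2[ks]) / n - m * m, 0))
    } else {
      mu[k] <- NA_real_; sdv[k] <- NA_real_
    }
  }
  bad <- which(is.na(mu))
  if (length(bad) > 0L) {
    good <- which(!is.na(mu))
    if (length(good) == 0L) stop("no slice has residual soft-tissue voxels")
    for (k in bad) {
      nearest <- good[which.min(abs(good - k))]
      mu[k] <- mu[nearest]; sdv[k] <- sdv[nearest]
    }
    message(sprintf("%d slice(s) without residual voxels copied stats from the nearest valid slice",
                    length(bad)))
  }
  structure(list(mean = mu, sd = sdv, n = cnt,
                 min = min(v[residual_soft])),
            class = "soft_stats")
}

#' Classify residual soft tissue into muscle, fat and contrast
#'
#' Per voxel, using its slice's statistics: intensities up to `mu_soft` are
#' muscle, intensities in `(mu_soft, mu_soft + fat_sigma * sigma_soft]` are
#' fat, anything brighter is contrast artifact. The three classes partition
#' the residual mask exactly (the boundary `I = mu_soft` belongs to muscle).
#'
#' @param volume the MR [intensity_volume].
#' @param residual_soft residual soft-tissue mask.
#' @param slice_stats a `soft_stats` from [per_slice_soft_stats()].
#' @param fat_sigma upper fat bound multiplier.
#' @return integer array: 0 outside the residual, otherwise
#'   `SCT_LABELS["MUSCLE"|"FAT"|"CONTRAST"]`.
#' @export
classify_soft_tissue <- function(volume, residual_soft, slice_stats,
                                 fat_sigma = 2.0) {
  v <- vol_data(volume)
  d <- dim(v)
  check_mask(residual_soft, volume)
  kidx <- rep(seq_len(d[1]), times = d[2] * d[3])
  mu <- slice_stats$mean[kidx]
  up <- mu + fat_sigma * slice_stats$sd[kidx]
  out <- array(0L, d)
  sel <- residual_soft
  out[sel & (v <= mu)] <- SCT_LABELS[["MUSCLE"]]
  out[sel & (v > mu) & (v <= up)] <- SCT_LABELS[["FAT"]]
  out[sel & (v > up)] <- SCT_LABELS[["CONTRAST"]]
  out
}
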