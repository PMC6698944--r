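# Bone segmentation: cortical bone shares the air intensity range and is
# grown from the skull reference seeds; trabecular (spongy) bone overlaps
# brain and fat in MR intensity and is recovered from the diploe enclosed in
# the cortical mask plus a local neighbourhood search.

#' Cortical bone segmentation
#'
#' Region growing from the skull reference voxels (dark voxels within the
#' body rim, as used for the skull mask) with the air-like window
#' `[0, mu_air + air_sigma * sigma_air]`, constrained to the body and kept
#' out of the contoured air mask (air takes precedence over bone).
#'
#' @param volume the MR [intensity_volume].
#' @param skull_mask skull mask from [build_skull_mask()] (its `"seeds"`
#'   attribute is reused when present).
#' @param air_mask contoured air mask.
#' @param air_stats air statistics.
#' @param body body mask.
#' @param air_sigma window multiplier.
#' @param rim_mm seed search depth from the body surface.
#' @return logical cortical bone mask.
#' @export
segment_cortical_bone <- function(volume, skull_mask, air_mask, air_stats,
                                  body, air_sigma = 3.0, rim_mm = 10) {
  v <- vol_data(volume)
  seeds <- attr(skull_mask, "seeds")
  if (is.null(seeds))
    seeds <- skull_seed_mask(volume, body, air_stats, rim_mm, air_sigma)
  barrier <- !body
  if (!is.null(air_mask)) barrier <- barrier | air_mask
  win <- c(0, air_stats$mean + air_sigma * air_stats$sd)
  seeds <- seeds & !barrier
  iv <- v[seeds]
  seeds[seeds] <- iv >= win[1] & iv <= win[2]
  if (!any(seeds)) stop("no skull seed voxels")
  region_grow(volume, seeds, win, barrier = barrier, connectivity = 6L)
}

#' Trabecular bone reference statistics
#'
#' The diploe enclosed in the cortical mask provides reference trabecular
#' voxels: non-cortical voxels that cannot be reached from the volume border
#' without crossing cortical bone. The cortical mask is sealed with a small
#' morphological closing first, so that single-voxel noise pinholes in the
#' thin tables do not let the outside flood into the diploe; real openings
#' (orbits, foramina) are far wider than the sealing radius. Voxels already
#' assigned to other tissues (brain, CSF, eyes, air) are excluded from the
#' reference set.
#'
#' @param volume the MR [intensity_volume].
#' @param cortical cortical bone mask.
#' @param exclude optional mask of already-labelled voxels.
#' @param seal_mm closing radius used to seal pinholes.
#' @return A [tissue_stats] with the reference mask attached as attribute
#'   `"mask"`.
#' @export
estimate_trabecular_stats <- function(volume, cortical, exclude = NULL,
                                      seal_mm = 2) {
  v <- vol_data(volume)
  d <- dim(v)
  check_mask(cortical, volume)
  sealed <- close_mm(cortical, seal_mm, vol_spacing(volume))
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  bseeds <- which(border & !sealed) - 1L
  outside <- .rg_flood(as.numeric(!sealed), d, as.integer(bseeds),
                       1, 1, NULL, 6L)
  dim(outside) <- d
  enclosed <- !sealed & !outside
  if (!is.null(exclude)) enclosed <- enclosed & !exclude
  if (!any(enclosed)) stop("no trabecular reference")
  # the enclosed set carries a minority of partial-volume and misassigned
  # voxels (dark CSF remnants, bright cortical noise); trim around the
  # median before taking mean/sd so the reference reflects the diploe
  x <- v[enclosed]
  med <- median(x)
  madn <- 1.4826 * median(abs(x - med))
  keep <- abs(x - med) <= 3 * madn
  xs <- x[keep]
  m <- mean(xs)
  st <- tissue_stats(mean = m, sd = sqrt(mean((xs - m)^2)),
                     min = min(xs), n = length(xs))
  refm <- enclosed
  refm[enclosed] <- keep
  attr(st, "mask") <- refm
  st
}

#' Recover trabecular bone near cortical bone
#'
#' Trabecular bone not fully enclosed by cortical bone (thin tables,
#' partial volume) is recovered by searching a small neighbourhood around
#' cortical voxels for intensities within
#' `[mu_trab - 2 sigma_trab, mu_trab + 2 sigma_trab]`, skipping voxels
#' already labelled brain/CSF/eye/air. The enclosed reference voxels are
#' part of the result.
#'
#' @param volume the MR [intensity_volume].
#' @param cortical cortical bone mask.
#' @param trab_stats statistics from [estimate_trabecular_stats()].
#' @param neighborhood_mm search distance from cortical bone.
#' @param exclude optional mask of already-labelled voxels.
#' @param trab_sigma window multiplier.
#' @return logical trabecular bone mask (disjoint from cortical).
#' @export
recover_trabecular_bone <- function(volume, cortical, trab_stats,
                                    neighborhood_mm = 5, exclude = NULL,
                                    trab_sigma = 2.0) {
  v <- vol_data(volume)
  sp <- vol_spacing(volume)
  near <- distance_to_mask(cortical, sp) <= neighborhood_mm
  lo <- trab_stats$mean - trab_sigma * trab_stats$sd
  hi <- trab_stats$mean + trab_sigma * trab_stats$sd
  out <- near & !cortical & (v >= lo) & (v <= hi)
  if (!is.null(exclude)) out <- out & !exclude
  refm <- attr(trab_stats, "mask")
  if (!is.null(refm)) out <- out | (refm & !cortical & !(if (is.null(exclude)) FALSE else exclude))
  dim(out) <- dim(v)
  out
}
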