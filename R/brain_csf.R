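# Automated brain and CSF segmentation: white-matter reference search,
# per-patient brain intensity windows, edge detection with gap closing,
# initial brain growing, CSF statistics and growing, skull mask, final
# brain. All intensity thresholds are relative to patient-specific
# statistics (wmIntensity, air and CSF stats), which makes every mask
# invariant to a global rescale of the MR intensities.

#' White-matter reference search
#'
#' Scans the middle coronal slice for the voxel whose 1 cm x 1 cm in-plane
#' neighbourhood has the largest intensity uniformity (mean/sd). Candidates
#' are restricted to body voxels brighter than the slice median (air and CSF
#' are also highly uniform; the brain reference must not land there). The
#' window mean at the winning voxel is the reference brain intensity
#' `wmIntensity`; ties on uniformity are broken by the larger window mean,
#' then the lowest voxel index.
#'
#' @param volume the MR [intensity_volume].
#' @param body logical body mask (see [external_body_contour()]).
#' @param stat_lo,stat_hi statistical brain window coefficients (defaults
#'   0.53 and 1.35 times `wmIntensity`).
#' @param grow_lo,grow_hi initial growing window coefficients (defaults 0.7
#'   and 1.2).
#' @param window_mm in-plane uniformity window extent.
#' @return Object of class `brain_reference` with fields `wm_voxel`
#'   (`(k, row, col)`), `wmIntensity`, `window_stat`, `window_grow`.
#' @export
find_wm_reference <- function(volume, body,
                              stat_lo = 0.53, stat_hi = 1.35,
                              grow_lo = 0.7, grow_hi = 1.2,
                              window_mm = 10) {
  v <- vol_data(volume)
  d <- dim(v)
  sp <- vol_spacing(volume)
  check_mask(body, volume)
  r0 <- as.integer(round(d[2] / 2))
  sl <- v[, r0, ]                       # (z, x) plane
  bd <- body[, r0, ]
  if (!any(bd)) stop("body mask empty on the middle coronal slice")
  med <- median(sl[bd])
  cand <- bd & (sl > med)
  if (!any(cand)) stop("no candidate voxels for the white-matter search")
  half <- (mm_to_voxels(c(window_mm, window_mm), sp[c(1, 3)]) - 1L) %/% 2L
  a3 <- array(sl, c(d[1], d[3], 1L))
  bm <- box_mean_sd(a3, c(half[1], half[2], 0L))
  mu <- bm$mean[, , 1]
  sdv <- bm$sd[, , 1]
  U <- ifelse(sdv == 0, Inf, mu / sdv)
  U[!cand] <- -Inf
  best <- order(-U, -mu, seq_along(U))[1]
  if (!is.finite(U[best]) && U[best] == -Inf) stop("no candidate voxels")
  kz <- (best - 1L) %% d[1] + 1L
  kx <- (best - 1L) %/% d[1] + 1L
  wm <- mu[best]
  if (wm <= 0) stop("non-positive white-matter reference intensity")
  structure(list(
    wm_voxel = c(kz, r0, kx),
    wmIntensity = wm,
    window_stat = intensity_window(stat_lo * wm, stat_hi * wm),
    window_grow = intensity_window(grow_lo * wm, grow_hi * wm)
  ), class = "brain_reference")
}

#' @export
print.brain_reference <- function(x, ...) {
  cat(sprintf("<brain_reference> wmIntensity %.4g at voxel (%d, %d, %d)\n",
              x$wmIntensity, x$wm_voxel[1], x$wm_voxel[2], x$wm_voxel[3]))
  cat(sprintf("  stat window [%.4g, %.4g]  grow window [%.4g, %.4g]\n",
              x$window_stat$lo, x$window_stat$hi,
              x$window_grow$lo, x$window_grow$hi))
  invisible(x)
}

bresenham2 <- function(p, q) {
  # integer points on the discrete segment p -> q (inclusive), 2D
  dr <- q[1] - p[1]; dc <- q[2] - p[2]
  n <- max(abs(dr), abs(dc))
  if (n == 0L) return(matrix(p, 1L, 2L))
  t <- seq(0, 1, length.out = n + 1L)
  cbind(round(p[1] + t * dr), round(p[2] + t * dc))
}

# Close gaps wider than one voxel in a planar edge curve: take the largest
# 8-connected component, order its pixels by angle around the component
# centroid and bridge any consecutive pair further than one voxel
# (Chebyshev) apart with the discrete straight segment between them.
close_contour_gaps <- function(edge2d) {
  if (!any(edge2d)) return(edge2d)
  comp <- largest_component(edge2d, 26L)
  dim(comp) <- dim(edge2d)
  idx <- which(comp)
  if (length(idx) < 3L) return(edge2d)
  nr <- nrow(edge2d)
  pr <- (idx - 1L) %% nr + 1L
  pc <- (idx - 1L) %/% nr + 1L
  ang <- atan2(pr - mean(pr), pc - mean(pc))
  o <- order(ang)
  pr <- pr[o]; pc <- pc[o]
  out <- edge2d
  n <- length(pr)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (max(abs(pr[j] - pr[i]), abs(pc[j] - pc[i])) > 1L) {
      seg <- bresenham2(c(pr[i], pc[i]), c(pr[j], pc[j]))
      out[seg] <- TRUE
    }
  }
  out
}

#' Edge detection with gap closing
#'
#' Zeroes all intensities outside the statistical brain window, runs 2D
#' Canny edge detection on every axial and every sagittal slice and takes
#' the union. Per axial slice, the largest edge curve is then traced and any
#' gap wider than one voxel between consecutive boundary pixels is bridged
#' by the discrete straight segment between them, so region growing cannot
#' leak through broken boundaries (the edge voxels act as barriers).
#'
#' @param volume the MR [intensity_volume].
#' @param ref a [find_wm_reference()] result.
#' @param sigma Canny Gaussian sd (voxels).
#' @param lo_frac,hi_frac Canny hysteresis fractions of the maximum slice
#'   gradient.
#' @return logical array of edge voxels.
#' @export
detect_and_close_edges <- function(volume, ref, sigma = 1,
                                   lo_frac = 0.4, hi_frac = 0.8) {
  v <- vol_data(volume)
  d <- dim(v)
  w <- v
  w[w < ref$window_stat$lo | w > ref$window_stat$hi] <- 0
  edges <- array(FALSE, d)
  for (k in seq_len(d[1])) {
    sl <- w[k, , ]; dim(sl) <- d[2:3]
    if (any(sl > 0)) edges[k, , ] <- canny_slice(sl, sigma, lo_frac, hi_frac)
  }
  for (x in seq_len(d[3])) {
    sl <- w[, , x]; dim(sl) <- d[1:2]
    ex <- edges[, , x]; dim(ex) <- d[1:2]
    if (any(sl > 0)) edges[, , x] <- ex | canny_slice(sl, sigma, lo_frac, hi_frac)
  }
  for (k in seq_len(d[1])) {
    ek <- edges[k, , ]; dim(ek) <- d[2:3]
    if (any(ek)) edges[k, , ] <- close_contour_gaps(ek)
  }
  edges
}

#' Initial brain segmentation
#'
#' 3D region growing from the white-matter reference voxel with the growing
#' window (default `[0.7, 1.2] * wmIntensity`, closed interval), blocked by
#' the detected edges. Captures the high-uniformity white-matter core.
#'
#' @param volume the MR [intensity_volume].
#' @param ref a `brain_reference`.
#' @param edges edge voxels from [detect_and_close_edges()] (barrier).
#' @return logical array (initial brain).
#' @export
segment_brain_initial <- function(volume, ref, edges = NULL) {
  v <- vol_data(volume)
  seed <- ref$wm_voxel
  iv <- v[seed[1], seed[2], seed[3]]
  if (iv < ref$window_grow$lo || iv > ref$window_grow$hi)
    stop("seed outside intensity window")
  barrier <- edges
  if (!is.null(barrier) && barrier[seed[1], seed[2], seed[3]]) {
    barrier <- barrier
    barrier[seed[1], seed[2], seed[3]] <- FALSE
  }
  region_grow(volume, matrix(seed, 1L), ref$window_grow, barrier = barrier,
              connectivity = 6L)
}

#' CSF reference statistics
#'
#' Searches 3D windows (default 5 mm x 5 mm x 5 mm) lying fully inside the
#' initial segmented brain region (after filling its interior holes — the
#' ventricles are cavities of the white-matter core, which is where the
#' search must look), whose centre voxel is darker than the lower
#' statistical brain bound (`0.53 * wmIntensity`), and picks the window
#' with the largest uniformity (ties: larger mean, then lowest index).
#' Returns the mean/sd over the winning window; the window voxels serve as
#' the CSF growing seeds.
#'
#' @param volume the MR [intensity_volume].
#' @param brain0 initial brain mask.
#' @param ref a `brain_reference`.
#' @param window_mm window extent in mm.
#' @return A [tissue_stats] with extra fields `center` (voxel index) and
#'   `seed_mask` (logical array of the window voxels).
#' @export
find_csf_reference <- function(volume, brain0, ref, window_mm = 5) {
  v <- vol_data(volume)
  d <- dim(v)
  sp <- vol_spacing(volume)
  check_mask(brain0, volume)
  if (!any(brain0)) stop("initial brain mask is empty")
  half <- (mm_to_voxels(rep(window_mm, 3L), sp) - 1L) %/% 2L
  # search region: the initial brain with its internal CSF spaces closed --
  # morphological closing at the window scale seals the narrow outlets of
  # the ventricles before the cavities are filled
  region <- fill_holes_3d(close_mm(brain0, window_mm, sp))
  thr <- ref$window_stat$lo
  bm <- box_mean_sd(v, half)
  # window fully inside the filled brain: the box sum of the region
  # indicator must equal the (clipped) box size
  rs <- box_sums(region * 1.0, half)
  cand <- region & (rs$sum == rs$n) & (v < thr)
  if (!any(cand)) stop("no CSF reference found")
  U <- ifelse(bm$sd == 0, Inf, bm$mean / bm$sd)
  U[!cand] <- -Inf
  best <- order(-as.vector(U), -as.vector(bm$mean), seq_along(U))[1]
  ctr <- arrayInd(best, d)[1, ]
  wlo <- ctr - half; whi <- ctr + half
  wvox <- v[wlo[1]:whi[1], wlo[2]:whi[2], wlo[3]:whi[3]]
  m <- mean(wvox)
  s <- sqrt(mean((wvox - m)^2))
  st <- tissue_stats(mean = m, sd = s, min = min(wvox), n = length(wvox))
  seed_mask <- array(FALSE, d)
  seed_mask[wlo[1]:whi[1], wlo[2]:whi[2], wlo[3]:whi[3]] <- TRUE
  st$center <- as.integer(ctr)
  st$seed_mask <- seed_mask
  st
}

# Skull reference seeds: dark voxels within `rim_mm` of the external body
# surface (geodesic depth measured from outside the body).
skull_seed_mask <- function(volume, body, air_stats, rim_mm = 10,
                            air_sigma = 3.0) {
  v <- vol_data(volume)
  depth <- distance_to_mask(!body, vol_spacing(volume))
  body & (depth <= rim_mm) & (v <= air_stats$mean + air_sigma * air_stats$sd)
}

#' Skull mask
#'
#' Seeds are dark voxels (intensity at most `mu_air + 3 sigma_air`) within
#' 1 cm of the external body contour; they are grown with the window
#' `[0, mu_csf + 2 sigma_csf]`, excluded from the initial brain, the CSF,
#' and the edge voxels. Because the subarachnoid CSF lies inside that
#' window and touches the inner skull table, a provisional CSF mask (grown
#' from the CSF reference without the skull constraint) is part of the
#' barrier. Finally every soft-tissue voxel external to the skull relative
#' to the brain is added: with the grown skull removed, any voxel not in
#' the connected component containing the initial brain cannot be reached
#' from the brain without crossing the skull, and joins the mask. The
#' result is an exclusion zone for the final brain and CSF growing, not a
#' bone label.
#'
#' @param volume the MR [intensity_volume].
#' @param body body mask.
#' @param brain0 initial brain mask.
#' @param csf_stats CSF reference from [find_csf_reference()].
#' @param air_stats air statistics.
#' @param edges edge voxels.
#' @param air_mask optional air mask (kept out of the skull).
#' @param rim_mm seed search depth from the body surface.
#' @param air_sigma,csf_sigma window multipliers.
#' @return logical skull mask, with the seed mask attached as attribute
#'   `"seeds"`.
#' @export
build_skull_mask <- function(volume, body, brain0, csf_stats, air_stats,
                             edges, air_mask = NULL, rim_mm = 10,
                             air_sigma = 3.0, csf_sigma = 2.0) {
  v <- vol_data(volume)
  d <- dim(v)
  seeds <- skull_seed_mask(volume, body, air_stats, rim_mm, air_sigma)
  if (!is.null(air_mask)) seeds <- seeds & !air_mask
  if (!any(seeds)) stop("no skull seed voxels")
  csf_prov <- NULL
  if (!is.null(csf_stats$seed_mask)) {
    wl <- c(csf_stats$mean - csf_sigma * csf_stats$sd,
            csf_stats$mean + csf_sigma * csf_stats$sd)
    bar0 <- brain0 | edges
    csf_seeds <- csf_stats$seed_mask & !bar0
    iv <- v[csf_seeds]
    csf_seeds[csf_seeds] <- iv >= wl[1] & iv <= wl[2]
    if (any(csf_seeds))
      csf_prov <- region_grow(volume, csf_seeds, wl, barrier = bar0,
                              connectivity = 6L)
  }
  barrier <- brain0 | edges
  if (!is.null(csf_prov)) barrier <- barrier | csf_prov
  if (!is.null(air_mask)) barrier <- barrier | air_mask
  win <- c(0, csf_stats$mean + csf_sigma * csf_stats$sd)
  gseeds <- seeds & !barrier
  iv <- v[gseeds]
  gseeds[gseeds] <- iv >= win[1] & iv <= win[2]
  if (!any(gseeds)) stop("no skull seed voxels")
  grown <- region_grow(volume, gseeds, win, barrier = barrier,
                       connectivity = 6L)
  # add everything lying outside the skull relative to the brain: voxels
  # that cannot be reached from the brain without crossing the grown skull
  interior <- .rg_flood(as.numeric(!grown), d, as.integer(which(brain0) - 1L),
                        1, 1, NULL, 6L)
  dim(interior) <- d
  cand <- body & !brain0 & !grown & !interior
  if (!is.null(csf_prov)) cand <- cand & !csf_prov
  if (!is.null(air_mask)) cand <- cand & !air_mask
  out <- grown | cand
  attr(out, "seeds") <- seeds
  out
}

#' CSF segmentation
#'
#' Region growing from the CSF reference voxels with the window
#' `[mu_csf - 2 sigma_csf, mu_csf + 2 sigma_csf]`, constrained by the skull
#' mask. Reaches the ventricles, the subarachnoid space around the brain
#' and the spinal canal when connected.
#'
#' @param volume the MR [intensity_volume].
#' @param csf_stats CSF reference (with `seed_mask`) or plain
#'   [tissue_stats] plus explicit `seeds`.
#' @param skull_mask skull exclusion mask (barrier).
#' @param seeds optional explicit seed mask or n x 3 index matrix
#'   (overrides `csf_stats$seed_mask`).
#' @param csf_sigma window multiplier.
#' @return logical CSF mask.
#' @export
segment_csf <- function(volume, csf_stats, skull_mask, seeds = NULL,
                        csf_sigma = 2.0) {
  if (is.null(seeds)) seeds <- csf_stats$seed_mask
  if (is.null(seeds)) stop("no CSF seeds supplied")
  if (!is.logical(seeds)) {
    sm <- array(FALSE, dim(vol_data(volume)))
    sm[normalize_seeds(seeds, dim(vol_data(volume))) + 1L] <- TRUE
    seeds <- sm
  }
  if (any(seeds & skull_mask)) stop("seed in skull mask")
  wl <- c(csf_stats$mean - csf_sigma * csf_stats$sd,
          csf_stats$mean + csf_sigma * csf_stats$sd)
  v <- vol_data(volume)
  iv <- v[seeds]
  seeds[seeds] <- iv >= wl[1] & iv <= wl[2]
  if (!any(seeds)) stop("seed outside intensity window")
  region_grow(volume, seeds, wl, barrier = skull_mask, connectivity = 6L)
}

#' Final brain segmentation
#'
#' Adds the brain voxels (gray matter in sulci and grooves) connected to the
#' initial brain within the statistical brain window
#' (`[0.53, 1.35] * wmIntensity`) that do not fall inside the skull mask.
#' The result always contains the initial brain and never overlaps the CSF
#' or the skull mask.
#'
#' @param volume the MR [intensity_volume].
#' @param ref a `brain_reference`.
#' @param brain0 initial brain mask.
#' @param csf CSF mask.
#' @param skull_mask skull exclusion mask.
#' @return logical final brain mask.
#' @export
segment_brain_final <- function(volume, ref, brain0, csf, skull_mask) {
  seeds <- brain0 & !skull_mask
  v <- vol_data(volume)
  iv <- v[seeds]
  seeds[seeds] <- iv >= ref$window_stat$lo & iv <= ref$window_stat$hi
  grown <- if (any(seeds))
    region_grow(volume, seeds, ref$window_stat, barrier = skull_mask,
                connectivity = 6L)
  else array(FALSE, dim(v))
  (grown | brain0) & !csf & !skull_mask
}
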