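# Eye detection by intensity, location, size and sphericity rules.

#' Segment the left and right eyes
#'
#' Eyes are darker than brain in contrast-enhanced T1 images, sit in the
#' anterior hemisphere of the head and are roughly spherical. The search box
#' spans from 5 cm superior to 7 cm inferior of the brain slice with the
#' largest anterior-posterior width, anterior of the brain's centroid
#' plane. Connected components of voxels darker than
#' `threshold_coeff * wmIntensity` are filtered: a component is rejected
#' when it touches the mid-sagittal slab of the brain (3 voxels thick),
#' when its volume is below half or above twice the volume of a sphere of
#' `diameter_cm` (the default volume-based size rule; set
#' `size_rule = "diameter"` to compare the largest extent to half/twice the
#' diameter instead), or when the maximum pairwise difference of its three
#' axis-aligned extents exceeds `sphericity_cm` (not spherical). Survivors
#' are labelled left/right by their position relative to the brain midline.
#'
#' @param volume the MR [intensity_volume].
#' @param brain final (or initial) brain mask, non-empty.
#' @param ref a `brain_reference`.
#' @param exclude optional mask of voxels already assigned to other tissues
#'   (air, brain, CSF); excluded from the candidate threshold mask so that
#'   detected eyes never intersect them.
#' @param threshold_coeff,diameter_cm,box_sup_cm,box_inf_cm,sphericity_cm
#'   tuning parameters (defaults are the intended clinical values).
#' @param size_rule `"volume"` or `"diameter"`.
#' @return list with `mask` (logical array, both eyes) and `components`
#'   (data.frame with side, voxel count, centroid and extents).
#' @export
segment_eyes <- function(volume, brain, ref, exclude = NULL,
                         threshold_coeff = 0.7, diameter_cm = 4.0,
                         box_sup_cm = 5, box_inf_cm = 7,
                         sphericity_cm = 1.0,
                         size_rule = c("volume", "diameter")) {
  size_rule <- match.arg(size_rule)
  v <- vol_data(volume)
  d <- dim(v)
  sp <- vol_spacing(volume)
  check_mask(brain, volume)
  if (!any(brain)) stop("brain mask is empty")
  bidx <- which(brain, arr.ind = TRUE)
  # axial brain slice with the largest anterior-posterior width
  ap_width <- vapply(seq_len(d[1]), function(k) {
    r <- bidx[bidx[, 1] == k, 2]
    if (length(r) == 0L) 0 else (max(r) - min(r) + 1) * sp[2]
  }, 0.0)
  k_ref <- which.max(ap_width)
  k_lo <- max(1L, k_ref - as.integer(round(box_inf_cm * 10 / sp[1])))
  k_hi <- min(d[1], k_ref + as.integer(round(box_sup_cm * 10 / sp[1])))
  mid_row <- mean(bidx[, 2])
  mid_col <- mean(bidx[, 3])
  box <- array(FALSE, d)
  rows_ant <- seq_len(d[2]) > mid_row     # anterior hemisphere
  box[k_lo:k_hi, rows_ant, ] <- TRUE
  thr <- threshold_coeff * ref$wmIntensity
  cand <- box & (v < thr)
  if (!is.null(exclude)) cand <- cand & !exclude
  empty <- list(mask = array(FALSE, d),
                components = data.frame(side = character(), n_voxels = integer(),
                                        k = double(), row = double(), col = double()))
  if (!any(cand)) {
    warning("no eye candidates found")
    return(empty)
  }
  cc <- connected_components(cand, 6L)
  lab <- cc$labels
  dim(lab) <- d
  eye_vol_mm3 <- (4 / 3) * pi * (diameter_cm * 10 / 2)^3
  vox_mm3 <- prod(sp)
  # per-component geometry in one vectorized pass over the foreground
  idx <- which(cand)
  lb <- lab[idx]
  zi <- (idx - 1L) %% d[1] + 1L
  rest <- (idx - 1L) %/% d[1]
  yi <- rest %% d[2] + 1L
  xi <- rest %/% d[2] + 1L
  lbf <- factor(lb, levels = seq_along(cc$sizes))
  rng <- function(v) cbind(tapply(v, lbf, min), tapply(v, lbf, max))
  ez <- rng(zi); ey <- rng(yi); ex <- rng(xi)
  ext_z <- (ez[, 2] - ez[, 1] + 1) * sp[1]
  ext_y <- (ey[, 2] - ey[, 1] + 1) * sp[2]
  ext_x <- (ex[, 2] - ex[, 1] + 1) * sp[3]
  ext_max <- pmax(ext_z, ext_y, ext_x)
  ext_min <- pmin(ext_z, ext_y, ext_x)
  touches_mid <- as.logical(tapply(abs(xi - mid_col) <= 1, lbf, any))
  cz <- tapply(zi, lbf, mean); cy <- tapply(yi, lbf, mean); cx <- tapply(xi, lbf, mean)
  ok <- !touches_mid
  if (size_rule == "volume") {
    volm <- cc$sizes * vox_mm3
    ok <- ok & volm >= 0.5 * eye_vol_mm3 & volm <= 2 * eye_vol_mm3
  } else {
    ok <- ok & ext_max >= 0.5 * diameter_cm * 10 & ext_max <= 2 * diameter_cm * 10
  }
  ok <- ok & (ext_max - ext_min) <= sphericity_cm * 10
  keep <- lapply(which(ok), function(id)
    list(id = id, n = cc$sizes[id],
         centroid = c(cz[id], cy[id], cx[id]),
         ext_spread = ext_max[id] - ext_min[id]))
  if (length(keep) == 0L) {
    warning("no eye components survived the filters")
    return(empty)
  }
  if (length(keep) > 2L) {
    warning("more than two eye candidates; keeping the two most spherical")
    keep <- keep[order(vapply(keep, `[[`, 0.0, "ext_spread"))[1:2]]
  }
  mask <- array(FALSE, d)
  comp <- do.call(rbind, lapply(keep, function(kp) {
    mask[lab == kp$id] <<- TRUE
    data.frame(side = if (kp$centroid[3] > mid_col) "left" else "right",
               n_voxels = as.integer(kp$n),
               k = kp$centroid[1], row = kp$centroid[2], col = kp$centroid[3])
  }))
  dim(mask) <- d
  list(mask = mask, components = comp)
}
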