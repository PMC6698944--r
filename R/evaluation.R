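# Evaluation of a synthetic CT against a co-registered CT: external bone
# contour distance on the widest slices, Dice similarity, and mean /
# mean-absolute HU error by region.

#' Dice similarity coefficient
#'
#' `2 |A n B| / (|A| + |B|)`; two empty masks are defined as identical
#' (DSC 1).
#'
#' @param mask_a,mask_b logical arrays of the same shape.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) stop("shape mismatch")
  sa <- sum(mask_a); sb <- sum(mask_b)
  if (sa + sb == 0) return(1.0)
  2 * sum(mask_a & mask_b) / (sa + sb)
}

#' Mean and mean absolute HU error over a region
#'
#' `ME = mean(CT - sCT)`, `MAE = mean |CT - sCT|` over the region voxels
#' (CT is the ground truth, so a positive ME means the sCT underestimates).
#'
#' @param sct,ct [intensity_volume]s (HU) on a common grid.
#' @param region non-empty logical array.
#' @return named numeric vector `c(ME = ..., MAE = ...)`, in HU.
#' @export
ed_errors <- function(sct, ct, region) {
  a <- vol_data(sct); b <- vol_data(ct)
  if (!identical(dim(a), dim(b))) stop("volumes must share a grid")
  if (!identical(dim(region), dim(a))) stop("region shape mismatch")
  if (!any(region)) stop("empty region")
  diffs <- b[region] - a[region]
  c(ME = mean(diffs), MAE = mean(abs(diffs)))
}

#' Evaluation regions from an sCT / CT pair
#'
#' `whole_body`: overlap of the two external body contours (HU > -400,
#' holes filled). `air`: voxels below -800 HU in both volumes (air moves
#' between scans, so only agreed air is compared). `soft_tissue`: CT HU in
#' `[-100, 200)` inside the whole body. `bone`: CT HU >= 200 (the 200 HU
#' boundary belongs to bone). When a label map is supplied, a mask per
#' labelled tissue (from the sCT segmentation) is added under
#' `tissue_<name>`.
#'
#' @param sct,ct [intensity_volume]s (HU) on a common grid.
#' @param labels optional [label_volume] from the sCT pipeline.
#' @return named list of logical arrays.
#' @export
build_eval_regions <- function(sct, ct, labels = NULL) {
  a <- vol_data(sct); b <- vol_data(ct)
  if (!identical(dim(a), dim(b))) stop("volumes must share a grid")
  body_s <- fill_holes_slicewise(largest_component(a > -400, 6L))
  body_c <- fill_holes_slicewise(largest_component(b > -400, 6L))
  whole_body <- body_s & body_c
  if (!any(whole_body)) stop("empty whole-body overlap")
  out <- list(
    whole_body = whole_body,
    air = (a < -800) & (b < -800),
    soft_tissue = whole_body & (b >= -100) & (b < 200),
    bone = b >= 200
  )
  if (!is.null(labels)) {
    lab <- if (inherits(labels, "label_volume")) labels$labels else labels
    for (nm in names(SCT_LABELS)) {
      code <- SCT_LABELS[[nm]]
      if (code == 0L) next
      m <- lab == code
      if (any(m)) out[[paste0("tissue_", tolower(nm))]] <- m
    }
  }
  out
}

# 2D boundary of a mask: 4-neighbour erosion with replicated edges, so that
# voxels at the image border are not spuriously boundary.
boundary_2d <- function(m) {
  er <- m & shift_mat(m, 1, 0) & shift_mat(m, -1, 0) &
    shift_mat(m, 0, 1) & shift_mat(m, 0, -1)
  m & !er
}

fill_holes_2d <- function(m) {
  inv <- !m
  cc <- connected_components(inv, 6L)
  lab <- cc$labels
  dim(lab) <- dim(m)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  out <- m | (inv & !array(lab %in% border, dim(m)))
  dim(out) <- dim(m)
  out
}

# External contour of the bone mask in one slice: boundary of the largest
# bone component after hole filling. Returns an n x 2 coordinate matrix.
external_contour_2d <- function(bone2d) {
  comp <- largest_component(bone2d, 26L)
  dim(comp) <- dim(bone2d)
  if (!any(comp)) return(NULL)
  b <- boundary_2d(fill_holes_2d(comp))
  w <- which(b, arr.ind = TRUE)
  if (nrow(w) == 0L) NULL else w
}

#' External bone contour distance between sCT and CT
#'
#' Bone is thresholded at 200 HU in both volumes. For each of the axial,
#' coronal and sagittal orientations, the slice with the largest in-plane
#' width of the sCT bone mask (extent along the view's horizontal axis) is
#' selected; on that slice the external contour (outer boundary of the
#' largest bone component) is extracted in both volumes, and for every sCT
#' contour voxel the shortest Euclidean distance (mm) to the CT contour is
#' recorded. The measure is directed (sCT to CT), as clinically reported.
#'
#' @param sct,ct [intensity_volume]s (HU). If the grids differ, the CT is
#'   resampled to the sCT grid by nearest neighbour.
#' @param threshold_hu bone threshold.
#' @return list with `per_view` (named mean distances, mm), `mean` (average
#'   over the views), and `slices` (selected slice index per view).
#' @export
external_bone_contour_distance <- function(sct, ct, threshold_hu = 200) {
  a <- vol_data(sct)
  b <- vol_data(ct)
  spa <- vol_spacing(sct)
  if (!identical(dim(a), dim(b))) b <- resample_nn(ct, sct)
  bone_s <- a >= threshold_hu
  bone_c <- b >= threshold_hu
  if (!any(bone_s) || !any(bone_c)) stop("no bone above threshold")
  # view: (slice axis, in-plane axes (vertical, horizontal))
  views <- list(axial = c(1L, 2L, 3L), coronal = c(2L, 1L, 3L),
                sagittal = c(3L, 1L, 2L))
  per_view <- c(axial = NA_real_, coronal = NA_real_, sagittal = NA_real_)
  slices <- c(axial = NA_integer_, coronal = NA_integer_, sagittal = NA_integer_)
  get_slice <- function(vol, axis, k) {
    switch(axis, vol[k, , ], vol[, k, ], vol[, , k])
  }
  for (vn in names(views)) {
    ax <- views[[vn]]
    nslice <- dim(a)[ax[1]]
    hax <- ax[3]
    width <- vapply(seq_len(nslice), function(k) {
      sl <- get_slice(bone_s, ax[1], k)
      if (!any(sl)) return(0)
      cols <- which(apply(sl, if (hax > ax[2]) 2L else 1L, any))
      (max(cols) - min(cols) + 1) * spa[hax]
    }, 0.0)
    if (max(width) == 0) next
    k <- which.max(width)
    slices[vn] <- k
    cs <- external_contour_2d(get_slice(bone_s, ax[1], k))
    cc2 <- get_slice(bone_c, ax[1], k)
    ctc <- external_contour_2d(cc2)
    if (is.null(cs) || is.null(ctc)) next
    ctm <- array(FALSE, dim(cc2))
    ctm[ctc] <- TRUE
    sp2 <- spa[ax[2:3]]
    dmap <- distance_to_mask(ctm, sp2)
    dim(dmap) <- dim(ctm)
    per_view[vn] <- mean(dmap[cs])
  }
  if (all(is.na(per_view))) stop("no external bone contour in any view")
  list(per_view = per_view, mean = mean(per_view, na.rm = TRUE), slices = slices)
}

# Nearest-neighbour resampling of `src` onto the grid of `dst` (aligned
# origins, spacing-based index mapping).
resample_nn <- function(src, dst) {
  s <- vol_data(src); sp_s <- vol_spacing(src)
  dd <- dim(vol_data(dst)); sp_d <- vol_spacing(dst)
  ds <- dim(s)
  ix <- function(axis) {
    i <- pmin(pmax(round(((seq_len(dd[axis]) - 1) * sp_d[axis]) / sp_s[axis]) + 1, 1), ds[axis])
    as.integer(i)
  }
  s[ix(1), ix(2), ix(3)]
}

#' Full sCT-vs-CT metrics report
#'
#' Computes the external bone contour distances, bone Dice (200 HU
#' threshold in both volumes), and ME/MAE per evaluation region; optionally
#' writes `metrics.csv` and `metrics.json` to a directory.
#'
#' @param sct,ct [intensity_volume]s (HU) on a common grid.
#' @param labels optional [label_volume] for per-tissue regions.
#' @param out_dir optional output directory.
#' @return list with `contour_distance`, `dice`, and `errors` (data.frame).
#' @export
evaluate_sct <- function(sct, ct, labels = NULL, out_dir = NULL) {
  regions <- build_eval_regions(sct, ct, labels)
  errs <- do.call(rbind, lapply(names(regions), function(nm) {
    e <- ed_errors(sct, ct, regions[[nm]])
    data.frame(region = nm, ME = e[["ME"]], MAE = e[["MAE"]],
               n_voxels = sum(regions[[nm]]))
  }))
  a <- vol_data(sct); b <- vol_data(ct)
  # brain DSC needs a manual reference contour and is left to the caller;
  # only the threshold-defined bone DSC is computed here
  dsc <- c(bone = dice(a >= 200, b >= 200))
  cd <- tryCatch(external_bone_contour_distance(sct, ct),
                 error = function(e) NULL)
  out <- list(contour_distance = cd, dice = dsc, errors = errs)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(errs, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(list(
      contour_distance_mm = if (is.null(cd)) NULL else
        list(per_view = as.list(cd$per_view), mean = cd$mean),
      dice = as.list(dsc),
      errors = errs
    ), file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  }
  out
}
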