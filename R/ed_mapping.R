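# Electron-density mapping: per-tissue transforms from MR intensity windows
# to CT-number (HU) intervals, and assembly of the synthetic CT.
#
# Default transform table (contrast-enhanced T1 -> HU):
#   air        all intensities           bulk           -1000
#   cortical   mu_cbone +/- 2 sigma      inverse linear [700, 1100]
#   trabecular mu_trab  +/- 2 sigma      inverse linear [500, 700]
#   brain      mu_brain +/- 2 sigma      linear         [40, 75]
#   CSF        all intensities           bulk           45
#   muscle     [min_soft, mu+sigma]      inverse linear [20, 80]
#   fat        [mu+sigma, mu+2 sigma]    inverse linear [-70, -20]
#   contrast   > mu + 2 sigma            bulk           0
# Eyes carry no row in the published table; they are water-like soft tissue
# and default to a bulk 45 HU (configurable).

#' Build a tissue-to-HU mapping table
#'
#' @param entries data.frame with columns `tissue` (names of [SCT_LABELS]),
#'   `transform` (`"bulk"`, `"linear"`, `"inverse_linear"`), `mr_lo`,
#'   `mr_hi` (NA for bulk / all-intensity entries) and `hu_lo`, `hu_hi`.
#' @return The validated data.frame, classed `mapping_spec`.
#' @export
mapping_spec <- function(entries) {
  req <- c("tissue", "transform", "mr_lo", "mr_hi", "hu_lo", "hu_hi")
  if (!all(req %in% names(entries))) stop("missing mapping columns")
  if (!all(entries$tissue %in% names(SCT_LABELS))) stop("unknown tissue name")
  if (anyDuplicated(entries$tissue)) stop("duplicate tissue entry")
  if (!all(entries$transform %in% c("bulk", "linear", "inverse_linear")))
    stop("unknown transform")
  if (any(entries$hu_lo > entries$hu_hi)) stop("hu_lo must be <= hu_hi")
  bulk <- entries$transform == "bulk"
  if (any(entries$hu_lo[bulk] != entries$hu_hi[bulk]))
    stop("bulk entries must have hu_lo == hu_hi")
  ok_win <- bulk | (!is.na(entries$mr_lo) & !is.na(entries$mr_hi))
  if (!all(ok_win)) stop("non-bulk entry with an all-intensity window")
  structure(entries, class = c("mapping_spec", "data.frame"))
}

#' Default mapping table instantiated from tissue statistics
#'
#' @param stats named list of [tissue_stats]: `cortical`, `trabecular`,
#'   `brain` (each may be `NULL`, dropping the row) and `soft` (mean/sd/min
#'   of the residual soft tissue, used for the muscle and fat windows).
#' @param eye_hu bulk HU assigned to the eyes.
#' @return A [mapping_spec].
#' @export
default_mapping_spec <- function(stats, eye_hu = 45) {
  rows <- list(
    data.frame(tissue = "BACKGROUND", transform = "bulk",
               mr_lo = NA_real_, mr_hi = NA_real_, hu_lo = -1000, hu_hi = -1000),
    data.frame(tissue = "AIR", transform = "bulk",
               mr_lo = NA_real_, mr_hi = NA_real_, hu_lo = -1000, hu_hi = -1000),
    data.frame(tissue = "CSF", transform = "bulk",
               mr_lo = NA_real_, mr_hi = NA_real_, hu_lo = 45, hu_hi = 45),
    data.frame(tissue = "EYE", transform = "bulk",
               mr_lo = NA_real_, mr_hi = NA_real_, hu_lo = eye_hu, hu_hi = eye_hu),
    data.frame(tissue = "CONTRAST", transform = "bulk",
               mr_lo = NA_real_, mr_hi = NA_real_, hu_lo = 0, hu_hi = 0)
  )
  two_sigma_row <- function(tissue, st, hu_lo, hu_hi, transform) {
    if (is.null(st)) return(NULL)
    data.frame(tissue = tissue, transform = transform,
               mr_lo = st$mean - 2 * st$sd, mr_hi = st$mean + 2 * st$sd,
               hu_lo = hu_lo, hu_hi = hu_hi)
  }
  rows <- c(rows, list(
    two_sigma_row("CORTICAL_BONE", stats$cortical, 700, 1100, "inverse_linear"),
    two_sigma_row("TRABECULAR_BONE", stats$trabecular, 500, 700, "inverse_linear"),
    two_sigma_row("BRAIN", stats$brain, 40, 75, "linear")
  ))
  if (!is.null(stats$soft)) {
    ms <- stats$soft
    rows <- c(rows, list(
      data.frame(tissue = "MUSCLE", transform = "inverse_linear",
                 mr_lo = ms$min, mr_hi = ms$mean + ms$sd,
                 hu_lo = 20, hu_hi = 80),
      data.frame(tissue = "FAT", transform = "inverse_linear",
                 mr_lo = ms$mean + ms$sd, mr_hi = ms$mean + 2 * ms$sd,
                 hu_lo = -70, hu_hi = -20)
    ))
  }
  mapping_spec(do.call(rbind, rows[!vapply(rows, is.null, TRUE)]))
}

#' Map MR intensities to HU through one mapping entry
#'
#' Bulk entries return their constant for any intensity. Linear entries map
#' the MR window `[mr_lo, mr_hi]` onto `[hu_lo, hu_hi]`; inverse-linear
#' entries onto `[hu_hi, hu_lo]` (brighter MR, lower HU). Intensities
#' outside the window are clipped to it first (partial-volume voxels
#' routinely fall outside a mu +/- 2 sigma window); a degenerate window
#' (`mr_lo == mr_hi`) returns the HU midpoint.
#'
#' @param intensity numeric vector of MR intensities.
#' @param entry one row of a [mapping_spec] (data.frame or list).
#' @return numeric vector of HU values.
#' @export
map_voxel <- function(intensity, entry) {
  tr <- entry$transform
  if (tr == "bulk") return(rep(entry$hu_lo, length(intensity)))
  if (is.na(entry$mr_lo) || is.na(entry$mr_hi))
    stop("non-bulk entry with an all-intensity window")
  lo <- entry$mr_lo; hi <- entry$mr_hi
  if (lo == hi) return(rep((entry$hu_lo + entry$hu_hi) / 2, length(intensity)))
  x <- pmin(pmax(intensity, lo), hi)
  f <- (x - lo) / (hi - lo)
  if (tr == "linear") entry$hu_lo + f * (entry$hu_hi - entry$hu_lo)
  else entry$hu_hi - f * (entry$hu_hi - entry$hu_lo)
}

#' Assemble the synthetic CT
#'
#' Substitutes every voxel's MR intensity with a CT number according to its
#' tissue label: air and background become -1000 HU, bulk tissues their
#' constant, and windowed tissues go through their linear or inverse-linear
#' transform. When per-slice soft-tissue statistics are supplied, the
#' muscle and fat windows are instantiated per axial slice (consistent with
#' the per-slice classification); otherwise the global windows from the
#' mapping table are used.
#'
#' @param volume the MR [intensity_volume].
#' @param labels a [label_volume] (complete: every voxel labelled).
#' @param spec a [mapping_spec]; defaults to
#'   `default_mapping_spec(stats)`.
#' @param stats named list of tissue statistics (see
#'   [default_mapping_spec()]); required when `spec` is NULL.
#' @param slice_stats optional `soft_stats` for per-slice muscle/fat
#'   windows.
#' @return An [intensity_volume] with modality `"CT"`.
#' @export
assemble_sct <- function(volume, labels, spec = NULL, stats = NULL,
                         slice_stats = NULL) {
  v <- vol_data(volume)
  d <- dim(v)
  lab <- if (inherits(labels, "label_volume")) labels$labels else labels
  if (!identical(dim(lab), d)) stop("labels shape does not match volume")
  if (is.null(spec)) spec <- default_mapping_spec(stats)
  present <- sort(unique(as.vector(lab)))
  codes <- SCT_LABELS[spec$tissue]
  missing_codes <- setdiff(present, codes)
  if (length(missing_codes) > 0L)
    stop("unlabelled or unmapped voxels: no mapping entry for code(s) ",
         paste(missing_codes, collapse = ", "))
  hu <- array(0, d)
  for (i in seq_len(nrow(spec))) {
    code <- SCT_LABELS[[spec$tissue[i]]]
    sel <- lab == code
    if (!any(sel)) next
    tissue <- spec$tissue[i]
    if (!is.null(slice_stats) && tissue %in% c("MUSCLE", "FAT")) {
      kidx <- rep(seq_len(d[1]), times = d[2] * d[3])
      mu <- slice_stats$mean; sd <- slice_stats$sd
      if (tissue == "MUSCLE") {
        wlo <- rep(slice_stats$min, d[1]); whi <- mu + sd
      } else {
        wlo <- mu + sd; whi <- mu + 2 * sd
      }
      lo <- wlo[kidx][sel]; hi <- whi[kidx][sel]
      x <- pmin(pmax(v[sel], lo), hi)
      f <- ifelse(hi > lo, (x - lo) / (hi - lo), 0.5)
      hu[sel] <- spec$hu_hi[i] - f * (spec$hu_hi[i] - spec$hu_lo[i])
    } else {
      hu[sel] <- map_voxel(v[sel], spec[i, ])
    }
  }
  intensity_volume(hu, spacing_mm = vol_spacing(volume), modality = "CT")
}
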