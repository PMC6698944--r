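# Volume I/O. NIfTI goes through RNifti; DICOM series go through the
# minimal reader/writer in dicom.R. In-memory arrays follow the package grid
# convention (k = axial slice, row = posterior->anterior, col = right->left);
# NIfTI files written here store the array with dim (nz, ny, nx) and pixdim
# carrying the spacing, and are read back verbatim.

#' Read an MR or CT volume
#'
#' Reads a NIfTI file (`.nii` / `.nii.gz`) or a DICOM series directory.
#' CT values have the rescale slope/intercept applied so they are HU; MR
#' intensities are shifted so that the minimum is >= 0. DICOM slices are
#' sorted by position along the slice normal, ascending.
#'
#' @param path file (NIfTI) or directory (DICOM series).
#' @param modality `"MR"` or `"CT"`; for DICOM, inferred from the Modality
#'   tag when present.
#' @return An [intensity_volume].
#' @export
read_volume <- function(path, modality = c("MR", "CT")) {
  modality <- match.arg(modality)
  if (dir.exists(path)) return(read_dicom_series(path, modality))
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L) stop("expected a 3D volume")
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop("missing or invalid voxel spacing in NIfTI header")
  a <- a * 1.0
  if (modality == "MR" && min(a) < 0) a <- a - min(a)
  intensity_volume(a, spacing_mm = sp[1:3], modality = modality)
}

#' Write a synthetic CT (or any HU volume)
#'
#' NIfTI: HU stored as 16-bit signed integers with identity scaling.
#' DICOM: one CT file per axial slice with RescaleSlope 1 and
#' RescaleIntercept -1024. HU outside `[-1024, 3071]` are clipped with a
#' warning.
#'
#' @param volume an [intensity_volume] with modality `"CT"`.
#' @param path output file (NIfTI) or directory (DICOM).
#' @param dialect `"nifti"` or `"dicom"`.
#' @return `path`, invisibly.
#' @export
write_sct <- function(volume, path, dialect = c("nifti", "dicom")) {
  dialect <- match.arg(dialect)
  if (!inherits(volume, "intensity_volume") || volume$modality != "CT")
    stop("write_sct() expects a CT intensity_volume")
  a <- volume$data
  if (min(a) < -1024 || max(a) > 3071) {
    warning("HU outside [-1024, 3071] clipped on write")
    a <- pmin(pmax(a, -1024), 3071)
  }
  a <- round(a)
  if (dialect == "nifti") {
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- volume$spacing_mm
    RNifti::writeNifti(img, path, datatype = "int16")
  } else {
    write_dicom_series(a, volume$spacing_mm, path)
  }
  invisible(path)
}

#' Write a label map as NIfTI (uint8)
#'
#' @param labels a [label_volume].
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_labels <- function(labels, path) {
  img <- RNifti::asNifti(labels$labels)
  RNifti::pixdim(img) <- labels$spacing_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a label map written by [write_labels()]
#'
#' @param path `.nii` / `.nii.gz` path.
#' @export
read_labels <- function(path) {
  img <- RNifti::readNifti(path)
  label_volume(as.array(img), spacing_mm = RNifti::pixdim(img)[1:3])
}
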