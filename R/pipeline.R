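# Pipeline orchestration: runs the stages in order (body, air, brain/CSF,
# eyes, bone, soft tissue, ED mapping) with the label precedence
# AIR > CORTICAL_BONE > TRABECULAR_BONE > EYE > CSF > BRAIN > CONTRAST >
# FAT > MUSCLE, collects the per-stage report, and returns a classed
# result.

#' Pipeline configuration
#'
#' All thresholds and coefficients of the pipeline in one nested list; the
#' defaults are the intended clinical values. Override any subset via
#' `...`, e.g. `sct_config(brain = list(grow_hi = 1.25))`.
#'
#' @param ... named lists merged over the defaults (one level deep).
#' @return nested configuration list.
#' @export
sct_config <- function(...) {
  cfg <- list(
    air = list(subtract_sigma = 3.0, stats_fraction = 0.5),
    body = list(closing_mm = 3.0),
    brain = list(stat_lo = 0.53, stat_hi = 1.35, grow_lo = 0.7, grow_hi = 1.2,
                 window_mm = 10),
    canny = list(sigma = 1.0, low = 0.4, high = 0.8),
    csf = list(window_mm = 5, sigma = 2.0),
    skull = list(rim_cm = 1.0),
    eye = list(threshold_coeff = 0.7, diameter_cm = 4.0, box_sup_cm = 5,
               box_inf_cm = 7, sphericity_cm = 1.0, size_rule = "volume"),
    bone = list(air_sigma = 3.0, trab_window_mm = 5.0, trab_sigma = 2.0),
    soft = list(context_slices = 1L, fat_sigma = 2.0),
    mapping = list(eye_hu = 45)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.null(cfg[[nm]])) stop("unknown config section: ", nm)
    cfg[[nm]][names(over[[nm]])] <- over[[nm]]
  }
  cfg
}

stage_run <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Generate a synthetic CT from an MR volume and manual air contours
#'
#' Runs the full tissue-segmentation pipeline and the electron-density
#' mapping. Deterministic: identical inputs and configuration produce an
#' identical sCT (there is no unseeded randomness anywhere).
#'
#' @param mr the MR [intensity_volume].
#' @param contours a [contour_set] of manual air contours.
#' @param config a [sct_config()] list.
#' @param verbose print per-stage progress.
#' @return Object of class `sct`: list with `sct` (HU [intensity_volume]),
#'   `labels` ([label_volume]), `stats` (tissue statistics used for the
#'   mapping), `ref` (brain reference), `mapping` (the instantiated
#'   [mapping_spec]), `report` (per-stage voxel counts) and `config`.
#' @export
mr2sct <- function(mr, contours, config = sct_config(), verbose = FALSE) {
  stopifnot(inherits(mr, "intensity_volume"))
  if (mr$modality != "MR") stop("mr2sct() expects an MR volume")
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  report <- list()
  note <- function(stage, mask) report[[stage]] <<- sum(mask)

  say("air: interpolating %d contour polygon(s)", length(contours$contours))
  roi <- stage_run("air", interpolate_contours(contours, mr))
  air_stats <- stage_run("air",
    estimate_air_stats(mr, roi, fraction = config$air$stats_fraction))
  body <- stage_run("body", external_body_contour(mr, air_stats,
    air_sigma = config$air$subtract_sigma, closing_mm = config$body$closing_mm))
  note("body", body)
  air <- stage_run("air", build_air_mask(mr, roi, air_stats,
    subtract_sigma = config$air$subtract_sigma))
  note("air", air)

  say("brain: white-matter reference search")
  ref <- stage_run("brain", find_wm_reference(mr, body,
    stat_lo = config$brain$stat_lo, stat_hi = config$brain$stat_hi,
    grow_lo = config$brain$grow_lo, grow_hi = config$brain$grow_hi,
    window_mm = config$brain$window_mm))
  say("brain: wmIntensity = %.4g", ref$wmIntensity)
  edges <- stage_run("brain", detect_and_close_edges(mr, ref,
    sigma = config$canny$sigma, lo_frac = config$canny$low,
    hi_frac = config$canny$high))
  note("edges", edges)
  brain0 <- stage_run("brain", segment_brain_initial(mr, ref, edges))
  note("brain_initial", brain0)
  csf_ref <- stage_run("csf", find_csf_reference(mr, brain0, ref,
    window_mm = config$csf$window_mm))
  skull <- stage_run("skull", build_skull_mask(mr, body, brain0, csf_ref,
    air_stats, edges, air_mask = air, rim_mm = config$skull$rim_cm * 10,
    air_sigma = config$air$subtract_sigma, csf_sigma = config$csf$sigma))
  note("skull_mask", skull)
  csf <- stage_run("csf", segment_csf(mr, csf_ref, skull,
    csf_sigma = config$csf$sigma))
  note("csf", csf)
  brain <- stage_run("brain", segment_brain_final(mr, ref, brain0, csf, skull))
  note("brain", brain)

  say("eyes: searching the anterior box")
  eyes_res <- stage_run("eyes", segment_eyes(mr, brain, ref,
    exclude = air | brain | csf,
    threshold_coeff = config$eye$threshold_coeff,
    diameter_cm = config$eye$diameter_cm,
    box_sup_cm = config$eye$box_sup_cm, box_inf_cm = config$eye$box_inf_cm,
    sphericity_cm = config$eye$sphericity_cm,
    size_rule = config$eye$size_rule))
  eyes <- eyes_res$mask
  if (any(eyes & (brain | csf | air)))
    stop("stage 'eyes' failed: eyes intersect brain, CSF or air")
  note("eyes", eyes)

  say("bone: cortical growing and trabecular recovery")
  cortical <- stage_run("bone", segment_cortical_bone(mr, skull, air,
    air_stats, body, air_sigma = config$bone$air_sigma))
  cortical <- cortical & !eyes
  note("cortical_bone", cortical)
  labelled <- air | brain | csf | eyes
  # the reference diploe lies inside the skull zone; intracranial voxels
  # that escaped the brain/CSF windows must not contaminate its statistics
  trab_stats <- tryCatch(
    estimate_trabecular_stats(mr, cortical, exclude = labelled | !skull),
    error = function(e) {
      warning("bone: ", conditionMessage(e), "; no trabecular bone labelled")
      NULL
    })
  trab <- if (is.null(trab_stats)) array(FALSE, dim(mr$data)) else
    stage_run("bone", recover_trabecular_bone(mr, cortical, trab_stats,
      neighborhood_mm = config$bone$trab_window_mm,
      exclude = labelled, trab_sigma = config$bone$trab_sigma))
  trab <- trab & body
  note("trabecular_bone", trab)

  say("soft tissue: per-slice statistics")
  residual <- body & !(air | cortical | trab | brain | csf | eyes)
  note("residual_soft", residual)
  slice_stats <- stage_run("soft", per_slice_soft_stats(mr, residual,
    context_slices = config$soft$context_slices))
  soft_lab <- stage_run("soft", classify_soft_tissue(mr, residual,
    slice_stats, fat_sigma = config$soft$fat_sigma))

  # label assembly in increasing precedence
  d <- dim(mr$data)
  lab <- array(SCT_LABELS[["BACKGROUND"]], d)
  lab[soft_lab == SCT_LABELS[["MUSCLE"]]] <- SCT_LABELS[["MUSCLE"]]
  lab[soft_lab == SCT_LABELS[["FAT"]]] <- SCT_LABELS[["FAT"]]
  lab[soft_lab == SCT_LABELS[["CONTRAST"]]] <- SCT_LABELS[["CONTRAST"]]
  lab[brain] <- SCT_LABELS[["BRAIN"]]
  lab[csf] <- SCT_LABELS[["CSF"]]
  lab[eyes] <- SCT_LABELS[["EYE"]]
  lab[trab] <- SCT_LABELS[["TRABECULAR_BONE"]]
  lab[cortical] <- SCT_LABELS[["CORTICAL_BONE"]]
  lab[air] <- SCT_LABELS[["AIR"]]
  if (any(lab[body] == SCT_LABELS[["BACKGROUND"]] & !air[body]))
    stop("label map is not a partition of the body")
  labels <- label_volume(lab, mr$spacing_mm)

  say("mapping: assembling the sCT")
  soft_global <- if (any(residual)) compute_region_stats(mr, residual) else NULL
  stats <- list(
    air = air_stats,
    cortical = if (any(cortical)) compute_region_stats(mr, cortical) else NULL,
    trabecular = trab_stats,
    brain = if (any(brain)) compute_region_stats(mr, brain) else NULL,
    csf = tissue_stats(csf_ref$mean, csf_ref$sd, csf_ref$min, csf_ref$n),
    soft = soft_global
  )
  mapping <- stage_run("mapping",
    default_mapping_spec(stats, eye_hu = config$mapping$eye_hu))
  sct <- stage_run("mapping",
    assemble_sct(mr, labels, spec = mapping, slice_stats = slice_stats))

  report$wmIntensity <- ref$wmIntensity
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  structure(list(sct = sct, labels = labels, stats = stats, ref = ref,
                 mapping = mapping, slice_stats = slice_stats,
                 eyes = eyes_res$components, report = report,
                 config = config),
            class = "sct")
}

#' @export
print.sct <- function(x, ...) {
  d <- dim(x$sct$data)
  cat(sprintf("<sct> %d x %d x %d voxels, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3], min(x$sct$data), max(x$sct$data)))
  cat(sprintf("  wmIntensity %.4g\n", x$ref$wmIntensity))
  tab <- tabulate(x$labels$labels + 1L, nbins = length(SCT_LABELS))
  names(tab) <- names(SCT_LABELS)
  print(tab[tab > 0])
  invisible(x)
}

#' @export
summary.sct <- function(object, ...) {
  print(object)
  cat("\nTissue statistics (MR units):\n")
  for (nm in names(object$stats)) {
    st <- object$stats[[nm]]
    if (is.null(st)) next
    cat(sprintf("  %-11s mean %8.2f  sd %7.2f  n %d\n", nm, st$mean, st$sd, st$n))
  }
  cat("\nMapping table:\n")
  print(as.data.frame(object$mapping), row.names = FALSE)
  invisible(object)
}

#' Plot a slice of an sCT result
#'
#' @param x an `sct` object.
#' @param slice axial slice index (default: middle slice).
#' @param what `"sct"` (HU, gray scale) or `"labels"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.sct <- function(x, slice = NULL, what = c("sct", "labels"), ...) {
  what <- match.arg(what)
  d <- dim(x$sct$data)
  if (is.null(slice)) slice <- as.integer(round(d[1] / 2))
  m <- if (what == "sct") x$sct$data[slice, , ] else
    x$labels$labels[slice, , ] * 1.0
  image(t(m), col = gray(seq(0, 1, length.out = 128)), asp = d[2] / d[3],
        axes = FALSE, main = sprintf("%s, axial slice %d", what, slice), ...)
  invisible(x)
}

#' Run the pipeline from files
#'
#' Reads the MR volume and air contours, runs [mr2sct()], and writes the
#' sCT, the label map, and a JSON report to `output_dir`. On failure a
#' MANIFEST.json noting the failed stage is still written.
#'
#' @param mr_path NIfTI file or DICOM directory.
#' @param contours_path JSON or RTSTRUCT contour file.
#' @param config a [sct_config()] list.
#' @param output_dir output directory (created if needed).
#' @param verbose print stage progress.
#' @return the `sct` object, invisibly.
#' @export
run_pipeline <- function(mr_path, contours_path, config = sct_config(),
                         output_dir = ".", verbose = TRUE) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  manifest <- file.path(output_dir, "MANIFEST.json")
  if (!file.exists(mr_path)) stop("MR volume not found: ", mr_path)
  if (!file.exists(contours_path))
    stop("stage 'air' failed: contour file not found: ", contours_path,
         " (draw the air regions on up to 12 axial slices and export them",
         " as JSON or RTSTRUCT)")
  mr <- read_volume(mr_path, "MR")
  contours <- read_air_contours(contours_path, mr)
  res <- tryCatch(mr2sct(mr, contours, config, verbose = verbose),
                  error = function(e) {
                    jsonlite::write_json(list(status = "failed",
                                              error = conditionMessage(e)),
                                         manifest, auto_unbox = TRUE)
                    stop(e)
                  })
  write_sct(res$sct, file.path(output_dir, "sct.nii.gz"))
  write_labels(res$labels, file.path(output_dir, "labels.nii.gz"))
  jsonlite::write_json(res$report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(status = "ok",
                            outputs = c("sct.nii.gz", "labels.nii.gz",
                                        "report.json")),
                       manifest, auto_unbox = TRUE)
  invisible(res)
}
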