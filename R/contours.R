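# Manual air contours: construction, JSON / RTSTRUCT reading, polygon
# rasterization and boundary tracing.

#' Construct a contour set
#'
#' Per-slice closed planar polygons delineating the air regions (sinuses and
#' airway). The clinical workflow draws these on no more than about a dozen
#' axial slices; a warning is issued above 12 distinct slices.
#'
#' @param contours list of `list(slice = k, vertices = <n x 2 matrix of
#'   (row, col)>)`; slice indices are 1-based; each polygon needs >= 3
#'   vertices and is closed (the first vertex is appended when absent).
#' @param dim grid dimensions `(nz, ny, nx)` of the annotated volume.
#' @return Object of class `contour_set`.
#' @export
contour_set <- function(contours, dim) {
  stopifnot(length(dim) == 3L)
  contours <- lapply(contours, function(ct) {
    v <- ct$vertices
    if (is.null(dim(v))) v <- matrix(v, ncol = 2L, byrow = TRUE)
    v <- apply(v, 2, as.numeric)
    if (is.null(dim(v))) v <- matrix(v, ncol = 2L)
    if (nrow(v) > 1L && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
    if (nrow(v) < 3L) stop("polygon with < 3 vertices")
    k <- as.integer(ct$slice)
    if (k < 1L || k > dim[1]) stop("contour slice index outside grid")
    list(slice = k, vertices = rbind(v, v[1, ]))   # stored closed
  })
  ks <- vapply(contours, `[[`, 1L, "slice")
  if (length(unique(ks)) > 12L)
    warning("more than 12 contoured slices; the intended workflow uses <= 12")
  structure(list(contours = contours, dim = as.integer(dim)),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  ks <- vapply(x$contours, `[[`, 1L, "slice")
  cat(sprintf("<contour_set> %d polygon(s) on %d slice(s): %s\n",
              length(x$contours), length(unique(ks)),
              paste(sort(unique(ks)), collapse = ", ")))
  invisible(x)
}

#' Read manual air contours
#'
#' Accepts either the package JSON schema (an object with a `contours` array
#' of `{"slice": k, "vertices": [[row, col], ...]}`, 1-based grid
#' coordinates) or a DICOM RTSTRUCT file containing an ROI named `"AIR"`
#' (case-insensitive). RTSTRUCT contour points (patient mm, identity
#' orientation assumed) are converted to grid row/col/slice coordinates via
#' the frame's spacing.
#'
#' @param path JSON file or DICOM RTSTRUCT file.
#' @param frame the [intensity_volume] the contours annotate.
#' @return A [contour_set].
#' @export
read_air_contours <- function(path, frame) {
  d <- dim(vol_data(frame))
  is_json <- grepl("\\.json$", path, ignore.case = TRUE)
  if (!is_json) {
    # sniff: JSON files start with printable '{' or '['
    b <- readBin(path, "raw", 1L)
    is_json <- length(b) == 1L && rawToChar(b) %in% c("{", "[")
  }
  if (is_json) {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    cts <- lapply(doc$contours, function(ct)
      list(slice = ct$slice,
           vertices = do.call(rbind, lapply(ct$vertices, unlist))))
    return(contour_set(cts, d))
  }
  rtstruct_air_contours(path, frame)
}

#' Write contours to the package JSON schema
#'
#' @param contours a [contour_set].
#' @param path output path.
#' @export
write_air_contours <- function(contours, path) {
  doc <- list(contours = lapply(contours$contours, function(ct)
    list(slice = ct$slice,
         vertices = lapply(seq_len(nrow(ct$vertices) - 1L),
                           function(i) as.numeric(ct$vertices[i, ])))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

rtstruct_air_contours <- function(path, frame) {
  el <- read_dicom_file(path)
  sp <- vol_spacing(frame)
  d <- dim(vol_data(frame))
  rois <- el[["3006,0020"]]
  if (is.null(rois)) stop("not an RTSTRUCT file (no StructureSetROISequence)")
  roi_num <- NULL
  for (item in rois) {
    nm <- dcm_string(item[["3006,0026"]])
    if (!is.null(nm) && toupper(nm) == "AIR") {
      roi_num <- dcm_string(item[["3006,0022"]])
      break
    }
  }
  if (is.null(roi_num)) stop("RTSTRUCT has no ROI named 'AIR'")
  rcs <- el[["3006,0039"]]
  cts <- list()
  for (item in rcs %||% list()) {
    ref <- dcm_string(item[["3006,0084"]])
    if (!identical(ref, roi_num)) next
    for (ct in item[["3006,0040"]] %||% list()) {
      xyz <- dcm_numbers(ct[["3006,0050"]])
      if (is.null(xyz)) next
      p <- matrix(xyz, ncol = 3L, byrow = TRUE)   # (x, y, z) patient mm
      k <- round(p[1, 3] / sp[1]) + 1L
      # x -> col, y -> row (identity orientation, zero origin)
      verts <- cbind(p[, 2] / sp[2] + 1, p[, 1] / sp[3] + 1)
      cts[[length(cts) + 1L]] <- list(slice = k, vertices = verts)
    }
  }
  if (length(cts) == 0L) stop("RTSTRUCT AIR ROI has no contour data")
  contour_set(cts, d)
}

#' Rasterize a closed planar polygon onto a slice grid
#'
#' A voxel belongs to the polygon when its centre is inside (even-odd rule)
#' or on the boundary. Vertex order (clockwise or counter-clockwise) does
#' not matter.
#'
#' @param vertices n x 2 matrix of `(row, col)` vertices (closed or open).
#' @param nr,nc slice dimensions.
#' @return logical `nr x nc` matrix.
#' @export
rasterize_polygon <- function(vertices, nr, nc) {
  v <- vertices
  if (nrow(v) > 1L && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  out <- matrix(FALSE, nr, nc)
  rlo <- max(1L, floor(min(v[, 1]))); rhi <- min(nr, ceiling(max(v[, 1])))
  clo <- max(1L, floor(min(v[, 2]))); chi <- min(nc, ceiling(max(v[, 2])))
  if (rlo > rhi || clo > chi) return(out)
  rows <- rlo:rhi; cols <- clo:chi
  py <- rep(rows, times = length(cols))      # row coordinate of candidates
  px <- rep(cols, each = length(rows))       # col coordinate
  inside <- logical(length(py))
  onedge <- logical(length(py))
  n <- nrow(v)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    y1 <- v[i, 1]; x1 <- v[i, 2]; y2 <- v[j, 1]; x2 <- v[j, 2]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      inside <- xor(inside, crosses & (px < xint))
    }
    # on-segment test
    dy <- y2 - y1; dx <- x2 - x1
    len2 <- dy * dy + dx * dx
    if (len2 == 0) {
      onedge <- onedge | (abs(py - y1) < 1e-9 & abs(px - x1) < 1e-9)
    } else {
      t <- ((py - y1) * dy + (px - x1) * dx) / len2
      tc <- pmin(pmax(t, 0), 1)
      d2 <- (py - (y1 + tc * dy))^2 + (px - (x1 + tc * dx))^2
      onedge <- onedge | (d2 < 1e-12)
    }
  }
  out[cbind(py, px)] <- inside | onedge
  out
}

# Moore boundary tracing of the largest 8-connected component of a 2D mask.
# Returns an ordered closed loop of boundary pixel coordinates (row, col).
trace_boundary <- function(mask2d) {
  comp <- largest_component(mask2d, 26L)
  dim(comp) <- dim(mask2d)
  if (!any(comp)) return(NULL)
  nr <- nrow(comp); nc <- ncol(comp)
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && comp[r, c]
  # start: first foreground pixel in column-major scan; its scan predecessor
  # is background, so backtrack direction "up the scan" is safe
  idx <- which(comp)[1]
  r0 <- (idx - 1L) %% nr + 1L
  c0 <- (idx - 1L) %/% nr + 1L
  # clockwise Moore neighbourhood starting pointing "up" (-row)
  nb <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L, 0L, -1L, -1L, -1L),
               ncol = 2L, byrow = TRUE)
  path <- matrix(0L, 0L, 2L)
  cur <- c(r0, c0)
  prev_dir <- 1L   # came from "up"
  repeat {
    path <- rbind(path, cur)
    found <- FALSE
    start <- (prev_dir + 5L) %% 8L   # begin search just after backtrack
    for (s in 0:7) {
      dirn <- (start + s) %% 8L
      nr2 <- cur[1] + nb[dirn + 1L, 1L]
      nc2 <- cur[2] + nb[dirn + 1L, 2L]
      if (at(nr2, nc2)) {
        cur <- c(nr2, nc2)
        prev_dir <- dirn
        found <- TRUE
        break
      }
    }
    if (!found) break                       # isolated pixel
    if (all(cur == c(r0, c0))) break
    if (nrow(path) > 4L * (nr * nc)) break  # safety
  }
  unname(path)
}

# Derive a contour set from a binary air mask: trace the largest component
# boundary on <= max_slices slices spread evenly over the slices containing
# air (always including the first and last).
contours_from_mask <- function(mask, max_slices = 12L) {
  d <- dim(mask)
  ks <- which(apply(mask, 1, any))
  if (length(ks) == 0L) stop("mask has no true voxels")
  pick <- unique(round(seq(min(ks), max(ks), length.out = min(max_slices, length(ks)))))
  pick <- intersect(pick, ks)
  used <- integer(0)
  cts <- list()
  mid <- mean(range(ks))
  for (k in pick) {
    # a slice whose air region is too small to trace falls back to the
    # nearest traceable slice towards the centre of the span
    step <- if (k <= mid) 1L else -1L
    kk <- k
    poly <- NULL
    while (kk %in% ks) {
      poly <- trace_boundary(mask[kk, , ])
      if (!is.null(poly) && nrow(poly) >= 3L) break
      poly <- NULL
      kk <- kk + step
    }
    if (is.null(poly) || kk %in% used) next
    used <- c(used, kk)
    cts[[length(cts) + 1L]] <- list(slice = kk, vertices = poly)
  }
  contour_set(cts, d)
}
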