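# Minimal DICOM support: uncompressed little-endian files (implicit VR and
# explicit VR transfer syntaxes), enough to read MR/CT slice series and
# RTSTRUCT contour sequences and to write CT slice series. This is a
# deliberately small format layer, not a general DICOM toolkit: no big
# endian, no compressed pixel data, no character-set handling.

DCM_EXPLICIT <- "1.2.840.10008.1.2.1"
DCM_IMPLICIT <- "1.2.840.10008.1.2"

tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

read_u16 <- function(con) readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
read_u32 <- function(con) {
  b <- readBin(con, "raw", 4L)
  if (length(b) < 4L) return(NULL)
  sum(as.numeric(b) * c(1, 256, 65536, 16777216))
}

# Parse a stream of data elements until `limit` bytes are consumed (or EOF
# when limit is NULL), or an item/sequence delimiter is met. Returns a named
# list keyed "GGGG,EEEE"; SQ values are lists of item element-lists.
parse_elements <- function(con, explicit, limit = NULL) {
  out <- list()
  consumed <- 0
  repeat {
    if (!is.null(limit) && consumed >= limit) break
    g <- tryCatch(read_u16(con), error = function(e) NULL)
    if (is.null(g) || length(g) == 0L) break
    e <- read_u16(con)
    consumed <- consumed + 4
    if (g == 0xFFFE) {              # item / delimitation
      len <- read_u32(con); consumed <- consumed + 4
      if (e == 0xE00D || e == 0xE0DD) break   # end of item / sequence
      stop("unexpected item tag outside sequence")
    }
    if (explicit && g != 0xFFFE) {
      vr <- rawToChar(readBin(con, "raw", 2L))
      consumed <- consumed + 2
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        readBin(con, "raw", 2L)                 # reserved
        len <- read_u32(con)
        consumed <- consumed + 6
      } else {
        len <- read_u16(con)
        consumed <- consumed + 2
      }
    } else {
      vr <- NA_character_
      len <- read_u32(con)
      consumed <- consumed + 4
    }
    key <- tag_key(g, e)
    if (!is.na(vr) && vr == "SQ" || (is.na(vr) && len == 0xFFFFFFFF)) {
      items <- parse_sequence(con, explicit, if (len == 0xFFFFFFFF) NULL else len)
      out[[key]] <- items$value
      consumed <- consumed + items$consumed
    } else if (len == 0xFFFFFFFF) {
      items <- parse_sequence(con, explicit, NULL)
      out[[key]] <- items$value
      consumed <- consumed + items$consumed
    } else {
      val <- readBin(con, "raw", len)
      consumed <- consumed + len
      out[[key]] <- val
    }
  }
  attr(out, "bytes") <- consumed
  out
}

# Parse sequence items; `limit` = declared byte length or NULL (undefined).
parse_sequence <- function(con, explicit, limit) {
  items <- list()
  consumed <- 0
  repeat {
    if (!is.null(limit) && consumed >= limit) break
    g <- read_u16(con)
    if (is.null(g) || length(g) == 0L) break
    e <- read_u16(con)
    len <- read_u32(con)
    consumed <- consumed + 8
    if (g == 0xFFFE && e == 0xE0DD) break     # sequence delimiter
    if (!(g == 0xFFFE && e == 0xE000)) stop("malformed sequence item")
    itlen <- if (len == 0xFFFFFFFF) NULL else len
    elems <- parse_elements(con, explicit, itlen)
    # parse_elements consumed itlen bytes, or up to the item delimiter (8
    # bytes of delimiter already swallowed by its loop)
    sz <- attr(elems, "bytes")
    items[[length(items) + 1L]] <- elems
    if (!is.null(itlen)) consumed <- consumed + itlen
    else consumed <- consumed + (sz %||% 0)
  }
  list(value = items, consumed = consumed)
}

dcm_string <- function(el) {
  if (is.null(el)) return(NULL)
  s <- rawToChar(el[el != as.raw(0L)])
  trimws(s)
}

dcm_numbers <- function(el) {
  s <- dcm_string(el)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_u16s <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el, "integer", length(el) %/% 2L, size = 2L, signed = FALSE, endian = "little")
}

#' Read a single DICOM file into a tag list
#'
#' Low-level reader for uncompressed little-endian DICOM. Returns a named
#' list of raw element values keyed `"GGGG,EEEE"`; sequences are nested
#' lists of items.
#'
#' @param path file path.
#' @return named list of elements (raw vectors / item lists).
#' @export
read_dicom_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  pre <- readBin(con, "raw", 132L)
  explicit <- TRUE
  if (length(pre) >= 132L && rawToChar(pre[129:132]) == "DICM") {
    # file meta group is always explicit VR; read it to get the transfer syntax
    meta <- list()
    repeat {
      pos <- seek(con, NA)
      g <- read_u16(con)
      if (length(g) == 0L) break
      if (g != 0x0002) { seek(con, pos); break }
      e <- read_u16(con)
      vr <- rawToChar(readBin(con, "raw", 2L))
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        readBin(con, "raw", 2L); len <- read_u32(con)
      } else len <- read_u16(con)
      meta[[tag_key(g, e)]] <- readBin(con, "raw", len)
    }
    ts <- dcm_string(meta[["0002,0010"]])
    if (!is.null(ts) && ts == DCM_IMPLICIT) explicit <- FALSE
  } else {
    # no preamble: sniff explicit VR from bytes 5-6 of the stream
    seek(con, 0L)
    probe <- readBin(con, "raw", 6L)
    seek(con, 0L)
    vrchars <- rawToChar(probe[5:6])
    explicit <- grepl("^[A-Z]{2}$", vrchars)
  }
  parse_elements(con, explicit)
}

slice_from_elements <- function(el) {
  rows <- dcm_u16s(el[["0028,0010"]])
  cols <- dcm_u16s(el[["0028,0011"]])
  if (is.null(rows) || is.null(cols)) stop("DICOM file has no image dimensions")
  bits <- dcm_u16s(el[["0028,0100"]]) %||% 16L
  if (bits != 16L) stop("only 16-bit DICOM pixel data supported")
  signed <- (dcm_u16s(el[["0028,0103"]]) %||% 0L) == 1L
  px <- el[["7FE0,0010"]]
  if (is.null(px)) stop("DICOM file has no pixel data")
  v <- readBin(px, "integer", rows * cols, size = 2L, signed = signed, endian = "little")
  if (!signed) v[v < 0] <- v[v < 0] + 65536L
  slope <- dcm_numbers(el[["0028,1053"]]) %||% 1
  inter <- dcm_numbers(el[["0028,1052"]]) %||% 0
  m <- matrix(v * slope + inter, nrow = rows, ncol = cols, byrow = TRUE)
  ipp <- dcm_numbers(el[["0020,0032"]]) %||% c(0, 0, 0)
  iop <- dcm_numbers(el[["0020,0037"]]) %||% c(1, 0, 0, 0, 1, 0)
  ps <- dcm_numbers(el[["0028,0030"]]) %||% c(1, 1)
  list(pixels = m, ipp = ipp, iop = iop, pixel_spacing = ps,
       thickness = dcm_numbers(el[["0018,0050"]]) %||% NA_real_,
       modality = dcm_string(el[["0008,0060"]]))
}

#' Read a DICOM slice series directory
#'
#' Slices are sorted by the projection of ImagePositionPatient on the slice
#' normal, ascending. All slices must share one orientation. CT values are
#' returned in HU (rescale applied); MR values are shifted non-negative.
#'
#' @param path directory containing one slice per file.
#' @param modality fallback modality when the files carry no Modality tag.
#' @return An [intensity_volume].
#' @export
read_dicom_series <- function(path, modality = c("MR", "CT")) {
  modality <- match.arg(modality)
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory")
  slices <- lapply(files, function(f) slice_from_elements(read_dicom_file(f)))
  iop0 <- slices[[1]]$iop
  ok <- vapply(slices, function(s) isTRUE(all.equal(s$iop, iop0, tolerance = 1e-6)), TRUE)
  if (!all(ok)) stop("mixed-orientation DICOM series")
  normal <- c(iop0[2] * iop0[6] - iop0[3] * iop0[5],
              iop0[3] * iop0[4] - iop0[1] * iop0[6],
              iop0[1] * iop0[5] - iop0[2] * iop0[4])
  zpos <- vapply(slices, function(s) sum(s$ipp * normal), 0.0)
  ordq <- order(zpos)
  slices <- slices[ordq]
  zpos <- zpos[ordq]
  nz <- length(slices)
  dz <- if (nz > 1L) median(diff(zpos)) else slices[[1]]$thickness
  if (!is.finite(dz) || is.na(dz) || dz <= 0) stop("missing spacing in DICOM series")
  ps <- slices[[1]]$pixel_spacing
  if (is.null(ps) || any(!is.finite(ps))) stop("missing spacing in DICOM series")
  nr <- nrow(slices[[1]]$pixels); ncl <- ncol(slices[[1]]$pixels)
  a <- array(0, c(nz, nr, ncl))
  for (k in seq_len(nz)) a[k, , ] <- slices[[k]]$pixels
  mod <- slices[[1]]$modality %||% modality
  if (!mod %in% c("MR", "CT")) mod <- modality
  if (mod == "MR" && min(a) < 0) a <- a - min(a)
  intensity_volume(a, spacing_mm = c(dz, ps[1], ps[2]), modality = mod)
}

# --- writing --------------------------------------------------------------

u16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
u32_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

element_raw <- function(group, element, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(paste(value, collapse = "\\"))
    if (length(value) %% 2L == 1L)
      value <- c(value, if (vr %in% c("UI")) as.raw(0L) else charToRaw(" "))
  }
  hdr <- c(u16_raw(group), u16_raw(element))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, charToRaw(vr), as.raw(c(0, 0)), u32_raw(length(value)), value)
  } else {
    c(hdr, charToRaw(vr), u16_raw(length(value)), value)
  }
}

dicom_file_raw <- function(elements, sop_class, sop_instance) {
  meta <- c(
    element_raw(0x0002, 0x0002, "UI", sop_class),
    element_raw(0x0002, 0x0003, "UI", sop_instance),
    element_raw(0x0002, 0x0010, "UI", DCM_EXPLICIT)
  )
  grouplen <- element_raw(0x0002, 0x0000, "UL", writeBin(length(meta), raw(), size = 4L, endian = "little"))
  c(raw(128L), charToRaw("DICM"), grouplen, meta, elements)
}

#' Write a CT volume as a DICOM slice series
#'
#' One explicit-VR little-endian CT file per axial slice, with
#' RescaleSlope 1 and RescaleIntercept -1024 (values stored as uint16).
#'
#' @param hu 3D array of HU values (already clipped to `[-1024, 3071]`).
#' @param spacing_mm `(dz, dy, dx)` spacing.
#' @param dir output directory (created if missing).
#' @export
write_dicom_series <- function(hu, spacing_mm, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(hu)
  uid_base <- "1.2.826.0.1.3680043.9.9999"
  for (k in seq_len(d[1])) {
    stored <- as.integer(round(hu[k, , ])) + 1024L
    px <- writeBin(as.vector(t(matrix(stored, d[2], d[3]))), raw(), size = 2L, endian = "little")
    sop_inst <- sprintf("%s.1.%d", uid_base, k)
    el <- c(
      element_raw(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      element_raw(0x0008, 0x0018, "UI", sop_inst),
      element_raw(0x0008, 0x0060, "CS", "CT"),
      element_raw(0x0020, 0x000D, "UI", paste0(uid_base, ".2")),
      element_raw(0x0020, 0x000E, "UI", paste0(uid_base, ".3")),
      element_raw(0x0020, 0x0013, "IS", as.character(k)),
      element_raw(0x0020, 0x0032, "DS", sprintf("%g\\%g\\%g", 0, 0, (k - 1) * spacing_mm[1])),
      element_raw(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      element_raw(0x0028, 0x0002, "US", u16_raw(1L)),
      element_raw(0x0028, 0x0004, "CS", "MONOCHROME2"),
      element_raw(0x0028, 0x0010, "US", u16_raw(d[2])),
      element_raw(0x0028, 0x0011, "US", u16_raw(d[3])),
      element_raw(0x0028, 0x0030, "DS", sprintf("%g\\%g", spacing_mm[2], spacing_mm[3])),
      element_raw(0x0018, 0x0050, "DS", sprintf("%g", spacing_mm[1])),
      element_raw(0x0028, 0x0100, "US", u16_raw(16L)),
      element_raw(0x0028, 0x0101, "US", u16_raw(16L)),
      element_raw(0x0028, 0x0102, "US", u16_raw(15L)),
      element_raw(0x0028, 0x0103, "US", u16_raw(0L)),
      element_raw(0x0028, 0x1052, "DS", "-1024"),
      element_raw(0x0028, 0x1053, "DS", "1"),
      element_raw(0x7FE0, 0x0010, "OW", px)
    )
    writeBin(dicom_file_raw(el, "1.2.840.10008.5.1.4.1.1.2", sop_inst),
             file.path(dir, sprintf("slice%04d.dcm", k)))
  }
  invisible(dir)
}
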