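# Minimal DICOM parser for uncompressed single-frame axial CT series.
# Supports implicit VR little endian (1.2.840.10008.1.2) and explicit VR
# little endian (1.2.840.10008.1.2.1). Only the tags needed to reconstruct
# the volume and its geometry are decoded; everything else is skipped.
# Sequences and undefined-length elements are not supported (they do not
# occur in the image-level tags read here; files carrying them in other
# elements are rejected rather than misparsed).

.u16 <- function(raw, pos) {
  readBin(raw[pos:(pos + 1L)], "integer", size = 2L, signed = FALSE,
          endian = "little")
}
.u32 <- function(raw, pos) {
  v <- readBin(raw[pos:(pos + 3L)], "integer", size = 4L, endian = "little")
  if (v < 0) v <- v + 2^32
  v
}
.tag_key <- function(group, element) sprintf("%04x,%04x", group, element)

# VRs whose explicit-VR length field is 4 bytes after 2 reserved bytes
.LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# Tags we decode; everything else is skipped over.
.WANTED <- c("0008,0018", "0020,000e", "0020,0032", "0020,0037",
             "0028,0010", "0028,0011", "0028,0030", "0028,0100",
             "0028,0103", "0028,1052", "0028,1053", "7fe0,0010")

.parse_dicom_elements <- function(raw, pos, end, explicit) {
  out <- list()
  while (pos + 7L <= end) {
    group <- .u16(raw, pos)
    element <- .u16(raw, pos + 2L)
    if (explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% .LONG_VRS) {
        len <- .u32(raw, pos + 8L)
        hdr <- 12L
      } else {
        len <- .u16(raw, pos + 6L)
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- .u32(raw, pos + 4L)
      hdr <- 8L
    }
    if (len == 4294967295) {
      stop("undefined-length DICOM element (", .tag_key(group, element),
           ") not supported")
    }
    key <- .tag_key(group, element)
    if (key %in% .WANTED) {
      out[[key]] <- raw[(pos + hdr):(pos + hdr + len - 1L)]
      if (key == "7fe0,0010") break
    }
    pos <- pos + hdr + len
  }
  out
}

.dcm_str <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el[el != as.raw(0)]))
}
.dcm_ds <- function(el) {
  s <- .dcm_str(el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
.dcm_us <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el, "integer", size = 2L, signed = FALSE, endian = "little")
}

.read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 136L || rawToChar(raw[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path)
  }
  # file meta group (0002) is always explicit little endian
  pos <- 133L
  group <- .u16(raw, pos)
  element <- .u16(raw, pos + 2L)
  if (group != 2L || element != 0L) stop("missing file meta group length: ", path)
  meta_len <- .u32(raw, pos + 8L)
  meta_end <- pos + 12L + meta_len - 1L
  meta <- .parse_dicom_meta(raw, pos, meta_end)
  ts <- meta[["0002,0010"]]
  if (is.null(ts)) stop("missing transfer syntax UID: ", path)
  explicit <- switch(ts,
    "1.2.840.10008.1.2"   = FALSE,
    "1.2.840.10008.1.2.1" = TRUE,
    stop("unsupported transfer syntax '", ts, "' in ", path,
         " (only uncompressed little endian is supported)")
  )
  els <- .parse_dicom_elements(raw, meta_end + 1L, length(raw), explicit)

  rows <- .dcm_us(els[["0028,0010"]])
  cols <- .dcm_us(els[["0028,0011"]])
  bits <- .dcm_us(els[["0028,0100"]])
  pixrep <- .dcm_us(els[["0028,0103"]])
  if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns: ", path)
  if (is.null(bits) || bits != 16L) {
    stop("only 16-bit DICOM pixel data is supported: ", path)
  }
  slope <- .dcm_ds(els[["0028,1053"]])
  intercept <- .dcm_ds(els[["0028,1052"]])
  if (is.null(slope) || is.null(intercept)) {
    stop("missing RescaleSlope/RescaleIntercept (cannot convert to HU): ", path)
  }
  ps <- .dcm_ds(els[["0028,0030"]])
  ipp <- .dcm_ds(els[["0020,0032"]])
  iop <- .dcm_ds(els[["0020,0037"]])
  if (is.null(ps) || length(ps) != 2L) stop("missing PixelSpacing: ", path)
  if (is.null(ipp) || length(ipp) != 3L) stop("missing ImagePositionPatient: ", path)
  if (is.null(iop) || length(iop) != 6L) stop("missing ImageOrientationPatient: ", path)
  pix <- els[["7fe0,0010"]]
  if (is.null(pix)) stop("missing PixelData: ", path)
  stored <- readBin(pix, "integer", size = 2L, n = rows * cols,
                    signed = !is.null(pixrep) && pixrep == 1L,
                    endian = "little")
  list(
    series_uid = .dcm_str(els[["0020,000e"]]),
    rows = rows, cols = cols,
    # PixelSpacing is (row spacing, column spacing) = (y, x)
    spacing_xy = c(ps[2], ps[1]),
    ipp = ipp, iop = iop,
    slope = slope, intercept = intercept,
    # PixelData is row-major: filling with nrow = cols gives [x = col, y = row]
    hu = matrix(stored * slope + intercept, nrow = cols, ncol = rows)
  )
}

.parse_dicom_meta <- function(raw, pos, meta_end) {
  out <- list()
  while (pos + 7L <= meta_end) {
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% .LONG_VRS) {
      len <- .u32(raw, pos + 8L); hdr <- 12L
    } else {
      len <- .u16(raw, pos + 6L); hdr <- 8L
    }
    key <- .tag_key(.u16(raw, pos), .u16(raw, pos + 2L))
    val <- raw[(pos + hdr):(pos + hdr + len - 1L)]
    if (key == "0002,0010") out[[key]] <- .dcm_str(val)
    pos <- pos + hdr + len
  }
  out
}

#' Read a single axial CT series from a directory of DICOM files
#'
#' All files in the directory must belong to one series. Slices are sorted
#' by their spatial position along the slice normal (never by file name),
#' the rescale slope/intercept is applied so voxel values are Hounsfield
#' units, and the DICOM LPS geometry is converted to the package's RAS
#' convention.
#'
#' @param directory Directory containing the `.dcm` files of one series.
#' @return A [ct_volume()].
#' @details Mixed series, missing rescale tags, non-uniform slice gaps and
#'   non-axial acquisitions are rejected with explicit errors. Only
#'   uncompressed little-endian transfer syntaxes are supported.
#' @export
read_dicom_series <- function(directory) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in ", directory)
  slices <- lapply(files, .read_dicom_file)

  uids <- unique(vapply(slices, function(s) s$series_uid %||% "", ""))
  if (length(uids) != 1L) {
    stop("directory holds ", length(uids), " series (",
         paste(uids, collapse = ", "), "); expected exactly one")
  }
  iop <- slices[[1]]$iop
  for (s in slices) {
    if (max(abs(s$iop - iop)) > 1e-4) stop("inconsistent slice orientation")
    if (s$rows != slices[[1]]$rows || s$cols != slices[[1]]$cols) {
      stop("inconsistent slice dimensions")
    }
  }
  xdir <- iop[1:3]  # direction of increasing column index
  ydir <- iop[4:6]  # direction of increasing row index
  normal <- c(xdir[2] * ydir[3] - xdir[3] * ydir[2],
              xdir[3] * ydir[1] - xdir[1] * ydir[3],
              xdir[1] * ydir[2] - xdir[2] * ydir[1])
  if (abs(abs(normal[3]) - 1) > 1e-3) {
    stop("non-axial acquisition (slice normal ",
         paste(sprintf("%.3f", normal), collapse = ", "),
         "); this pipeline is defined on axial slices")
  }
  zpos <- vapply(slices, function(s) sum(s$ipp * normal), 0)
  ord <- order(zpos)
  slices <- slices[ord]
  zpos <- zpos[ord]
  nz <- length(slices)
  if (nz > 1L) {
    gaps <- diff(zpos)
    if (any(gaps <= 0)) stop("duplicate slice positions in series")
    if (max(gaps) - min(gaps) > 1e-3 * mean(gaps) + 1e-6) {
      stop(sprintf("non-uniform slice spacing (gaps %.4f-%.4f mm)",
                   min(gaps), max(gaps)))
    }
    dz <- mean(gaps)
  } else {
    dz <- 1
  }
  vox <- array(0, dim = c(slices[[1]]$cols, slices[[1]]$rows, nz))
  for (k in seq_len(nz)) vox[, , k] <- slices[[k]]$hu

  lps2ras <- diag(c(-1, -1, 1))
  direction <- lps2ras %*% cbind(xdir, ydir, normal)
  dimnames(direction) <- NULL
  origin <- drop(lps2ras %*% slices[[1]]$ipp)
  ct_volume(voxels = vox,
            spacing = c(slices[[1]]$spacing_xy, dz),
            origin = origin, direction = direction)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
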