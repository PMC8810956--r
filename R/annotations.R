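#' Read lesion-center fiducials from a 3D Slicer FCSV file
#'
#' Parses the comma-separated fiducial format written by 3D Slicer's
#' Markups module. Header lines begin with `#`; the `CoordinateSystem`
#' header decides whether the stored points are RAS (`RAS` or `0`) or LPS
#' (`LPS` or `1`). LPS points are sign-converted so the returned
#' coordinates are always RAS millimetres.
#'
#' @param path Path to an `.fcsv` file.
#' @return A data frame with columns `label`, `r`, `a`, `s` (one row per
#'   fiducial; zero rows for a comment-only file).
#' @export
read_fiducials <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_comment <- startsWith(trimws(lines), "#") | trimws(lines) == ""
  coord_sys <- "RAS"
  cs_line <- grep("CoordinateSystem", lines[is_comment], value = TRUE)
  if (length(cs_line)) {
    val <- trimws(sub(".*=", "", cs_line[1]))
    coord_sys <- switch(val,
                        "0" = "RAS", "RAS" = "RAS",
                        "1" = "LPS", "LPS" = "LPS",
                        stop("unknown CoordinateSystem '", val, "' in ", path))
  }
  rows <- which(!is_comment)
  out <- data.frame(label = character(0), r = numeric(0), a = numeric(0),
                    s = numeric(0), stringsAsFactors = FALSE)
  for (i in rows) {
    fields <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(fields) < 4L) {
      stop("malformed fiducial row at line ", i, " of ", path,
           " (fewer than 4 fields)")
    }
    xyz <- suppressWarnings(as.numeric(fields[2:4]))
    if (any(is.na(xyz))) {
      stop("malformed fiducial row at line ", i, " of ", path,
           " (non-numeric coordinates)")
    }
    label <- if (length(fields) >= 12L && nzchar(fields[12])) fields[12] else fields[1]
    if (coord_sys == "LPS") xyz[1:2] <- -xyz[1:2]
    out <- rbind(out, data.frame(label = label, r = xyz[1], a = xyz[2],
                                 s = xyz[3], stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Write lesion centers as a 3D Slicer FCSV fiducial file
#'
#' @param points Data frame with columns `label`, `r`, `a`, `s` (RAS mm),
#'   as returned by [read_fiducials()].
#' @param path Output `.fcsv` path.
#' @return `path`, invisibly.
#' @export
write_fiducials <- function(points, path) {
  stopifnot(all(c("label", "r", "a", "s") %in% names(points)))
  hdr <- c("# Markups fiducial file version = 4.11",
           "# CoordinateSystem = RAS",
           "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID")
  body <- vapply(seq_len(nrow(points)), function(i) {
    sprintf("F_%d,%.6f,%.6f,%.6f,0,0,0,1,1,1,0,%s,,",
            i, points$r[i], points$a[i], points$s[i], points$label[i])
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write plain lesion coordinate tables
#'
#' CSV tables with columns `case_id, x, y, z` holding 0-based voxel indices
#' of lesion centers — the phantom generator's native annotation format.
#'
#' @param path CSV path.
#' @return `read_lesion_table()`: a data frame with columns
#'   `case_id, x, y, z` (integer voxel indices).
#' @export
read_lesion_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("lesion table must have columns ", paste(need, collapse = ", "))
  }
  df$x <- as.integer(df$x); df$y <- as.integer(df$y); df$z <- as.integer(df$z)
  df[need]
}

#' @rdname read_lesion_table
#' @param lesions Data frame with columns `case_id, x, y, z`.
#' @export
write_lesion_table <- function(lesions, path) {
  utils::write.csv(lesions[c("case_id", "x", "y", "z")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach voxel indices to RAS fiducials for a given volume
#'
#' @param fiducials Data frame from [read_fiducials()].
#' @param volume The [ct_volume()] the fiducials were placed on.
#' @param case_id Case identifier recorded with each annotation.
#' @return Data frame with columns `case_id, label, r, a, s, x, y, z` where
#'   `x, y, z` are 0-based voxel indices.
#' @export
lesion_annotations <- function(fiducials, volume, case_id) {
  vox <- t(vapply(seq_len(nrow(fiducials)), function(i) {
    ras_to_voxel(volume, c(fiducials$r[i], fiducials$a[i], fiducials$s[i]))
  }, integer(3)))
  cbind(data.frame(case_id = rep(case_id, nrow(fiducials)),
                   stringsAsFactors = FALSE),
        fiducials,
        data.frame(x = vox[, 1], y = vox[, 2], z = vox[, 3]))
}
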