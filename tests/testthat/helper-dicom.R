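# Writes a synthetic DICOM CT series with pydicom (the independent oracle
# writer); our reader is tested against files we did not produce ourselves.

python_available <- local({
  ok <- NULL
  function() {
    if (is.null(ok)) {
      ok <<- nzchar(Sys.which("python")) &&
        system2("python", c("-c", shQuote("import pydicom")),
                stdout = FALSE, stderr = FALSE) == 0
    }
    ok
  }
})

# hu: 3D integer array [x, y, z]; origin_lps in mm; writes one file per
# slice, optionally shuffled on disk, with the given rescale pair
write_dicom_series_py <- function(hu, dir, spacing = c(0.7, 0.7, 3.0),
                                  origin_lps = c(0, 0, 0), slope = 1,
                                  intercept = -1024, series_uid = "1.2.3.4",
                                  shuffle = FALSE, omit_rescale = FALSE,
                                  reverse_on_disk = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(hu)
  stored <- round((hu - intercept) / slope)
  storage.mode(stored) <- "integer"  # keep the array dims
  npy <- file.path(dir, "stored.txt")
  # stored values slice by slice in row-major order (y outer, x inner);
  # with the [x, y] matrix layout that is plain column-major order
  mat_lines <- vapply(seq_len(d[3]), function(z) {
    paste(as.vector(stored[, , z]), collapse = " ")
  }, "")
  writeLines(mat_lines, npy)
  script <- file.path(dir, "make_series.py")
  writeLines(sprintf('
import pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
import struct, os

outdir = %s
nx, ny, nz = %d, %d, %d
sx, sy, sz = %f, %f, %f
ox, oy, oz = %f, %f, %f
slope, intercept = %f, %f
series_uid = %s
omit_rescale = %s
shuffle = %s
reverse_on_disk = %s

rows = []
with open(os.path.join(outdir, "stored.txt")) as f:
    for line in f:
        rows.append([int(v) for v in line.split()])

order = list(range(nz))
names = ["slice_%%03d.dcm" %% i for i in range(nz)]
if reverse_on_disk:
    names = names[::-1]
if shuffle:
    names = names[1:] + names[:1]

for k in order:
    ds = Dataset()
    meta = FileMetaDataset()
    meta.MediaStorageSOPClassUID = pydicom.uid.CTImageStorage
    meta.MediaStorageSOPInstanceUID = generate_uid()
    meta.TransferSyntaxUID = ExplicitVRLittleEndian
    ds.file_meta = meta
    ds.SOPClassUID = pydicom.uid.CTImageStorage
    ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
    ds.Modality = "CT"
    ds.SeriesInstanceUID = series_uid
    ds.Rows = ny
    ds.Columns = nx
    ds.PixelSpacing = [str(sy), str(sx)]
    ds.ImagePositionPatient = [str(ox), str(oy), str(oz + k * sz)]
    ds.ImageOrientationPatient = ["1", "0", "0", "0", "1", "0"]
    ds.BitsAllocated = 16
    ds.BitsStored = 16
    ds.HighBit = 15
    ds.PixelRepresentation = 1
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    if not omit_rescale:
        ds.RescaleSlope = str(slope)
        ds.RescaleIntercept = str(intercept)
    vals = rows[k]
    ds.PixelData = struct.pack("<%%dh" %% len(vals), *vals)
    ds.is_little_endian = True
    ds.is_implicit_VR = False
    ds.save_as(os.path.join(outdir, names[k]), enforce_file_format=True)
os.remove(os.path.join(outdir, "stored.txt"))
os.remove(os.path.join(outdir, "make_series.py"))
',
    deparse(dir), d[1], d[2], d[3], spacing[1], spacing[2], spacing[3],
    origin_lps[1], origin_lps[2], origin_lps[3], slope, intercept,
    deparse(series_uid),
    if (omit_rescale) "True" else "False",
    if (shuffle) "True" else "False",
    if (reverse_on_disk) "True" else "False"), script)
  status <- system2("python", shQuote(script), stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status"))) {
    stop("pydicom fixture writer failed: ", paste(status, collapse = "\n"))
  }
  invisible(dir)
}
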