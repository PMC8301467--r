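# Volume file I/O: minimal NIfTI-1 (.nii / .nii.gz) and MetaImage (.mha).
# Only the subset needed to round-trip grids with spacing and origin is
# implemented; axes are written in the package's (x, y, z) storage order.

nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L)
)

guess_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.(mha|mhd)$", lp)) return("metaimage")
  if (grepl("\\.(tif|tiff)$", lp)) return("tiff_stack")
  stop("cannot guess volume format from extension of: ", path)
}

#' Read a volume from disk
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) and MetaImage (`.mha`, LOCAL
#' payload). Intensities are returned unmodified; spacing and origin are
#' taken from the header. TIFF stacks are not supported by this build and
#' produce an error naming the missing capability.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"nifti"`, `"metaimage"`, or
#'   `"tiff_stack"`.
#' @return an [volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "metaimage", "tiff_stack")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("volume file does not exist: ", path)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    nifti = read_nifti(path),
    metaimage = read_metaimage(path),
    tiff_stack = stop("tiff_stack input is not supported by this build; ",
                      "convert to NIfTI or MetaImage (spacing metadata ",
                      "must travel in the header)")
  )
}

#' Write a volume to disk
#'
#' @param vol an [volume()].
#' @param path output path; `.nii`, `.nii.gz` or `.mha` select the format.
#' @param datatype storage type: `"float64"` (default, lossless for R
#'   doubles) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = c("float64", "float32")) {
  stopifnot_volume(vol)
  datatype <- match.arg(datatype)
  fmt <- guess_format(path)
  switch(fmt,
    nifti = write_nifti(vol, path, datatype),
    metaimage = write_metaimage(vol, path, datatype),
    stop("unsupported output format for: ", path)
  )
  invisible(path)
}

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", tolower(path))) gzfile(path, mode) else file(path, mode)
}

write_nifti <- function(vol, path, datatype) {
  code <- if (datatype == "float64") 64L else 16L
  dt <- nifti_datatypes[[as.character(code)]]
  d <- dim(vol$data)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wchar <- function(s, n) {
    r <- raw(n)
    b <- charToRaw(s)
    if (length(b)) r[seq_along(b)] <- b[seq_len(min(n, length(b)))]
    writeBin(r, con)
  }
  wb(348L, 4)                       # sizeof_hdr
  wchar("", 10); wchar("", 18)      # data_type, db_name
  wb(0L, 4); wb(0L, 2)              # extents, session_error
  wchar("r", 1); wchar("", 1)       # regular, dim_info
  wb(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), 2)       # dim[8]
  wb(numeric(3), 4)                 # intent_p1..p3
  wb(0L, 2); wb(code, 2); wb(dt$bitpix, 2); wb(0L, 2) # intent, datatype, bitpix, slice_start
  wb(c(1, vol$spacing, 0, 0, 0, 0), 4)              # pixdim[8], qfac = 1
  wb(352, 4)                        # vox_offset
  wb(c(1, 0), 4)                    # scl_slope, scl_inter
  wb(0L, 2); wchar("", 1)           # slice_end, slice_code
  writeBin(as.raw(2L), con)         # xyzt_units = mm
  wb(numeric(4), 4)                 # cal_max, cal_min, slice_duration, toffset
  wb(c(0L, 0L), 4)                  # glmax, glmin
  wchar("mandimorph", 80); wchar("", 24)            # descrip, aux_file
  wb(0L, 2); wb(1L, 2)              # qform_code = 0, sform_code = 1
  wb(numeric(3), 4)                 # quaternion
  wb(vol$origin, 4)                 # qoffset (informational)
  wb(c(vol$spacing[1], 0, 0, vol$origin[1]), 4)     # srow_x
  wb(c(0, vol$spacing[2], 0, vol$origin[2]), 4)     # srow_y
  wb(c(0, 0, vol$spacing[3], vol$origin[3]), 4)     # srow_z
  wchar("", 16); wchar("n+1", 4)    # intent_name, magic
  writeBin(raw(4), con)             # no header extensions
  writeBin(as.vector(vol$data), con, size = dt$size, endian = "little")
  path
}

read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in: ", path)
  endian <- "little"
  rb <- function(off, what, n, size, signed = TRUE)
    readBin(hdr[(off + 1L):348L], what, n = n, size = size,
            endian = endian, signed = signed)
  if (rb(0, "integer", 1, 4) != 348L) {
    endian <- "big"
    if (rb(0, "integer", 1, 4) != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  dim8 <- rb(40, "integer", 8, 2)
  ndim <- dim8[1]
  if (ndim < 3L) stop("NIfTI volume must be 3D: ", path)
  d <- dim8[2:4]
  if (ndim > 3L && any(dim8[5:(ndim + 1)] > 1L))
    stop("NIfTI file has more than 3 non-singleton dimensions: ", path)
  code <- rb(70, "integer", 1, 2)
  dt <- nifti_datatypes[[as.character(code)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", code, " in: ", path)
  pixdim <- rb(76, "double", 8, 4)
  spacing <- pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("missing or invalid voxel spacing (pixdim) in NIfTI header: ", path)
  vox_offset <- rb(108, "double", 1, 4)
  sform_code <- rb(254, "integer", 1, 2)
  origin <- c(0, 0, 0)
  if (sform_code > 0L) {
    srow <- rbind(rb(280, "double", 4, 4), rb(296, "double", 4, 4),
                  rb(312, "double", 4, 4))
    origin <- srow[, 4]
  }
  scl_slope <- rb(112, "double", 1, 4)
  scl_inter <- rb(116, "double", 1, 4)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(d)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) < n) stop("truncated NIfTI data in: ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  volume(array(as.numeric(vals), d), spacing, origin)
}

metaimage_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "double",  size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double",  size = 8L, signed = TRUE)
)

write_metaimage <- function(vol, path, datatype) {
  met <- if (datatype == "float64") "MET_DOUBLE" else "MET_FLOAT"
  ty <- metaimage_types[[met]]
  d <- dim(vol$data)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(vol$origin, digits = 17), collapse = " ")),
    paste("ElementSpacing =", paste(format(vol$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(d, collapse = " ")),
    paste("ElementType =", met),
    "ElementDataFile = LOCAL"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  writeBin(as.vector(vol$data), con, size = ty$size, endian = "little")
  path
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_line <- function() {
    out <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0L || b == as.raw(10L)) break
      out <- c(out, b)
    }
    rawToChar(out)
  }
  fields <- list()
  repeat {
    ln <- read_line()
    if (!nzchar(ln)) stop("unterminated MetaImage header in: ", path)
    kv <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", ln)
    fields[[kv[2]]] <- kv[3]
    if (kv[2] == "ElementDataFile") break
  }
  need <- function(key) {
    if (is.null(fields[[key]]))
      stop("MetaImage header missing required field `", key, "` in: ", path)
    fields[[key]]
  }
  if (need("ElementDataFile") != "LOCAL")
    stop("only ElementDataFile = LOCAL MetaImage files are supported: ", path)
  if (!is.null(fields$CompressedData) &&
      tolower(fields$CompressedData) == "true")
    stop("compressed MetaImage payloads are not supported: ", path)
  d <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  if (length(d) != 3L) stop("MetaImage volume must be 3D: ", path)
  spacing <- as.numeric(strsplit(need("ElementSpacing"), "\\s+")[[1]])
  origin <- if (is.null(fields$Offset)) c(0, 0, 0)
            else as.numeric(strsplit(fields$Offset, "\\s+")[[1]])
  ty <- metaimage_types[[need("ElementType")]]
  if (is.null(ty)) stop("unsupported MetaImage ElementType: ", fields$ElementType)
  msb <- !is.null(fields$BinaryDataByteOrderMSB) &&
    tolower(fields$BinaryDataByteOrderMSB) == "true"
  n <- prod(d)
  vals <- readBin(con, ty$what, n = n, size = ty$size,
                  endian = if (msb) "big" else "little", signed = ty$signed)
  if (length(vals) < n) stop("truncated MetaImage data in: ", path)
  volume(array(as.numeric(vals), d), spacing, origin)
}
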