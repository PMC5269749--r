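#' Read and write attenuation volumes
#'
#' Volumes are stored either as MetaImage (`.mha` single-file or `.mhd` +
#' `.raw` pair, 32-bit float, little-endian, x-fastest) or as multi-page
#' 32-bit-float TIFF stacks (one page per z slice). A JSON sidecar
#' (`<path>.json`) carries the voxel size, origin and any provenance the
#' caller supplies; when it is missing on read, defaults are assumed with a
#' warning. Float data round-trip losslessly at single precision.
#'
#' @param volume A [volume3d()].
#' @param path Output path ending in `.mha`, `.mhd`, `.tif` or `.tiff`.
#' @param sidecar Optional named list merged into the JSON sidecar (e.g. a
#'   geometry block from [geometry_to_list()], seeds, configuration).
#' @return `write_volume`: the path, invisibly. `read_volume`: a
#'   [volume3d()].
#' @export
write_volume <- function(volume, path, sidecar = list()) {
  stopifnot(inherits(volume, "volume3d"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         mha = write_metaimage(volume, path, local = TRUE),
         mhd = write_metaimage(volume, path, local = FALSE),
         tif = ,
         tiff = write_tiff_float(volume$data, path),
         stop("unknown volume format '.", ext, "' (use .mha, .mhd or .tif)"))
  meta <- utils::modifyList(
    list(format = ext, dim = dim(volume$data),
         voxel_size_mm = volume$voxel_size, origin_mm = volume$origin,
         package = "auglam",
         version = as.character(utils::packageVersion("auglam"))),
    sidecar)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  ext <- tolower(tools::file_ext(path))
  dat <- switch(ext,
                mha = ,
                mhd = read_metaimage(path),
                tif = ,
                tiff = read_tiff_stack(path),
                stop("unknown volume format '.", ext, "'"))
  sc_path <- paste0(path, ".json")
  meta <- if (file.exists(sc_path)) {
    jsonlite::read_json(sc_path, simplifyVector = TRUE)
  } else {
    warning("missing sidecar ", basename(sc_path),
            "; assuming defaults for any unrecorded metadata")
    list()
  }
  voxel <- if (!is.null(meta$voxel_size_mm)) meta$voxel_size_mm
           else if (!is.null(dat$spacing)) dat$spacing[1] else 1
  origin <- if (!is.null(meta$origin_mm)) meta$origin_mm else dat$origin
  out <- volume3d(dat$data, voxel, origin)
  attr(out, "sidecar") <- meta
  out
}

# --- MetaImage ---------------------------------------------------------
# Minimal MetaImage support (MET_FLOAT, 3D, uncompressed): no installed R
# package reads or writes this format. Header keys follow the ITK
# conventions so files interoperate with standard MetaImage readers.

write_metaimage <- function(volume, path, local = TRUE) {
  d <- dim(volume$data)
  raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(format(volume$origin, digits = 17),
                                   collapse = " ")),
           paste("ElementSpacing =",
                 paste(rep(format(volume$voxel_size, digits = 17), 3),
                       collapse = " ")),
           paste("DimSize =", paste(d, collapse = " ")),
           "ElementType = MET_FLOAT",
           paste("ElementDataFile =", if (local) "LOCAL" else raw_name))
  if (local) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.numeric(volume$data), con, size = 4, endian = "little")
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(con))
    writeBin(as.numeric(volume$data), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("MetaImage header has no ElementDataFile key")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr$NDims, "3")) stop("expected a 3D MetaImage volume")
  if (!identical(hdr$ElementType, "MET_FLOAT"))
    stop("only MET_FLOAT MetaImage volumes are supported")
  if (identical(hdr$CompressedData, "True"))
    stop("compressed MetaImage volumes are not supported")
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else NULL
  msb <- identical(hdr$BinaryDataByteOrderMSB, "True")
  endian <- if (msb) "big" else "little"
  n <- prod(d)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    vals <- readBin(con, "numeric", n = n, size = 4, endian = endian)
  } else {
    rawfile <- file.path(dirname(path), hdr$ElementDataFile)
    vals <- readBin(rawfile, "numeric", n = n, size = 4, endian = endian)
  }
  if (length(vals) != n) stop("MetaImage raw data shorter than DimSize")
  list(data = array(vals, dim = d), spacing = spacing, origin = origin)
}

# --- TIFF --------------------------------------------------------------
# Reading goes through tiff::readTIFF (which handles 32-bit float sample
# data); writing floats is not supported by the tiff package, so the writer
# below emits a minimal uncompressed little-endian multi-IFD TIFF with
# SampleFormat = IEEE float, one z slice per page, verified round-trip
# against tiff::readTIFF.

read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2)
    stop("expected a 3D TIFF stack (one page per z slice), got a single ",
         "2D image")
  mats <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    t(p)  # readTIFF returns row-major (y, x); volumes are (x, y)
  })
  d <- dim(mats[[1]])
  arr <- array(unlist(mats), dim = c(d[1], d[2], length(mats)))
  list(data = arr, spacing = NULL, origin = NULL)
}

write_tiff_float <- function(data, path) {
  d <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)   # header, first IFD at 8
  n_entries <- 10L
  ifd_size <- 2 + n_entries * 12 + 4
  page_bytes <- d[1] * d[2] * 4
  offset <- 8
  for (k in seq_len(d[3])) {
    data_off <- offset + ifd_size
    next_ifd <- if (k < d[3]) data_off + page_bytes else 0L
    entry <- function(tag, type, count, value) {
      w2(tag); w2(type); w4(count); w4(value)
    }
    w2(n_entries)
    entry(256L, 3L, 1L, d[1])          # ImageWidth
    entry(257L, 3L, 1L, d[2])          # ImageLength
    entry(258L, 3L, 1L, 32L)           # BitsPerSample
    entry(259L, 3L, 1L, 1L)            # Compression: none
    entry(262L, 3L, 1L, 1L)            # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off)      # StripOffsets
    entry(277L, 3L, 1L, 1L)            # SamplesPerPixel
    entry(278L, 3L, 1L, d[2])          # RowsPerStrip
    entry(279L, 4L, 1L, page_bytes)    # StripByteCounts
    entry(339L, 3L, 1L, 3L)            # SampleFormat: IEEE float
    w4(next_ifd)
    # TIFF rows scan y; our arrays are (x, y): write row-major
    writeBin(as.numeric(data[, , k]), con, size = 4, endian = "little")
    offset <- data_off + page_bytes
  }
  invisible(path)
}
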