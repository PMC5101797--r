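# MetaImage (.mha / .mhd + .raw) reader and writer. Plain ASCII header plus
# an uncompressed binary raster; compressed files are rejected. Only the 3D
# scalar element types that angiographic exports actually use are handled.

metaimage_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_UINT   = list(what = "integer", size = 4L, signed = TRUE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

read_metaimage <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # header = ASCII "Key = value" lines up to and including ElementDataFile;
  # payload (if LOCAL) follows the newline of that line
  newlines <- which(bytes == as.raw(10L))
  hdr <- list()
  payload_start <- NA_integer_
  prev <- 0L
  for (nl in newlines) {
    line <- rawToChar(bytes[seq.int(prev + 1L, nl - 1L)])
    line <- sub("\r$", "", line)
    prev <- nl
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", line))[[1]]
    if (length(kv) != 3L)
      stop(sprintf("read_volume: malformed MetaImage header line: %s", line),
           call. = FALSE)
    hdr[[kv[2]]] <- kv[3]
    if (kv[2] == "ElementDataFile") {
      payload_start <- nl + 1L
      break
    }
  }
  if (is.null(hdr$ElementDataFile))
    stop(sprintf("read_volume: truncated MetaImage header in %s", path),
         call. = FALSE)

  ndims <- as.integer(hdr$NDims %||% "0")
  if (ndims != 3L)
    stop(sprintf("read_volume: %s is not a 3D image (NDims = %d)", path, ndims),
         call. = FALSE)
  if (isTRUE(toupper(hdr$CompressedData %||% "FALSE") == "TRUE"))
    stop(sprintf("read_volume: compressed MetaImage not supported: %s", path),
         call. = FALSE)
  dims <- as.integer(strsplit(trimws(hdr$DimSize), "\\s+")[[1]])
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop(sprintf("read_volume: bad DimSize in %s", path), call. = FALSE)
  type <- metaimage_types[[hdr$ElementType %||% ""]]
  if (is.null(type))
    stop(sprintf("read_volume: unsupported ElementType '%s' in %s",
                 hdr$ElementType, path), call. = FALSE)
  spacing <- as.numeric(strsplit(trimws(hdr$ElementSpacing %||% "1 1 1"),
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(trimws(hdr$Offset %||% "0 0 0"), "\\s+")[[1]])
  msb <- toupper(hdr$BinaryDataByteOrderMSB %||% "FALSE") == "TRUE"
  endian <- if (msb) "big" else "little"

  n <- prod(dims)
  datafile <- trimws(hdr$ElementDataFile)
  if (toupper(datafile) == "LOCAL") {
    raw <- readBin(bytes[seq.int(payload_start, length(bytes))],
                   what = type$what, n = n, size = type$size,
                   signed = type$signed, endian = endian)
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath))
      stop(sprintf("read_volume: raw data file not found: %s", rawpath),
           call. = FALSE)
    raw <- readBin(rawpath, what = type$what, n = n, size = type$size,
                   signed = type$signed, endian = endian)
  }
  if (length(raw) != n)
    stop(sprintf("read_volume: %s holds %d values, expected %d", path,
                 length(raw), n), call. = FALSE)
  volume3d(array(as.numeric(raw), dim = dims), spacing = spacing,
           origin = origin,
           meta = list(format = "metaimage",
                       transform = hdr$TransformMatrix))
}

write_metaimage <- function(vol, path) {
  d <- dim(vol$data)
  vals <- as.numeric(vol$data)
  # labels and small integer rasters go out compact, everything else as double
  int_like <- all(vals == round(vals)) && min(vals) >= 0 && max(vals) <= 255
  type <- if (int_like) "MET_UCHAR" else "MET_DOUBLE"
  tinfo <- metaimage_types[[type]]

  is_mhd <- grepl("\\.mhd$", tolower(path))
  datafile <- if (is_mhd)
    paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  else "LOCAL"

  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    if (!is.null(vol$meta$transform))
      paste("TransformMatrix =", vol$meta$transform)
    else "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(vol$origin, scientific = FALSE), collapse = " ")),
    paste("ElementSpacing =", paste(format(vol$spacing, scientific = FALSE), collapse = " ")),
    paste("DimSize =", paste(d, collapse = " ")),
    paste("ElementType =", type),
    paste("ElementDataFile =", datafile)
  )

  write_payload <- function(con) {
    if (tinfo$what == "integer") {
      writeBin(as.integer(vals), con, size = tinfo$size, endian = "little")
    } else {
      writeBin(vals, con, size = tinfo$size, endian = "little")
    }
  }
  open_wb <- function(p) {
    tryCatch(file(p, "wb"), error = function(e)
      stop(sprintf("write_volume: could not open %s for writing", p),
           call. = FALSE),
      warning = function(w)
        stop(sprintf("write_volume: could not open %s for writing", p),
             call. = FALSE))
  }

  con <- open_wb(path)
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con, sep = "\n")
  if (!is_mhd) write_payload(con)
  if (is_mhd) {
    rawpath <- file.path(dirname(path), datafile)
    rcon <- open_wb(rawpath)
    on.exit(close(rcon), add = TRUE)
    write_payload(rcon)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
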