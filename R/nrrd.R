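# Minimal NRRD (NRRD0004) reader/writer for 3D integer label grids.
# The fastest axis comes first in the NRRD header; our arrays store z as
# the first (fastest, column-major) dimension, so sizes/spacings are
# written in (z, y, x) order and round-trip without permutation.

nrrd_type_table <- list(
  "signed char" = list(what = integer(), size = 1L, signed = TRUE),
  "int8"        = list(what = integer(), size = 1L, signed = TRUE),
  "uchar"       = list(what = integer(), size = 1L, signed = FALSE),
  "unsigned char" = list(what = integer(), size = 1L, signed = FALSE),
  "uint8"       = list(what = integer(), size = 1L, signed = FALSE),
  "short"       = list(what = integer(), size = 2L, signed = TRUE),
  "int16"       = list(what = integer(), size = 2L, signed = TRUE),
  "ushort"      = list(what = integer(), size = 2L, signed = FALSE),
  "uint16"      = list(what = integer(), size = 2L, signed = FALSE),
  "int"         = list(what = integer(), size = 4L, signed = TRUE),
  "int32"       = list(what = integer(), size = 4L, signed = TRUE),
  "float"       = list(what = numeric(), size = 4L, signed = TRUE),
  "double"      = list(what = numeric(), size = 8L, signed = TRUE)
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[0-9]$", magic)) stopf("not a NRRD file: %s", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stopf("unexpected end of NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) != 3L) stopf("malformed NRRD header line: %s", line)
    fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  needed <- c("type", "dimension", "sizes", "encoding")
  miss <- setdiff(needed, names(fields))
  if (length(miss)) stopf("NRRD header missing: %s", paste(miss, collapse = ", "))
  ndim <- as.integer(fields$dimension)
  sizes <- as.integer(strsplit(fields$sizes, "[[:space:]]+")[[1]])
  if (ndim != 3L || length(sizes) != 3L)
    stopf("only 3D NRRD volumes are supported")
  tname <- fields$type
  tinfo <- nrrd_type_table[[tname]]
  if (is.null(tinfo)) stopf("unsupported NRRD type '%s'", tname)
  if (is.numeric(tinfo$what) && !is.integer(tinfo$what))
    stopf("NRRD pixel type '%s' is not integer; label volumes must be integer",
          tname)
  n <- prod(sizes)
  enc <- tolower(fields$encoding)
  if (enc == "raw") {
    endian <- if (!is.null(fields$endian) && fields$endian == "big")
      "big" else "little"
    vals <- readBin(con, what = tinfo$what, n = n, size = tinfo$size,
                    signed = if (tinfo$size < 4L) tinfo$signed else TRUE,
                    endian = endian)
  } else if (enc %in% c("ascii", "txt", "text")) {
    vals <- as.integer(scan(con, what = integer(), n = n, quiet = TRUE))
  } else {
    stopf("unsupported NRRD encoding '%s' (raw or ascii)", enc)
  }
  if (length(vals) != n) stopf("NRRD data truncated: %d of %d values",
                               length(vals), n)
  spacing <- NULL
  if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "[[:space:]]+")[[1]])
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
      stopf("invalid NRRD spacings field")
  }
  list(data = array(as.integer(vals), dim = sizes), spacing = spacing)
}

write_nrrd <- function(labels, path, spacing,
                       encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  stopifnot(is.integer(labels), length(dim(labels)) == 3L)
  hdr <- c(
    "NRRD0004",
    "# perisyn label volume",
    "type: int32",
    "dimension: 3",
    sprintf("sizes: %s", paste(dim(labels), collapse = " ")),
    sprintf("spacings: %s", paste(format(spacing, scientific = FALSE),
                                  collapse = " ")),
    sprintf("encoding: %s", encoding),
    if (encoding == "raw") "endian: little" else NULL,
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.vector(labels), con, size = 4L, endian = "little")
  } else {
    writeLines(paste(as.vector(labels), collapse = " "), con, sep = "\n")
  }
  invisible(path)
}
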