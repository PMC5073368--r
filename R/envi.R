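# ENVI flat-binary cube I/O.
#
# Dialect: ASCII ".hdr" sidecar with samples/lines/bands, interleave
# (bil/bsq/bip), data type (12 = unsigned 16-bit for DN cubes, 4 = 32-bit
# float for reflectance), byte order 0 (little-endian) and a
# "wavelength = { ... }" block in nm. The binary file is the header path
# without the .hdr suffix. Internal array convention is [row, col, band];
# interleave is handled only at this I/O boundary.

.envi_kinds <- c(raw = 12L, white_ref = 12L, dark_ref = 12L,
                 reflectance = 4L)

#' Write a hyperspectral cube in ENVI format
#'
#' @param cube A `hypercube`.
#' @param path Path of the binary image file; the header is written to
#'   `<path>.hdr`. DN cubes are stored as unsigned 16-bit integers,
#'   reflectance cubes as 32-bit floats, little-endian.
#' @param interleave One of `"bil"`, `"bsq"`, `"bip"`.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bil", "bsq", "bip")) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  d <- dim(cube$data)
  dtype <- .envi_kinds[[cube$kind]]

  hdr <- c(
    "ENVI",
    "description = { hsibruise cube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", dtype),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = nm",
    sprintf("kind = %s", cube$kind),
    sprintf("wavelength = { %s }",
            paste(format(cube$grid$values, trim = TRUE), collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))

  # disk orders (fastest index first):
  #   bsq: sample, line, band; bil: sample, band, line; bip: band, sample, line
  perm <- switch(interleave,
                 bsq = c(2L, 1L, 3L),
                 bil = c(2L, 3L, 1L),
                 bip = c(3L, 2L, 1L))
  v <- as.vector(aperm(cube$data, perm))
  con <- file(path, "wb")
  on.exit(close(con))
  if (dtype == 12L) {
    writeBin(as.integer(round(v)), con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = 4L, endian = "little")
  }
  invisible(path)
}

.parse_envi_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  txt <- paste(lines, collapse = " ")
  get_scalar <- function(key) {
    hit <- grep(sprintf("^%s[[:space:]]*=", key), lines, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    val <- sub(sprintf("^%s[[:space:]]*=[[:space:]]*", key), "", hit[1])
    if (grepl("\\{", val)) return(NA_character_)
    trimws(val)
  }
  get_block <- function(key) {
    m <- regmatches(txt, regexec(
      sprintf("%s[[:space:]]*=[[:space:]]*\\{([^}]*)\\}", key), txt))[[1]]
    if (length(m) < 2) return(NULL)
    parts <- strsplit(m[2], "[,[:space:]]+")[[1]]
    as.numeric(parts[nzchar(parts)])
  }
  list(
    samples = as.integer(get_scalar("samples")),
    lines = as.integer(get_scalar("lines")),
    bands = as.integer(get_scalar("bands")),
    dtype = as.integer(get_scalar("data type")),
    interleave = tolower(get_scalar("interleave")),
    byte_order = as.integer(get_scalar("byte order")),
    kind = get_scalar("kind"),
    wavelength = get_block("wavelength")
  )
}

#' Read a hyperspectral cube from ENVI format
#'
#' @param header_path Path to the `.hdr` header; the binary file is the same
#'   path without the suffix.
#' @return A `hypercube`. Write/read is a lossless round trip for integer DN
#'   cubes in all three interleaves.
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path)) stop("header not found: ", header_path)
  h <- .parse_envi_header(header_path)
  for (f in c("samples", "lines", "bands")) {
    if (is.na(h[[f]])) stop("ENVI header missing field: ", f)
  }
  if (is.null(h$wavelength)) {
    stop("ENVI header has no wavelength block")
  }
  if (length(h$wavelength) != h$bands) {
    stop(sprintf("header declares %d bands but lists %d wavelengths",
                 h$bands, length(h$wavelength)))
  }
  if (!h$interleave %in% c("bil", "bsq", "bip")) {
    stop("unsupported interleave: ", h$interleave)
  }
  if (!h$dtype %in% c(4L, 12L)) stop("unsupported ENVI data type: ", h$dtype)

  bin_path <- sub("\\.hdr$", "", header_path)
  if (!file.exists(bin_path)) stop("binary cube not found: ", bin_path)
  n <- h$samples * h$lines * h$bands
  expected_bytes <- n * if (h$dtype == 12L) 2L else 4L
  if (file.size(bin_path) != expected_bytes) {
    stop(sprintf("binary size %d does not match header (expected %d bytes)",
                 file.size(bin_path), expected_bytes))
  }
  con <- file(bin_path, "rb")
  on.exit(close(con))
  v <- if (h$dtype == 12L) {
    readBin(con, "integer", n = n, size = 2L, signed = FALSE,
            endian = "little")
  } else {
    readBin(con, "numeric", n = n, size = 4L, endian = "little")
  }

  dims_disk <- switch(h$interleave,
                      bsq = c(h$samples, h$lines, h$bands),
                      bil = c(h$samples, h$bands, h$lines),
                      bip = c(h$bands, h$samples, h$lines))
  unperm <- switch(h$interleave,
                   bsq = c(2L, 1L, 3L),
                   bil = c(3L, 1L, 2L),
                   bip = c(3L, 2L, 1L))
  data <- aperm(array(v, dims_disk), unperm)

  step <- diff(h$wavelength)
  if (any(abs(step - step[1]) > 1e-6)) {
    stop("wavelength block is not uniformly spaced")
  }
  grid <- make_wavelength_grid(h$wavelength[1],
                               h$wavelength[length(h$wavelength)], step[1])
  kind <- if (!is.na(h$kind) && h$kind %in% names(.envi_kinds)) h$kind
          else if (h$dtype == 4L) "reflectance" else "raw"
  hypercube(data, grid, kind = kind)
}
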