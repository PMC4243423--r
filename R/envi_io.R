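#' ENVI-style hyperspectral cube input/output
#'
#' Line-scan cameras of the kind targeted here store each acquisition as a
#' flat binary payload (`.dat`, 32-bit float, or `.raw`, 16-bit unsigned)
#' plus a text header (`.hdr`) holding the geometry, the interleave and the
#' wavelength list.  These functions read and write that layout.
#'
#' The camera records one spatial line with the full spectrum at a time, so
#' the native interleave is BIL (band-interleaved-by-line): to reassemble
#' the 2-D image of one wavelength, every M-th stored line is read.  BSQ and
#' BIP are supported for generality.  16-bit payloads are mapped to
#' reflectance-scale reals by dividing by 65535 at read time (set
#' `scale = FALSE` for raw integer counts).
#'
#' @name envi_io
NULL

.hs_data_kinds <- c(uint16 = 12L, float32 = 4L)
.hs_bytes <- c(uint16 = 2L, float32 = 4L)

#' Predicted ENVI payload size in bytes
#'
#' @param lines,samples,bands cube geometry (rows, columns, bands).
#' @param data_kind `"uint16"` or `"float32"`.
#' @return expected payload length in bytes.
#' @export
envi_payload_bytes <- function(lines, samples, bands, data_kind) {
  data_kind <- match.arg(data_kind, names(.hs_bytes))
  as.numeric(lines) * samples * bands * .hs_bytes[[data_kind]]
}

#' Parse an ENVI header
#'
#' @param header_source path to a `.hdr` file or a character vector of
#'   header lines.
#' @return a list with fields `samples`, `lines`, `bands`, `data_kind`,
#'   `interleave`, `byte_order`, `wavelengths_nm` and `extra` (unknown keys,
#'   preserved verbatim).
#' @export
read_envi_header <- function(header_source) {
  lines <- if (length(header_source) == 1L && !grepl("\n", header_source)) {
    if (file.exists(header_source)) readLines(header_source, warn = FALSE)
    else if (grepl("\\.hdr$", header_source))
      hs_stop("hs_io_error", "header file not found: %s", header_source)
    else as.character(header_source)
  } else as.character(header_source)
  txt <- paste(lines, collapse = "\n")
  hs_assert(grepl("ENVI", txt, fixed = TRUE), "hs_format_error",
            "not an ENVI header (missing 'ENVI' magic)")
  # join multi-line { ... } values, then split into key = value entries
  txt <- sub("^\\s*ENVI\\s*", "", txt)
  entries <- list()
  pat <- "([A-Za-z ][A-Za-z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt)[[1]]
  if (m[1] != -1) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
      key <- trimws(sub("=.*$", "", piece))
      val <- trimws(sub("^[^=]*=", "", piece))
      entries[[tolower(key)]] <- val
    }
  }
  need <- c("samples", "lines", "bands", "data type", "interleave")
  missing <- setdiff(need, names(entries))
  hs_assert(length(missing) == 0L, "hs_format_error",
            "ENVI header missing key(s): %s", toString(missing))

  num <- function(key) as.numeric(entries[[key]])
  dt <- as.integer(num("data type"))
  kind <- names(.hs_data_kinds)[match(dt, .hs_data_kinds)]
  hs_assert(!is.na(kind), "hs_unsupported_format",
            "unsupported ENVI data type %d (only 12 = uint16, 4 = float32)", dt)
  il <- toupper(trimws(entries[["interleave"]]))
  hs_assert(il %in% c("BIL", "BSQ", "BIP"), "hs_unsupported_format",
            "unsupported interleave '%s'", il)
  bo <- if (!is.null(entries[["byte order"]])) as.integer(num("byte order")) else 0L
  wl <- NULL
  if (!is.null(entries[["wavelength"]])) {
    wl <- as.numeric(strsplit(gsub("[{}\n]", " ", entries[["wavelength"]]),
                              ",")[[1]])
    hs_assert(!anyNA(wl) && length(wl) == num("bands"), "hs_format_error",
              "wavelength list does not match 'bands'")
  }
  known <- c(need, "byte order", "wavelength", "header offset")
  list(samples = as.integer(num("samples")),
       lines = as.integer(num("lines")),
       bands = as.integer(num("bands")),
       data_kind = kind,
       interleave = il,
       byte_order = if (bo == 0L) "little" else "big",
       wavelengths_nm = wl,
       extra = entries[setdiff(names(entries), known)])
}

# storage-order permutations: ENVI payloads are sample-fastest within a
# line; R arrays are column-major, hence the aperm gymnastics.
.deinterleave <- function(vec, M, N, K, interleave) {
  switch(interleave,
         BSQ = aperm(array(vec, c(N, M, K)), c(2, 1, 3)),
         BIL = aperm(array(vec, c(N, K, M)), c(3, 1, 2)),
         BIP = aperm(array(vec, c(K, N, M)), c(3, 2, 1)))
}

.interleave <- function(values, interleave) {
  switch(interleave,
         BSQ = as.vector(aperm(values, c(2, 1, 3))),
         BIL = as.vector(aperm(values, c(2, 3, 1))),
         BIP = as.vector(aperm(values, c(3, 2, 1))))
}

#' Read an ENVI cube
#'
#' @param header_source path to the `.hdr` file or character vector of
#'   header lines.
#' @param payload_source path to the binary payload or a raw vector.  When
#'   `NULL` and `header_source` is a path, the payload is looked for next to
#'   the header with extension `.dat` (float32) or `.raw` (uint16).
#' @param scale for uint16 payloads, divide by 65535 so values land in
#'   `[0, 1]`; set `FALSE` to keep integer counts.
#' @return a [hyper_cube()] in `[row, column, band]` order, independent of
#'   the stored interleave.
#' @export
read_cube <- function(header_source, payload_source = NULL, scale = TRUE) {
  hdr <- read_envi_header(header_source)
  if (is.null(payload_source)) {
    hs_assert(length(header_source) == 1L && file.exists(header_source),
              "hs_io_error", "payload_source needed when header is not a file")
    ext <- if (hdr$data_kind == "float32") ".dat" else ".raw"
    payload_source <- paste0(sub("\\.hdr$", "", header_source), ext)
  }
  expected <- envi_payload_bytes(hdr$lines, hdr$samples, hdr$bands, hdr$data_kind)
  payload <- if (is.raw(payload_source)) payload_source else {
    hs_assert(file.exists(payload_source), "hs_io_error",
              "payload file not found: %s", payload_source)
    readBin(payload_source, "raw", n = file.size(payload_source))
  }
  hs_assert(length(payload) == expected, "hs_payload_truncation",
            "payload has %d bytes, header promises %.0f",
            length(payload), expected)
  endian <- if (hdr$byte_order == "little") "little" else "big"
  n_elem <- hdr$lines * hdr$samples * hdr$bands
  vec <- if (hdr$data_kind == "uint16") {
    v <- readBin(payload, "integer", n = n_elem, size = 2L,
                 signed = FALSE, endian = endian)
    if (scale) v / 65535 else v
  } else {
    readBin(payload, "numeric", n = n_elem, size = 4L, endian = endian)
  }
  values <- .deinterleave(vec, hdr$lines, hdr$samples, hdr$bands, hdr$interleave)
  wl <- hdr$wavelengths_nm
  if (is.null(wl)) wl <- seq_len(hdr$bands)
  hyper_cube(values, wl, header_extra = hdr$extra)
}

#' Serialize a cube to ENVI header text + binary payload
#'
#' `read_cube(write_cube(cube))` is the identity bit-for-bit for uint16 and
#' to one float32 ulp otherwise.  Unknown header keys carried on the cube
#' are written back verbatim.
#'
#' @param cube a [hyper_cube()], finite-valued.
#' @param interleave storage order, `"BIL"` (native for line-scan cameras),
#'   `"BSQ"` or `"BIP"`.
#' @param data_kind `"float32"` or `"uint16"`.  uint16 requires values in
#'   `[0, 1]`; they are stored as `round(v * 65535)`.
#' @param byte_order `"little"` (default) or `"big"`.
#' @return list with elements `header` (character vector of lines) and
#'   `payload` (raw vector).
#' @export
write_cube <- function(cube, interleave = c("BIL", "BSQ", "BIP"),
                       data_kind = c("float32", "uint16"),
                       byte_order = c("little", "big")) {
  interleave <- match.arg(interleave)
  data_kind <- match.arg(data_kind)
  byte_order <- match.arg(byte_order)
  v <- cube$values
  hs_assert(all(is.finite(v)), "hs_range_error", "cube contains non-finite values")
  d <- dim(v)
  vec <- .interleave(v, interleave)
  if (data_kind == "uint16") {
    hs_assert(min(vec) >= 0 && max(vec) <= 1, "hs_range_error",
              "uint16 output requires values in [0, 1]")
    ints <- as.integer(round(vec * 65535))
    # writeBin has no unsigned 16-bit: fold into signed range manually
    ints <- ifelse(ints > 32767L, ints - 65536L, ints)
    payload <- writeBin(ints, raw(), size = 2L, endian = byte_order)
  } else {
    payload <- writeBin(as.numeric(vec), raw(), size = 4L, endian = byte_order)
  }
  header <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    sprintf("data type = %d", .hs_data_kinds[[data_kind]]),
    sprintf("interleave = %s", tolower(interleave)),
    sprintf("byte order = %d", if (byte_order == "little") 0L else 1L),
    sprintf("wavelength = { %s }",
            paste(format(cube$wavelengths_nm, trim = TRUE, digits = 10),
                  collapse = ", ")))
  if (length(cube$header_extra))
    header <- c(header, sprintf("%s = %s", names(cube$header_extra),
                                unlist(cube$header_extra)))
  list(header = header, payload = payload)
}

#' Write an ENVI cube to disk
#'
#' @param cube a [hyper_cube()].
#' @param base_path output path without extension; `.hdr` and `.dat`/`.raw`
#'   are appended.
#' @inheritParams write_cube
#' @return invisibly, the two file paths written.
#' @export
write_envi <- function(cube, base_path, interleave = "BIL",
                       data_kind = "float32", byte_order = "little") {
  enc <- write_cube(cube, interleave, data_kind, byte_order)
  hdr <- paste0(base_path, ".hdr")
  bin <- paste0(base_path, if (data_kind == "float32") ".dat" else ".raw")
  writeLines(enc$header, hdr)
  writeBin(enc$payload, bin)
  invisible(c(header = hdr, payload = bin))
}
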