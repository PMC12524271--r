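# Single-channel float raster I/O: PFM and raw float32 with a JSON sidecar.
# PFM stores rows bottom-up; the in-memory convention everywhere in this
# package is a matrix with row 1 = top image row (v = 0).

#' Read a PFM depth/disparity raster
#'
#' Grayscale PFM ("Pf" header). The scale line's sign encodes endianness;
#' both are handled. Returned as a numeric matrix with row 1 = top image
#' row, so `raster[v + 1, u + 1]` addresses pixel (u, v).
#'
#' @param path file path.
#' @return numeric matrix (height x width).
#' @export
read_pfm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "Pf"))
    stopf("not a grayscale PFM file: %s", path, class = "io_error")
  dims <- scan(text = readLines(con, n = 1), quiet = TRUE)
  scale <- scan(text = readLines(con, n = 1), quiet = TRUE)
  w <- as.integer(dims[1]); h <- as.integer(dims[2])
  endian <- if (scale < 0) "little" else "big"
  vals <- readBin(con, "numeric", n = w * h, size = 4, endian = endian)
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  m[h:1, , drop = FALSE]  # PFM is bottom-up
}

#' Write a PFM raster
#'
#' @param m numeric matrix, row 1 = top image row.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(m, path) {
  stopifnot(is.matrix(m))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("Pf", sprintf("%d %d", ncol(m), nrow(m)), "-1.0"), con)
  writeBin(as.numeric(t(m[nrow(m):1, , drop = FALSE])), con,
           size = 4, endian = "little")
  invisible(path)
}

#' Read/write a raw float32 raster with a JSON shape sidecar
#'
#' The raw format is row-major float32, top row first; `<path>.json` holds
#' `{"width": w, "height": h, "dtype": "float32", "order": "row-major"}`.
#'
#' @param m numeric matrix (for writing).
#' @param path path of the `.raw` file; the sidecar lives at `<path>.json`.
#' @return the matrix (read) or `path` invisibly (write).
#' @export
read_raw_raster <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stopf("missing raster sidecar: %s", side, class = "io_error")
  meta <- jsonlite::fromJSON(side)
  n <- meta$width * meta$height
  vals <- readBin(path, "numeric", n = n, size = 4, endian = "little")
  matrix(vals, nrow = meta$height, ncol = meta$width, byrow = TRUE)
}

#' @rdname read_raw_raster
#' @export
write_raw_raster <- function(m, path) {
  stopifnot(is.matrix(m))
  writeBin(as.numeric(t(m)), path, size = 4, endian = "little")
  jsonlite::write_json(list(width = ncol(m), height = nrow(m),
                            dtype = "float32", order = "row-major"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
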