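#' Read and write elevation rasters
#'
#' `read_raster()` reads a single-band elevation grid from an ESRI ASCII grid
#' (`.asc`/`.txt`) or a single-band TIFF/GeoTIFF (`.tif`/`.tiff`).
#' `write_raster()` writes an ESRI ASCII grid, which round-trips values, cell
#' size and origin exactly within float formatting tolerance. TIFF output is
#' not offered: the available TIFF writer stores only values clamped to
#' [0, 1], which cannot represent elevations.
#'
#' TIFF files carry no georeferencing that this reader interprets, so TIFF
#' input falls back to origin (0, 0) with a warning and takes the cell size
#' from the `cell_size` argument.
#'
#' @param path File path; format is chosen by extension.
#' @param cell_size Cell edge (m) used for TIFF input, which stores none.
#' @param raster A [terrain_raster()].
#' @param nodata Sentinel written for missing cells in ASCII output.
#' @param digits Significant digits written for ASCII values.
#' @return `read_raster()` returns a [terrain_raster()]; `write_raster()`
#'   returns `path` invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".asc")
#' write_raster(make_ramp(4, 5, 90, slope_x = 0.01), f)
#' read_raster(f)
read_raster <- function(path, cell_size = 90) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("asc", "txt", "grd")) {
    read_ascii_grid(path)
  } else if (ext %in% c("tif", "tiff")) {
    read_tiff_grid(path, cell_size)
  } else {
    abort(sprintf("Unsupported raster extension '.%s' (use .asc or .tif).", ext))
  }
}

#' @rdname read_raster
#' @export
write_raster <- function(raster, path, nodata = -9999, digits = 15) {
  if (!inherits(raster, "terrain_raster")) {
    abort("`raster` must be a terrain_raster.")
  }
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("asc", "txt", "grd")) {
    abort("write_raster() writes ESRI ASCII grids; use an .asc path.")
  }
  v <- raster$values
  header <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10f", raster$origin[1]),
    sprintf("yllcorner %.10f", raster$origin[2]),
    sprintf("cellsize %.10f", raster$cell_size),
    sprintf("NODATA_value %s", format(nodata))
  )
  # ASCII grids store rows north-to-south; internal row 1 is the south row.
  out <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  out[is.na(out)] <- nodata
  body <- apply(out, 1L, function(row) {
    paste(formatC(row, digits = digits, format = "g"), collapse = " ")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- list()
  i <- 1L
  while (i <= length(lines) &&
    grepl("^\\s*[A-Za-z_]+\\s+\\S+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(header))) {
    abort("Not an ESRI ASCII grid: missing ncols/nrows/cellsize header.")
  }
  nc <- as.integer(header$ncols)
  nr <- as.integer(header$nrows)
  xll <- header$xllcorner %||% 0
  yll <- header$yllcorner %||% 0
  nodata <- header$nodata_value
  vals <- scan(
    text = paste(lines[i:length(lines)], collapse = "\n"),
    quiet = TRUE
  )
  if (length(vals) != nr * nc) {
    abort(sprintf(
      "ASCII grid body has %d values, expected %d.", length(vals), nr * nc
    ))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(nodata)) m[m == nodata] <- NA_real_
  # stored north-to-south; flip so row 1 is the south row
  terrain_raster(m[rev(seq_len(nr)), , drop = FALSE], header$cellsize,
    origin = c(xll, yll)
  )
}

read_tiff_grid <- function(path, cell_size) {
  img <- tiff::readTIFF(path, as.is = FALSE, all = FALSE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1L) {
      abort(sprintf(
        "Multi-band rasters are not supported (%d bands found).", dim(img)[3]
      ))
    }
    img <- img[, , 1L]
  }
  warn("TIFF input carries no georeferencing here; using origin (0, 0).")
  terrain_raster(img[rev(seq_len(nrow(img))), , drop = FALSE], cell_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
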