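#' Lightweight single-band raster
#'
#' An `oc_raster` is a numeric or integer matrix with a cell size (metres per
#' pixel edge) and an implicit planar grid whose origin is the lower-left
#' corner at (0, 0). Nodata cells are `NA`. Rows run north to south (row 1 is
#' the top of the scene), matching on-disk raster conventions.
#'
#' @param data numeric or integer matrix.
#' @param cell_size positive number, metres per pixel edge.
#' @param categorical logical; `TRUE` for class-coded rasters (stored integer).
#' @return An object of class `oc_raster`.
#' @export
oc_raster <- function(data, cell_size = 10, categorical = FALSE) {
  if (!is.matrix(data)) stop("`data` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a positive scalar")
  if (categorical) storage.mode(data) <- "integer"
  structure(data,
            cell_size = cell_size,
            categorical = categorical,
            class = c("oc_raster", class(data)))
}

#' @export
print.oc_raster <- function(x, ...) {
  v <- as.vector(x)
  cat(sprintf("<oc_raster> %d x %d cells, %.6g m cells, %s\n",
              nrow(x), ncol(x), attr(x, "cell_size"),
              if (isTRUE(attr(x, "categorical"))) "categorical" else "continuous"))
  cat(sprintf("  nodata: %d cells; range of data: [%.6g, %.6g]\n",
              sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

cell_size <- function(r) attr(r, "cell_size")

#' Check that rasters share a grid
#'
#' @param ... `oc_raster` objects.
#' @return `TRUE` invisibly; errors describing the mismatch otherwise.
#' @export
check_same_grid <- function(...) {
  rs <- list(...)
  if (length(rs) < 2L) return(invisible(TRUE))
  ref <- rs[[1L]]
  for (i in seq_along(rs)[-1L]) {
    r <- rs[[i]]
    if (!identical(dim(r), dim(ref)))
      stop(sprintf("grid mismatch: raster %d is %dx%d, expected %dx%d",
                   i, nrow(r), ncol(r), nrow(ref), ncol(ref)))
    if (!isTRUE(all.equal(cell_size(r), cell_size(ref))))
      stop(sprintf("cell size mismatch: raster %d has %g, expected %g",
                   i, cell_size(r), cell_size(ref)))
  }
  invisible(TRUE)
}

#' Land-use class codes
#'
#' Integer codes for the six land-use classes used throughout:
#' arable (AR=1), garden (GA=2), forest-grassland (FO=3), construction (CO=4),
#' water (WA=5), unused (UN=6). Nodata is `NA` in memory and 0 on disk.
#'
#' @return Named integer vector of codes.
#' @export
lu_codes <- function() {
  c(AR = 1L, GA = 2L, FO = 3L, CO = 4L, WA = 5L, UN = 6L)
}

lu_names <- function() names(lu_codes())

#' Write a raster as an Esri ASCII grid
#'
#' Plain-text `.asc` interchange format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by one line of
#' space-separated values per raster row, north to south. Continuous values
#' are written with 12 significant digits; categorical rasters as integers.
#'
#' @param r an `oc_raster`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "oc_raster"))
  nodata <- -9999
  m <- unclass(r)
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(r)),
           sprintf("nrows %d", nrow(r)),
           "xllcorner 0",
           "yllcorner 0",
           sprintf("cellsize %.10g", cell_size(r)),
           sprintf("NODATA_value %d", as.integer(nodata)))
  fmt <- if (isTRUE(attr(r, "categorical"))) "%d" else "%.12g"
  rows <- apply(m, 1L, function(v) paste(sprintf(fmt, v), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an Esri ASCII grid raster
#'
#' @param path `.asc` file written by [write_raster()] or any conforming tool.
#' @param categorical logical; read as integer class codes.
#' @return An `oc_raster`.
#' @export
read_raster <- function(path, categorical = FALSE) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d in %s", nr * nc, length(vals), path))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  oc_raster(m, cell_size = hdr$cellsize, categorical = categorical)
}

#' Write / read a data frame as CSV
#'
#' Thin wrappers that fix the conventions used across the package: no row
#' names, full numeric precision (12 significant digits survive the
#' round trip), stable column order.
#'
#' @param x data frame.
#' @param path file path.
#' @return `path` (write) or a data frame (read).
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
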