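#' Multispectral raster container
#'
#' An in-memory 4-band (or n-band) georeferenced raster: a named list of
#' equally sized numeric matrices plus an affine geotransform mapping pixel
#' indices to world coordinates in meters. This is the pixel-space substrate
#' every pipeline stage operates on.
#'
#' The geotransform follows the usual north-up raster convention:
#' `x = x0 + (col + 0.5) * px_x`, `y = y0 - (row + 0.5) * px_y` for 0-based
#' `(col, row)` with row 0 at the top; world coordinates refer to pixel
#' centers. Rotated geotransforms are not supported.
#'
#' @param bands named list of numeric matrices (same dimensions), typically
#'   `G`, `R`, `RE`, `NIR` for 550/660/735/790 nm.
#' @param origin numeric length-2, world coordinates `(x0, y0)` of the raster's
#'   top-left corner (not a pixel center).
#' @param pixel_size numeric length-2 (or 1, recycled), pixel width/height in
#'   meters; both strictly positive.
#' @param crs_id character CRS identifier; `"unknown"` is tolerated (synthetic
#'   scenes use a local metric frame).
#' @param nodata_mask logical matrix flagging missing cells, or `NULL` for none.
#' @return an object of class `ms_raster`.
#' @export
ms_raster <- function(bands, origin = c(0, 0), pixel_size = c(1, 1),
                      crs_id = "unknown", nodata_mask = NULL) {
  if (!is.list(bands) || length(bands) < 1L)
    stop("`bands` must be a non-empty named list of matrices", call. = FALSE)
  if (is.null(names(bands)) || any(!nzchar(names(bands))))
    stop("every band must be named", call. = FALSE)
  bands <- lapply(bands, function(b) {
    if (!is.matrix(b)) b <- as.matrix(b)
    storage.mode(b) <- "double"
    b
  })
  dims <- vapply(bands, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all band grids must share identical dimensions", call. = FALSE)
  pixel_size <- rep_len(as.numeric(pixel_size), 2L)
  if (any(!is.finite(pixel_size)) || any(pixel_size <= 0))
    stop("pixel size must be strictly positive in both axes", call. = FALSE)
  if (is.null(nodata_mask)) {
    nodata_mask <- matrix(FALSE, dims[1, 1], dims[2, 1])
  } else {
    if (!identical(dim(nodata_mask), dim(bands[[1]])))
      stop("nodata_mask dimensions must equal band dimensions", call. = FALSE)
    nodata_mask <- matrix(as.logical(nodata_mask), dims[1, 1], dims[2, 1])
  }
  structure(
    list(bands = bands, origin = as.numeric(origin)[1:2],
         pixel_size = pixel_size, crs_id = as.character(crs_id)[1],
         nodata_mask = nodata_mask),
    class = "ms_raster")
}

#' @export
print.ms_raster <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("<ms_raster> %d x %d px, %d band(s): %s\n", d[1], d[2],
              length(x$bands), paste(names(x$bands), collapse = ", ")))
  cat(sprintf("  pixel %.4g x %.4g m, origin (%.4g, %.4g), crs '%s', %d nodata px\n",
              x$pixel_size[1], x$pixel_size[2], x$origin[1], x$origin[2],
              x$crs_id, sum(x$nodata_mask)))
  invisible(x)
}

raster_dim <- function(raster) dim(raster$bands[[1]])

#' Pixel/world coordinate transforms
#'
#' Convert 0-based pixel indices `(col, row)` to pixel-center world
#' coordinates `(x, y)` and back. The two maps are mutually inverse.
#'
#' @param raster an [ms_raster].
#' @param col,row 0-based pixel indices (vectors allowed; may be fractional).
#' @param x,y world coordinates in meters.
#' @return `pixel_to_world`: a two-column matrix `(x, y)`;
#'   `world_to_pixel`: a two-column matrix of fractional `(col, row)`.
#' @export
pixel_to_world <- function(raster, col, row) {
  cbind(x = raster$origin[1] + (col + 0.5) * raster$pixel_size[1],
        y = raster$origin[2] - (row + 0.5) * raster$pixel_size[2])
}

#' @rdname pixel_to_world
#' @export
world_to_pixel <- function(raster, x, y) {
  cbind(col = (x - raster$origin[1]) / raster$pixel_size[1] - 0.5,
        row = (raster$origin[2] - y) / raster$pixel_size[2] - 0.5)
}

NODATA_ASC <- -9999

#' Read a multiband raster
#'
#' Reads either a multiband float TIFF with an accompanying ESRI world file
#' (`<path>.tfw`, or `.wld`) or a stack of per-band ESRI ASCII grids written by
#' [write_raster()] (pass the stack's base path, without `_BAND.asc`). A
#' sidecar `<base>.prj` file, when present, supplies the CRS identifier;
#' missing CRS is recorded as `"unknown"`, not an error.
#'
#' @param path file path (`.tif`/`.tiff`) or ASCII-grid stack base path.
#' @param bands expected band names, in order. A file whose band count
#'   differs raises a band-mapping error naming the missing bands.
#' @return an [ms_raster].
#' @export
read_raster <- function(path, bands = c("G", "R", "RE", "NIR")) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    read_raster_tif(path, bands)
  } else {
    read_raster_asc(path, bands)
  }
}

read_raster_tif <- function(path, bands) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  img <- tryCatch(suppressWarnings(tiff::readTIFF(path, as.is = FALSE)),
                  error = function(e) stop("unreadable TIFF '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  base <- sub("\\.tiff?$", "", path, ignore.case = TRUE)
  scl_path <- paste0(base, ".bands.json")
  has_sidecar <- file.exists(scl_path)
  nb <- dim(img)[3]
  if (nb != length(bands)) {
    miss <- if (nb < length(bands))
      paste(bands[seq.int(nb + 1L, length(bands))], collapse = ", ") else "none"
    stop(sprintf("band-mapping error: file has %d band(s), expected %d (missing: %s)",
                 nb, length(bands), miss), call. = FALSE)
  }
  wf <- c(paste0(base, ".tfw"), paste0(base, ".wld"))
  wf <- wf[file.exists(wf)][1]
  if (is.na(wf)) stop("no world file (.tfw/.wld) found for ", path, call. = FALSE)
  w <- as.numeric(readLines(wf, n = 6L))
  if (length(w) != 6L || any(!is.finite(w)))
    stop("malformed world file: ", wf, call. = FALSE)
  if (w[2] != 0 || w[3] != 0 || w[1] <= 0 || w[4] >= 0)
    stop("only north-up, unrotated geotransforms are supported", call. = FALSE)
  # world file gives the center of the top-left pixel
  origin <- c(w[5] - w[1] / 2, w[6] - w[4] / 2)
  crs_id <- read_sidecar_crs(base)
  scl <- if (has_sidecar) jsonlite::fromJSON(scl_path) else
    list(offset = rep(0, nb), scale = rep(1, nb))
  blist <- stats::setNames(lapply(seq_len(nb), function(i)
    img[, , i] * scl$scale[i] + scl$offset[i]), bands)
  nodata <- Reduce(`|`, lapply(blist, function(b) !is.finite(b)))
  mask_path <- paste0(base, ".mask.tif")
  if (file.exists(mask_path))
    nodata <- nodata | suppressWarnings(tiff::readTIFF(mask_path)) > 0.5
  blist <- lapply(blist, function(b) { b[!is.finite(b)] <- NA_real_; b })
  ms_raster(blist, origin = origin, pixel_size = c(w[1], -w[4]),
            crs_id = crs_id, nodata_mask = nodata)
}

read_raster_asc <- function(base, bands) {
  paths <- paste0(base, "_", bands, ".asc")
  missing <- bands[!file.exists(paths)]
  if (length(missing) == length(bands) && file.exists(base))
    stop("'", base, "' is not an ASCII-grid stack base path", call. = FALSE)
  if (length(missing))
    stop("band-mapping error: missing band file(s) for ",
         paste(missing, collapse = ", "), call. = FALSE)
  grids <- lapply(paths, read_asc_grid)
  hdr <- grids[[1]]$header
  blist <- stats::setNames(lapply(grids, `[[`, "values"), bands)
  nodata <- Reduce(`|`, lapply(blist, is.na))
  nr <- nrow(blist[[1]])
  origin <- c(hdr["xllcorner"], hdr["yllcorner"] + nr * hdr["cellsize"])
  ms_raster(blist, origin = origin, pixel_size = rep(hdr["cellsize"], 2),
            crs_id = read_sidecar_crs(base), nodata_mask = nodata)
}

read_asc_grid <- function(path) {
  lines <- readLines(path)
  hdr_n <- 6L
  hdr_kv <- strsplit(trimws(lines[seq_len(hdr_n)]), "[[:space:]]+")
  hdr <- stats::setNames(as.numeric(vapply(hdr_kv, `[`, "", 2L)),
                         tolower(vapply(hdr_kv, `[`, "", 1L)))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII grid header in ", path, call. = FALSE)
  vals <- scan(text = lines[-seq_len(hdr_n)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr["nrows"], ncol = hdr["ncols"], byrow = TRUE)
  m[m == hdr["nodata_value"]] <- NA_real_
  list(header = hdr, values = m)
}

read_sidecar_crs <- function(base) {
  prj <- paste0(base, ".prj")
  if (file.exists(prj)) trimws(readLines(prj, n = 1L)) else "unknown"
}

#' Write a multiband raster
#'
#' Two dialects: `"asc"` (default) writes one full-precision ESRI ASCII grid
#' per band (`<path>_<BAND>.asc`) — a lossless text round-trip; `"tif"` writes
#' a multiband 32-bit float TIFF with an ESRI world file (`.tfw`), the
#' interchange form for GIS software (precision limited to float32). Both
#' write the CRS identifier to `<base>.prj`. Nodata cells are stored as the
#' grid's nodata value (asc) or NaN (tif).
#'
#' @param raster an [ms_raster].
#' @param path output base path (asc) or `.tif` path.
#' @param dialect `"asc"` or `"tif"`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path, dialect = c("asc", "tif")) {
  dialect <- match.arg(dialect)
  if (dialect == "tif") write_raster_tif(raster, path) else write_raster_asc(raster, path)
}

write_raster_asc <- function(raster, base) {
  if (abs(raster$pixel_size[1] - raster$pixel_size[2]) > 1e-12)
    stop("ASCII-grid dialect requires square pixels", call. = FALSE)
  d <- raster_dim(raster)
  hdr <- sprintf(paste0("ncols %d\nnrows %d\nxllcorner %.17g\nyllcorner %.17g\n",
                        "cellsize %.17g\nNODATA_value %d"),
                 d[2], d[1], raster$origin[1],
                 raster$origin[2] - d[1] * raster$pixel_size[2],
                 raster$pixel_size[1], NODATA_ASC)
  for (bn in names(raster$bands)) {
    b <- raster$bands[[bn]]
    b[raster$nodata_mask | is.na(b)] <- NODATA_ASC
    rows <- apply(b, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
    writeLines(c(hdr, rows), paste0(base, "_", bn, ".asc"))
  }
  writeLines(raster$crs_id, paste0(base, ".prj"))
  invisible(base)
}

write_raster_tif <- function(raster, path) {
  d <- raster_dim(raster)
  arr <- array(0, c(d, length(raster$bands)))
  # TIFF samples are stored in [0,1]; per-band linear coefficients go to a
  # JSON sidecar so read_raster_tif can restore physical values (float32
  # precision — the asc dialect is the lossless one).
  offs <- scls <- numeric(length(raster$bands))
  for (i in seq_along(raster$bands)) {
    b <- raster$bands[[i]]
    b[raster$nodata_mask] <- NA_real_
    rng <- range(b, na.rm = TRUE, finite = TRUE)
    if (!all(is.finite(rng))) rng <- c(0, 1)
    offs[i] <- rng[1]
    scls[i] <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    b <- (b - offs[i]) / scls[i]
    b[is.na(b)] <- 0
    arr[, , i] <- b
  }
  suppressWarnings(tiff::writeTIFF(arr, path, bits.per.sample = 32L, reduce = FALSE))
  base <- sub("\\.tiff?$", "", path, ignore.case = TRUE)
  # nodata mask goes to a sidecar grayscale TIFF (float samples cannot hold NaN)
  if (any(raster$nodata_mask))
    tiff::writeTIFF(raster$nodata_mask * 1, paste0(base, ".mask.tif"))
  jsonlite::write_json(list(bands = names(raster$bands), offset = offs, scale = scls),
                       paste0(base, ".bands.json"), digits = NA)
  # world file: pixel sizes + center of top-left pixel
  writeLines(sprintf("%.17g", c(raster$pixel_size[1], 0, 0, -raster$pixel_size[2],
                                raster$origin[1] + raster$pixel_size[1] / 2,
                                raster$origin[2] - raster$pixel_size[2] / 2)),
             paste0(base, ".tfw"))
  writeLines(raster$crs_id, paste0(base, ".prj"))
  invisible(path)
}
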