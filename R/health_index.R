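#' Health-index parameters
#'
#' @param r disc-neighborhood radius in meters; default 0.075 (7.5 cm).
#' @param include_nonvegetation when TRUE, soil/shadow members of the
#'   neighborhood set count toward the denominator (they carry no health
#'   level, so they dilute the index toward 0); default FALSE keeps the index
#'   on the 1-5 scale by averaging over health-labeled segments only.
#' @param discretize how the real-valued index becomes a discrete class:
#'   `"round-half-up"` (default), `"floor"`, or `"none"`.
#' @return a `health_params` object.
#' @export
health_params <- function(r = 0.075, include_nonvegetation = FALSE,
                          discretize = c("round-half-up", "floor", "none")) {
  stopifnot(r >= 0)
  structure(list(r = r, include_nonvegetation = include_nonvegetation,
                 discretize = match.arg(discretize)),
            class = "health_params")
}

#' Segments intersecting a disc neighborhood
#'
#' Returns every segment whose footprint intersects the closed disc of radius
#' `r` centered at `p` (boundary contact counts). Footprints are unions of
#' pixel squares, so the predicate is the exact closed-form distance from `p`
#' to each member pixel's square — exact polygon-disc geometry for
#' rectilinear footprints, not a rasterized approximation.
#'
#' @param p numeric length-2, world coordinates (x, y).
#' @param r radius in meters (r = 0 degenerates to point-in-segment).
#' @param segmap a `segment_map`.
#' @return integer vector of segment labels (possibly empty).
#' @export
segments_near_point <- function(p, r, segmap) {
  lg <- segmap$label_grid
  nr <- nrow(lg); nc <- ncol(lg)
  px <- segmap$pixel_size
  # candidate pixel window covering the disc
  # one extra pixel on each side so exact boundary touches are never missed
  c0 <- floor((p[1] - r - segmap$origin[1]) / px[1]) - 1
  c1 <- ceiling((p[1] + r - segmap$origin[1]) / px[1])
  r0 <- floor((segmap$origin[2] - (p[2] + r)) / px[2]) - 1
  r1 <- ceiling((segmap$origin[2] - (p[2] - r)) / px[2])
  if (c0 > nc - 1 || c1 < 0 || r0 > nr - 1 || r1 < 0) return(integer())
  cols <- max(0, c0):min(nc - 1, c1)
  rows <- max(0, r0):min(nr - 1, r1)
  grid <- expand.grid(row = rows, col = cols)
  x0 <- segmap$origin[1] + grid$col * px[1]
  y1 <- segmap$origin[2] - grid$row * px[2]       # top edge
  dx <- pmax(x0 - p[1], p[1] - (x0 + px[1]), 0)
  dy <- pmax(p[2] - y1, (y1 - px[2]) - p[2], 0)
  hit <- dx^2 + dy^2 <= r^2 + 1e-15
  labs <- lg[cbind(grid$row[hit] + 1L, grid$col[hit] + 1L)]
  sort(unique(labs[labs >= 0L]))
}

#' Health index at a seeding point
#'
#' `I(p)` is the mean health level of the segments whose footprints
#' intersect the disc `B(p, r)`. With the default parameters only segments
#' labeled HL1..HL5 qualify; if none qualifies the index is undefined (`NA`,
#' the no-surviving-plant marker).
#'
#' @param p numeric length-2 world coordinates.
#' @param segmap a `segment_map`.
#' @param labels named vector: segment label (character) -> class token.
#' @param params a [health_params].
#' @return list with `index` (real or NA), `class` (integer or NA), `n`
#'   (number of qualifying segments) and `segments` (their labels).
#' @export
health_index <- function(p, segmap, labels, params = health_params()) {
  s <- segments_near_point(p, params$r, segmap)
  toks <- labels[as.character(s)]
  hv <- health_value(toks)
  veg <- !is.na(hv)
  n <- if (params$include_nonvegetation) length(s) else sum(veg)
  if (n == 0L)
    return(list(index = NA_real_, class = NA_integer_, n = 0L,
                segments = s[veg]))
  idx <- sum(hv[veg]) / n
  cls <- switch(params$discretize,
                "round-half-up" = as.integer(round_half_up(idx)),
                "floor" = as.integer(floor(idx)),
                "none" = NA_integer_)
  list(index = idx, class = cls, n = n, segments = s[veg])
}

#' Annotate seeding points with health indices
#'
#' @param points data.frame with `x`, `y` columns (from
#'   [detect_seeding_points()]).
#' @inheritParams health_index
#' @return `points` with `health_index`, `health_class` and `n_segments`
#'   columns appended; order of rows is preserved and row order does not
#'   affect any per-point result.
#' @export
index_all <- function(points, segmap, labels, params = health_params()) {
  if (!nrow(points)) {
    points$health_index <- numeric(0)
    points$health_class <- integer(0)
    points$n_segments <- integer(0)
    return(points)
  }
  res <- lapply(seq_len(nrow(points)), function(i)
    health_index(c(points$x[i], points$y[i]), segmap, labels, params))
  points$health_index <- vapply(res, `[[`, 0, "index")
  points$health_class <- vapply(res, `[[`, 0L, "class")
  points$n_segments <- vapply(res, `[[`, 0L, "n")
  points
}

#' Normalized difference vegetation index
#'
#' Per pixel `(NIR - R) / (NIR + R)`; cells where the denominator is zero (or
#' either band is nodata) are NA. All defined values lie in `[-1, 1]` for
#' non-negative radiances.
#'
#' @param raster an [ms_raster] with `NIR` and `R` bands.
#' @return an [ms_raster] with a single `NDVI` band.
#' @export
ndvi <- function(raster) {
  if (!all(c("NIR", "R") %in% names(raster$bands)))
    stop("configuration error: NDVI needs bands NIR and R", call. = FALSE)
  nir <- raster$bands$NIR; red <- raster$bands$R
  den <- nir + red
  v <- (nir - red) / den
  v[den == 0] <- NA_real_
  v[raster$nodata_mask] <- NA_real_
  ms_raster(list(NDVI = v), origin = raster$origin,
            pixel_size = raster$pixel_size, crs_id = raster$crs_id,
            nodata_mask = is.na(v))
}

#' Match detected seeding points to a reference layout
#'
#' Greedy nearest-neighbor pairing: candidate (reference, detection) pairs
#' within `tol` are taken in order of increasing distance, each reference and
#' detection used at most once. Unmatched reference positions are the
#' no-plant predictions; unmatched detections are flagged spurious.
#'
#' @param detected data.frame with `x`, `y` (and optionally `health_class`).
#' @param reference data.frame with `x`, `y` (and optionally `class`).
#' @param tol pairing tolerance in meters; default `d/2` for d = 0.3.
#' @return list with `pairs` (data.frame: `ref`, `det`, `dist` — row indices
#'   into the inputs), `unmatched_ref` and `spurious_det` (integer indices).
#' @export
match_to_reference <- function(detected, reference, tol = 0.15) {
  nd <- nrow(detected); nref <- nrow(reference)
  if (!nd || !nref) {
    return(list(pairs = data.frame(ref = integer(), det = integer(),
                                   dist = numeric()),
                unmatched_ref = seq_len(nref), spurious_det = seq_len(nd)))
  }
  dx <- outer(reference$x, detected$x, `-`)
  dy <- outer(reference$y, detected$y, `-`)
  dist <- sqrt(dx^2 + dy^2)
  cand <- which(dist <= tol, arr.ind = TRUE)
  ord <- order(dist[cand])
  cand <- cand[ord, , drop = FALSE]
  ref_used <- logical(nref); det_used <- logical(nd)
  pairs <- list()
  for (i in seq_len(nrow(cand))) {
    rr <- cand[i, 1]; dd <- cand[i, 2]
    if (ref_used[rr] || det_used[dd]) next
    ref_used[rr] <- TRUE; det_used[dd] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(ref = rr, det = dd,
                                              dist = dist[rr, dd])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(ref = integer(), det = integer(), dist = numeric())
  list(pairs = pairs,
       unmatched_ref = which(!ref_used),
       spurious_det = which(!det_used))
}

#' Per-row health-class count table
#'
#' Cross-tabulates seeding points by discrete health class (the no-plant
#' marker first, then levels 1-5) against plowing row, with a row-sum column.
#'
#' @param points data.frame with `health_class` (NA = no plant) and `row_id`.
#' @param rows row ids to report; default the sorted observed ids.
#' @return integer matrix, classes x rows plus a `Sum` column.
#' @export
health_count_table <- function(points, rows = NULL) {
  if (is.null(rows)) rows <- sort(unique(points$row_id))
  cls <- factor(ifelse(is.na(points$health_class), "\u2205",
                       as.character(points$health_class)),
                levels = c("\u2205", as.character(1:5)))
  rid <- factor(points$row_id, levels = rows)
  m <- table(cls, rid)
  m <- matrix(as.integer(m), nrow = 6,
              dimnames = list(`I(p)` = levels(cls), row = paste0("R", rows)))
  cbind(m, Sum = rowSums(m))
}
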